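# six-frame ORF scan and coding triage at the 300 bp CDS threshold

#' Six-frame open reading frame scan
#'
#' For each of the six reading frames, reports the longest open span between
#' stop codons (getORF-like; `require_start = TRUE` instead anchors each span
#' at its first in-frame `ATG`). Codons containing `N` are treated as neither
#' stop nor start. Reverse-strand ORFs are reported in forward-strand 0-based
#' half-open coordinates with a negative frame sign.
#'
#' @param seq a single DNA sequence over `A,C,G,T,N`.
#' @param require_start anchor ORFs at an `ATG` (default FALSE: stop-to-stop
#'   spans, the more permissive convention).
#' @return data.frame with one row per frame: `frame` (+1..+3, -1..-3),
#'   `strand`, `start`, `end` (forward-strand coordinates; `NA` when the
#'   frame has no open span), `length` (bp, multiple of 3), `has_start`,
#'   `has_stop`.
#' @export
#' @examples
#' find_orfs("ATGAAACCCTAA")
find_orfs <- function(seq, require_start = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (off in 0:2) {
      frame <- (off + 1L) * (if (strand == "+") 1L else -1L)
      n_cod <- (L - off) %/% 3L
      blank <- data.frame(frame = frame, strand = strand,
                          start = NA_integer_, end = NA_integer_,
                          length = 0L, has_start = FALSE, has_stop = FALSE,
                          stringsAsFactors = FALSE)
      if (n_cod < 1) { rows[[length(rows) + 1L]] <- blank; next }
      starts <- off + seq.int(1L, by = 3L, length.out = n_cod)
      cods <- substring(s, starts, starts + 2L)
      is_stop <- cods %in% STOP_CODONS
      r <- rle(!is_stop)
      seg_end <- cumsum(r$lengths)
      seg_start <- seg_end - r$lengths + 1L
      open <- which(r$values)
      if (!length(open)) { rows[[length(rows) + 1L]] <- blank; next }
      ci <- seg_start[open]; cj <- seg_end[open]
      if (require_start) {
        ci <- vapply(seq_along(ci), function(g) {
          atg <- which(cods[ci[g]:cj[g]] == "ATG")
          if (length(atg)) ci[g] + atg[1] - 1L else NA_integer_
        }, integer(1))
        keep <- !is.na(ci)
        ci <- ci[keep]; cj <- cj[keep]
      }
      if (!length(ci)) { rows[[length(rows) + 1L]] <- blank; next }
      best <- which.max(cj - ci)           # leftmost on ties
      bi <- ci[best]; bj <- cj[best]
      local_start <- off + (bi - 1L) * 3L  # 0-based on the scanned strand
      local_end <- off + bj * 3L
      if (strand == "+") {
        fs <- local_start; fe <- local_end
      } else {
        fs <- L - local_end; fe <- L - local_start
      }
      rows[[length(rows) + 1L]] <- data.frame(
        frame = frame, strand = strand, start = fs, end = fe,
        length = local_end - local_start,
        has_start = any(cods[bi:bj] == "ATG"),
        has_stop = bj < n_cod,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coding triage of unigenes by best ORF length
#'
#' A unigene is classified as putatively protein coding when its best open
#' reading frame over all six frames is strictly longer than `min_cds_bp`
#' (default 300 bp). Ties between frames are broken toward the forward strand,
#' then the lower frame number.
#'
#' @param seqs named character vector of unigene sequences (a single unnamed
#'   sequence is also accepted).
#' @param min_cds_bp coding-length threshold in bp; the comparison is strict.
#' @param require_start passed to [find_orfs()].
#' @return data.frame with columns `unigene_id`, `coding`, `length`, `frame`,
#'   `strand`, `start`, `end`.
#' @export
classify_coding <- function(seqs, min_cds_bp = 300L, require_start = FALSE) {
  if (length(seqs) == 1 && is.null(names(seqs))) names(seqs) <- "seq1"
  seqs <- as_sequences(seqs)
  rows <- lapply(names(seqs), function(id) {
    orfs <- find_orfs(seqs[[id]], require_start = require_start)
    # rows come ordered +1,+2,+3,-1,-2,-3; which.max keeps the first maximum,
    # giving the forward-strand / lower-frame tie-break
    best <- orfs[which.max(orfs$length), ]
    data.frame(unigene_id = id, coding = best$length > min_cds_bp,
               length = best$length, frame = best$frame,
               strand = best$strand, start = best$start, end = best$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
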