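# perfect microsatellite (EST-SSR) detection, canonical motif classification,
# summaries and marker-locus selection filters

#' Primitivity of a repeat unit
#'
#' A unit is primitive when it is not a whole-number repetition of any shorter
#' string (e.g. `"ATAT"` is `"AT"` twice, hence not primitive).
#'
#' @param unit motif string.
#' @return logical.
#' @export
is_primitive <- function(unit) {
  k <- nchar(unit)
  if (k <= 1) return(k == 1)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 && strrep(substr(unit, 1, d), k / d) == unit) return(FALSE)
  }
  TRUE
}

#' Canonical motif class of a repeat unit
#'
#' Motif units are grouped under cyclic rotation only (no reverse-complement
#' merging): the class representative is the lexicographically minimal
#' rotation, so `"TC"` and `"CT"` both canonicalize to `"CT"`. This grouping
#' yields exactly 6 dinucleotide and 20 trinucleotide classes. Non-primitive
#' units are rejected (returned as `NA`).
#'
#' @param unit motif string over `A,C,G,T`, length 1-6.
#' @return the canonical rotation, or `NA_character_` for a non-primitive
#'   unit.
#' @export
#' @examples
#' canonical_motif("TC")    # "CT"
#' canonical_motif("ATAT")  # NA: not primitive
canonical_motif <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1)
  unit <- toupper(unit)
  k <- nchar(unit)
  if (k < 1 || k > 6) stop("motif unit must be 1-6 bp")
  if (grepl("[^ACGT]", unit)) stop("motif unit has non-ACGT characters: ", unit)
  if (!is_primitive(unit)) return(NA_character_)
  rots <- vapply(seq_len(k), function(i) {
    paste0(substr(unit, i, k), substr(unit, 1, i - 1))
  }, character(1))
  min(rots)
}

#' Number of canonical motif classes for a unit length
#'
#' Enumerates every length-`k` DNA string, discards non-primitive units and
#' counts distinct canonical rotations: 4, 6, 20, 60, 204 and 670 classes for
#' k = 1..6.
#'
#' @param k unit length, 1-6.
#' @return integer class count.
#' @export
motif_class_count <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > 6) stop("k must be in 1..6")
  units <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                       stringsAsFactors = FALSE))
  canon <- vapply(units, canonical_motif, character(1))
  length(unique(canon[!is.na(canon)]))
}

#' Detect perfect microsatellites
#'
#' Finds every maximal perfect tandem repeat of a primitive 2-6 bp unit
#' repeated at least `min_repeats` times (default 5). `N` breaks any repeat.
#' Overlapping candidates are resolved deterministically: longest span wins,
#' then leftmost, then smallest unit length; the reported unit is the phase
#' starting at the locus start, and spans are trimmed to whole repeat units.
#' Coordinates are 0-based half-open.
#'
#' @param seqs named character vector of sequences over `A,C,G,T,N` (a single
#'   unnamed sequence is also accepted).
#' @param min_repeats minimum number of unit repetitions (default 5).
#' @param k_range inclusive unit-length range, within 2..6 by default.
#' @return data.frame with columns `unigene_id`, `start`, `end`, `unit`,
#'   `canonical`, `n_repeats`.
#' @export
#' @examples
#' detect_ssrs(c(u1 = "GGACACACACACTT"))
detect_ssrs <- function(seqs, min_repeats = 5L, k_range = c(2L, 6L)) {
  if (length(seqs) == 1 && is.null(names(seqs))) names(seqs) <- "seq1"
  seqs <- as_sequences(seqs)
  stopifnot(min_repeats >= 2, k_range[1] >= 1, k_range[2] <= 6,
            k_range[1] <= k_range[2])
  rows <- lapply(names(seqs), function(id) {
    cand <- ssr_candidates(seqs[[id]], min_repeats, k_range)
    if (is.null(cand)) return(NULL)
    cand <- resolve_overlaps(cand)
    data.frame(unigene_id = id, start = cand$start, end = cand$end,
               unit = cand$unit,
               canonical = vapply(cand$unit, canonical_motif, character(1)),
               n_repeats = cand$n_repeats,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_locus_frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# all maximal tandem-repeat candidates of one sequence (primitive units only)
ssr_candidates <- function(s, min_repeats, k_range) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  valid <- ch %in% c("A", "C", "G", "T")
  out <- list()
  for (k in seq(k_range[1], k_range[2])) {
    if (L < k * min_repeats) next
    m <- L - k
    eq <- ch[seq_len(m)] == ch[(k + 1):L] & valid[seq_len(m)] & valid[(k + 1):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (h in which(r$values & r$lengths >= (min_repeats - 1L) * k)) {
      i <- starts[h]
      n_rep <- (r$lengths[h] + k) %/% k
      unit <- substr(s, i, i + k - 1L)
      if (!is_primitive(unit)) next
      out[[length(out) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + k * n_rep, k = k, unit = unit,
        n_repeats = n_rep, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# greedy non-overlap resolution: longest span, then leftmost, then smallest k
resolve_overlaps <- function(cand) {
  cand <- cand[order(-(cand$end - cand$start), cand$start, cand$k), ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  acc_s <- integer(0); acc_e <- integer(0)
  for (j in seq_len(nrow(cand))) {
    if (!any(cand$start[j] < acc_e & cand$end[j] > acc_s)) {
      keep[j] <- TRUE
      acc_s <- c(acc_s, cand$start[j]); acc_e <- c(acc_e, cand$end[j])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand[order(cand$start), , drop = FALSE]
}

#' Summarize detected microsatellites by unit length
#'
#' Tabulates locus counts, bp occupied, percent of the non-ambiguous sequence
#' (half-up, 2 decimals) and distinct canonical classes per unit length, plus
#' an overall row.
#'
#' @param loci data.frame from [detect_ssrs()].
#' @param total_non_ambiguous_bp total non-ambiguous bp of the sequence set
#'   (> 0).
#' @param k_range unit lengths to report.
#' @return data.frame with columns `unit_length`, `n_loci`, `bp`, `percent`,
#'   `n_classes` (the final row, `unit_length = "all"`, holds the totals).
#' @export
summarize_ssrs <- function(loci, total_non_ambiguous_bp, k_range = c(2L, 6L)) {
  if (total_non_ambiguous_bp <= 0) stop("total_non_ambiguous_bp must be > 0")
  ks <- seq(k_range[1], k_range[2])
  ulen <- nchar(loci$unit)
  span <- loci$end - loci$start
  per_k <- lapply(ks, function(k) {
    sel <- ulen == k
    data.frame(unit_length = as.character(k), n_loci = sum(sel),
               bp = sum(span[sel]),
               percent = percent_of(sum(span[sel]), total_non_ambiguous_bp),
               n_classes = length(unique(loci$canonical[sel])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_k)
  rbind(out, data.frame(unit_length = "all", n_loci = nrow(loci),
                        bp = sum(span),
                        percent = percent_of(sum(span),
                                             total_non_ambiguous_bp),
                        n_classes = length(unique(loci$canonical))))
}

#' Select candidate marker loci for primer design
#'
#' Applies the marker-selection filters used for EST-SSR panels: a locus is
#' eligible only if (a) its unigene is sequence-unique — it shares no exact
#' `window_bp` window with any other unigene (an alignment-free stand-in for
#' an all-against-all BLAST uniqueness screen), (b) the flanking
#' `min_flank_bp` on both sides contains no short repeat (any tandem of >= 3
#' repetitions), (c) both flanks are at least `min_flank_bp` long, and (d) the
#' unigene can yield a PCR product of at least `min_product_bp` spanning the
#' locus.
#'
#' @param loci data.frame from [detect_ssrs()].
#' @param unigenes named character vector containing every unigene referenced
#'   by `loci`.
#' @param min_flank_bp minimum repeat-free flank on each side (default 50).
#' @param min_product_bp minimum spanning PCR product size (default 150).
#' @param window_bp exact-window size for the uniqueness screen (default 60).
#' @return `loci` with added columns `left_flank`, `right_flank`, `unique`,
#'   `flank_repeat_free`, `eligible`.
#' @export
select_marker_loci <- function(loci, unigenes, min_flank_bp = 50L,
                               min_product_bp = 150L, window_bp = 60L) {
  unigenes <- as_sequences(unigenes, "unigenes")
  dangling <- setdiff(loci$unigene_id, names(unigenes))
  if (length(dangling)) {
    stop("loci reference unknown unigene(s): ",
         paste(utils::head(dangling, 5), collapse = ", "))
  }
  non_unique_ids <- shared_window_ids(unigenes, window_bp)
  lens <- nchar(unigenes)

  n <- nrow(loci)
  left <- loci$start
  right <- lens[loci$unigene_id] - loci$end
  repeat_free <- vapply(seq_len(n), function(j) {
    s <- unigenes[[loci$unigene_id[j]]]
    lf <- substr(s, max(1L, loci$start[j] - min_flank_bp + 1L), loci$start[j])
    rf <- substr(s, loci$end[j] + 1L,
                 min(nchar(s), loci$end[j] + min_flank_bp))
    nrow(detect_ssrs(c(flank = lf), min_repeats = 3L)) == 0 &&
      nrow(detect_ssrs(c(flank = rf), min_repeats = 3L)) == 0
  }, logical(1))
  out <- loci
  out$left_flank <- as.integer(left)
  out$right_flank <- as.integer(unname(right))
  out$unique <- !(loci$unigene_id %in% non_unique_ids)
  out$flank_repeat_free <- repeat_free
  out$eligible <- out$unique & out$flank_repeat_free &
    out$left_flank >= min_flank_bp & out$right_flank >= min_flank_bp &
    unname(lens[loci$unigene_id]) >= min_product_bp
  out
}

# ids of unigenes sharing at least one exact length-w window with another
shared_window_ids <- function(unigenes, w) {
  if (length(unigenes) < 2) return(character(0))
  per <- lapply(names(unigenes), function(id) {
    s <- unigenes[[id]]
    L <- nchar(s)
    if (L < w) return(NULL)
    starts <- seq_len(L - w + 1L)
    data.frame(id = id, win = unique(substring(s, starts, starts + w - 1L)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, per)
  if (is.null(df)) return(character(0))
  shared <- unique(df$win[duplicated(df$win)])
  unique(df$id[df$win %in% shared])
}

#' Summarize a validated SSR-locus panel
#'
#' Counts loci by polymorphism status (`YES` polymorphic, `NO` monomorphic,
#' `NULL` null alleles) and by motif unit length, as reported for a
#' PCR-validated EST-SSR panel (see [load_table1()]).
#'
#' @param panel data.frame with columns `motif_unit` and `polymorphic`;
#'   defaults to the packaged 23-locus reference panel.
#' @return list with components `status` (named counts: polymorphic,
#'   monomorphic, null_allele) and `motif_length` (named counts by unit
#'   length).
#' @export
summarize_table1 <- function(panel = load_table1()) {
  if (!all(c("motif_unit", "polymorphic") %in% names(panel))) {
    stop("panel must have columns motif_unit and polymorphic")
  }
  if (!all(panel$polymorphic %in% c("YES", "NO", "NULL"))) {
    stop("malformed polymorphic status (expected YES/NO/NULL)")
  }
  status <- c(polymorphic = sum(panel$polymorphic == "YES"),
              monomorphic = sum(panel$polymorphic == "NO"),
              null_allele = sum(panel$polymorphic == "NULL"))
  ml <- table(factor(nchar(panel$motif_unit), levels = 2:6))
  list(status = status,
       motif_length = setNames(as.integer(ml), names(ml)))
}
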