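# k-mer seeded read-to-unigene assignment with a mismatch budget

#' Build a k-mer occurrence index over a unigene set
#'
#' Records every length-`k` substring occurrence of every unigene (forward
#' strand only; reverse-complement hits are found at query time by seeding the
#' reverse complement of the read). With the default `k = 21`, any 75 bp read
#' placed with at most two mismatches is guaranteed to share at least one of
#' its three disjoint 21-mers exactly with the target (pigeonhole), so seeding
#' loses no qualifying placement.
#'
#' @param unigenes named character vector of unigene sequences over `A,C,G,T`.
#' @param k seed length (integer, `11 <= k <=` shortest unigene).
#' @return an object of class `"kmer_index"`.
#' @export
build_kmer_index <- function(unigenes, k = 21L) {
  unigenes <- as_sequences(unigenes, "unigenes")
  k <- as.integer(k)
  if (k < 11L) stop("k must be >= 11")
  lens <- nchar(unigenes)
  if (length(unigenes) && k > min(lens)) {
    stop("k exceeds the shortest unigene length (", min(lens), ")")
  }
  kmer <- character(0); uid <- integer(0); pos <- integer(0)
  if (length(unigenes)) {
    per <- lapply(seq_along(unigenes), function(i) {
      L <- lens[i]
      starts <- seq_len(L - k + 1L)
      list(kmer = substring(unigenes[[i]], starts, starts + k - 1L),
           uid = rep.int(i, length(starts)), pos = starts - 1L)
    })
    kmer <- unlist(lapply(per, `[[`, "kmer"), use.names = FALSE)
    uid <- unlist(lapply(per, `[[`, "uid"), use.names = FALSE)
    pos <- unlist(lapply(per, `[[`, "pos"), use.names = FALSE)
  }
  env <- list2env(split(seq_along(kmer), kmer), hash = TRUE,
                  size = max(1L, length(kmer)))
  structure(list(k = k, ids = names(unigenes), lengths = unname(lens),
                 ints = lapply(unigenes, utf8ToInt),
                 uid = uid, pos = pos, env = env),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("k-mer index: ", length(x$ids), " unigene(s), k = ", x$k, ", ",
      length(x$uid), " stored occurrence(s)\n", sep = "")
  invisible(x)
}

# disjoint seed offsets covering the read (0-based)
seed_offsets <- function(len, k) {
  off <- seq.int(0L, len - k, by = k)
  unique(c(off, len - k))
}

#' Assign reads to unigenes and tabulate raw counts
#'
#' Each read is placed by full-length ungapped alignment at every candidate
#' offset suggested by exact k-mer seed hits (both orientations unless
#' `revcomp = FALSE`). The read is counted for the unigene with the fewest
#' mismatches provided that number is at most `max_mismatch`; reads with no
#' qualifying placement, or whose best score is tied across distinct unigenes,
#' are left unassigned (deterministic, conservative counting). `N` bases never
#' match. The library total `N` is the number of assigned reads.
#'
#' @param reads named character vector of read sequences, or a data.frame with
#'   columns `read_id` and `seq` (as produced by [generate_reads()]).
#' @param index a [build_kmer_index()] over the target unigene set.
#' @param max_mismatch maximum substitutions allowed (default 2).
#' @param revcomp also try the reverse-complement orientation (default TRUE;
#'   libraries are typically unstranded).
#' @return data.frame with columns `unigene_id`, `count` (zero rows retained),
#'   with attributes `N` (assigned-read total) and `stats` (assignment /
#'   tie / no-hit breakdown).
#' @export
count_reads <- function(reads, index, max_mismatch = 2L, revcomp = TRUE) {
  stopifnot(inherits(index, "kmer_index"))
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$read_id)
  if (length(reads) && is.null(names(reads))) {
    names(reads) <- sprintf("read%06d", seq_along(reads))
  }
  reads <- toupper(reads)
  k <- index$k
  n_ref <- length(index$ids)
  counts <- integer(n_ref)
  stats <- c(assigned = 0L, tie = 0L, no_hit = 0L, too_short = 0L)

  for (r in reads) {
    len <- nchar(r)
    if (len < k) {
      stats["too_short"] <- stats["too_short"] + 1L
      next
    }
    rint <- utf8ToInt(r)
    rint[rint == utf8ToInt("N")] <- -1L          # N never matches
    orientations <- list(r)
    rints <- list(rint)
    if (revcomp) {
      rc <- revcomp(r)
      rci <- utf8ToInt(rc)
      rci[rci == utf8ToInt("N")] <- -1L
      orientations <- c(orientations, rc)
      rints <- c(rints, list(rci))
    }
    best <- max_mismatch + 1L
    best_uids <- integer(0)
    for (oi in seq_along(orientations)) {
      seq_o <- orientations[[oi]]
      int_o <- rints[[oi]]
      offs <- seed_offsets(len, k)
      cand_uid <- integer(0); cand_diag <- integer(0)
      for (so in offs) {
        hit <- get0(substr(seq_o, so + 1L, so + k), index$env)
        if (is.null(hit)) next
        cand_uid <- c(cand_uid, index$uid[hit])
        cand_diag <- c(cand_diag, index$pos[hit] - so)
      }
      if (!length(cand_uid)) next
      keep <- !duplicated(cand_uid * 1e9 + cand_diag)
      cand_uid <- cand_uid[keep]; cand_diag <- cand_diag[keep]
      for (ci in seq_along(cand_uid)) {
        u <- cand_uid[ci]; d <- cand_diag[ci]
        if (d < 0L || d + len > index$lengths[u]) next
        mm <- sum(index$ints[[u]][(d + 1L):(d + len)] != int_o)
        if (mm < best) {
          best <- mm
          best_uids <- u
        } else if (mm == best) {
          best_uids <- union(best_uids, u)
        }
      }
    }
    if (best > max_mismatch || length(best_uids) == 0L) {
      stats["no_hit"] <- stats["no_hit"] + 1L
    } else if (length(best_uids) > 1L) {
      stats["tie"] <- stats["tie"] + 1L
    } else {
      counts[best_uids] <- counts[best_uids] + 1L
      stats["assigned"] <- stats["assigned"] + 1L
    }
  }
  out <- data.frame(unigene_id = index$ids, count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "N") <- sum(counts)
  attr(out, "stats") <- stats
  out
}

#' Exhaustive Hamming-scan read assignment (reference scanner)
#'
#' Brute-force counterpart of [count_reads()]: scores a full-length ungapped
#' alignment at every offset of every unigene (both orientations unless
#' `revcomp = FALSE`) and reports, per read, the unique best-scoring unigene
#' within the mismatch budget, or `NA` for no hit or a best-score tie across
#' distinct unigenes. Intended for validating the seeded counter on small
#' inputs; quadratic in input size.
#'
#' @param reads character vector of read sequences.
#' @param unigenes named character vector of unigene sequences.
#' @param max_mismatch maximum substitutions allowed.
#' @param revcomp also try the reverse-complement orientation.
#' @return character vector of assigned unigene ids (`NA` when unassigned).
#' @export
hamming_scan <- function(reads, unigenes, max_mismatch = 2L, revcomp = TRUE) {
  unigenes <- as_sequences(unigenes, "unigenes")
  idx <- hamming_scan_assign(toupper(as.character(reads)), unname(unigenes),
                             as.integer(max_mismatch), isTRUE(revcomp))
  names(unigenes)[idx]
}
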