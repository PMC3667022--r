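# RPKM normalization: reads per kilobase of transcript per million mapped reads

#' RPKM of a single count
#'
#' `RPKM = 1e9 * C / (N * L)`, with `C` the reads mapped to the unigene, `N`
#' the total mappable reads in the library and `L` the unigene length in bp.
#' Vectorized over all three arguments.
#'
#' @param C mapped-read count (>= 0).
#' @param N library total mappable reads (> 0).
#' @param L unigene length in bp (> 0).
#' @return non-negative numeric.
#' @export
#' @examples
#' rpkm(10, 1e6, 1000)  # 10
rpkm <- function(C, N, L) {
  if (any(N <= 0)) stop("N must be > 0 (undefined normalization)")
  if (any(L <= 0)) stop("L must be > 0 (undefined normalization)")
  if (any(C < 0)) stop("C must be >= 0")
  1e9 * C / (as.numeric(N) * as.numeric(L))
}

#' RPKM table for one library
#'
#' @param counts named count vector or data.frame with `unigene_id`, `count`.
#' @param lengths named vector of unigene lengths in bp (or a named character
#'   vector of sequences, in which case `nchar()` is used).
#' @param N library total; defaults to the realized sum of `counts` (the
#'   mappable-read total of the formula's definition).
#' @return data.frame with columns `unigene_id`, `length`, `count`, `rpkm`
#'   (zero-count rows retained with RPKM 0).
#' @export
rpkm_table <- function(counts, lengths, N = NULL) {
  v <- as_count_vector(counts)
  if (is.character(lengths)) lengths <- vapply(lengths, nchar, integer(1))
  missing <- setdiff(names(v), names(lengths))
  if (length(missing)) {
    stop("no length known for unigene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  L <- lengths[names(v)]
  N <- N %||% sum(v)
  data.frame(unigene_id = names(v), length = as.integer(L),
             count = as.integer(v),
             rpkm = if (length(v)) rpkm(v, N, L) else numeric(0),
             stringsAsFactors = FALSE, row.names = NULL)
}
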