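# hypergeometric term over-representation of a DE gene set

#' Hypergeometric over-representation p-value
#'
#' Probability of observing at least `m` term-annotated genes among `n` DE
#' genes drawn from a background of `N` annotated genes of which `M` carry the
#' term:
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}}
#' Computed as the upper hypergeometric tail ([stats::phyper()], log-space
#' binomials internally), so it is stable for backgrounds up to 1e5 and
#' beyond. Vectorized. Note this `N` is the annotated background size, not a
#' library total.
#'
#' @param N annotated background size.
#' @param n number of DE genes in the background.
#' @param M number of background genes annotated to the term.
#' @param m number of DE genes annotated to the term.
#' @return upper-tail probability `P(X >= m)`.
#' @export
#' @examples
#' hypergeom_pvalue(10, 5, 4, 4)  # 6/252
hypergeom_pvalue <- function(N, n, M, m) {
  ok <- m >= 0 & M <= N & n <= N & m <= pmin(n, M)
  if (any(!ok)) stop("infeasible hypergeometric quadruple (need 0 <= m <= min(n, M) <= N)")
  phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Term over-representation of a DE gene set
#'
#' Tests every term with at least one annotated member for over-representation
#' of `de_set` by the upper-tail hypergeometric test, then corrects for
#' multiple testing: Bonferroni (multiply by the number of terms tested,
#' capped at 1; the GO-style convention) or Benjamini-Hochberg FDR (the
#' KEGG-pathway-style convention). The background is the set of annotated
#' unigenes in `term_map`, not the full transcriptome.
#'
#' @param de_set character vector of DE unigene ids; must be a subset of the
#'   annotated background.
#' @param term_map data.frame with columns `term_id`, `unigene_id` (and
#'   optionally `category`), as from [read_term_map()] or
#'   [generate_term_map()].
#' @param correction `"bonferroni"` or `"bh"`.
#' @param alpha significance cutoff on the corrected value (default 0.05).
#' @return data.frame with one row per tested term: `term_id`, `category`,
#'   `N`, `n`, `M`, `m`, `p`, `corrected`, `significant`; ordered by `p`.
#' @export
enrich <- function(de_set, term_map, correction = c("bonferroni", "bh"),
                   alpha = 0.05) {
  correction <- match.arg(correction)
  stopifnot(all(c("term_id", "unigene_id") %in% names(term_map)))
  term_map <- unique(term_map[c("term_id",
                                intersect("category", names(term_map)),
                                "unigene_id")])
  if (!"category" %in% names(term_map)) term_map$category <- "term"
  background <- unique(term_map$unigene_id)
  de_set <- unique(de_set)
  outside <- setdiff(de_set, background)
  if (length(outside)) {
    stop("DE genes outside the annotated background: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) " ..." else "")
  }
  N <- length(background)
  n <- length(de_set)
  in_de <- term_map$unigene_id %in% de_set
  M <- tapply(term_map$unigene_id, term_map$term_id, length)
  m <- tapply(in_de, term_map$term_id, sum)
  cat_of <- tapply(term_map$category, term_map$term_id, `[`, 1)
  terms <- names(M)
  p <- hypergeom_pvalue(N, n, as.integer(M), as.integer(m))
  corrected <- switch(correction,
                      bonferroni = pmin(1, p * length(terms)),
                      bh = bh_fdr(p))
  out <- data.frame(term_id = terms, category = as.character(cat_of),
                    N = N, n = n, M = as.integer(M), m = as.integer(m),
                    p = p, corrected = corrected,
                    significant = corrected <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$term_id), , drop = FALSE]
}
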