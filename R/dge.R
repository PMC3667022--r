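# two-library differential expression: Audic-Claverie exact test,
# Benjamini-Hochberg FDR, and the combined significance rule

#' Audic-Claverie single-term probability
#'
#' The probability of observing `y` reads for a unigene in a library of total
#' `N2`, conditional on `x` reads in a library of total `N1`, under the
#' Poisson tag-sampling model of Audic & Claverie (1997):
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^y
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}
#' Evaluated in log space; numerically stable for `x + y` well beyond 1e5.
#' Vectorized.
#'
#' @param x,y non-negative integer read counts in libraries 1 and 2.
#' @param N1,N2 positive library totals.
#' @return probability (numeric).
#' @export
#' @examples
#' ac_term(1, 1, 1e6, 1e6)  # 0.25
ac_term <- function(x, y, N1, N2) {
  check_ac_args(x, y, N1, N2)
  r <- N2 / N1
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

check_ac_args <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y))) {
    stop("x and y must be non-negative integers")
  }
  if (any(N1 <= 0) || any(N2 <= 0)) stop("N1 and N2 must be positive")
  invisible(NULL)
}

# log p(y' | x) as a function of y', fixed x and r = N2/N1
ac_log_term <- function(yy, x, r) {
  yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
    (x + yy + 1) * log1p(r)
}

# log-sum-exp accumulation of the lower tail P(Y <= y | x), summing from y
# toward 0; terms below the mode shrink monotonically, so the sum is
# truncated once a term falls below 1e-18 of the running total
ac_lower_log <- function(x, y, r) {
  lt <- ac_log_term(y, x, r)
  ls <- lt
  yy <- y
  while (yy >= 1) {
    # t(yy-1) = t(yy) * yy * (1+r) / (r * (x+yy))
    lt <- lt + log(yy) + log1p(r) - log(r) - log(x + yy)
    ls <- ls + log1p(exp(lt - ls))
    if (lt - ls < log(1e-18)) break
    yy <- yy - 1
  }
  ls
}

# upper tail P(Y >= y | x) by forward summation; valid (terms decreasing)
# for y at or above the distribution mode
ac_upper_log <- function(x, y, r) {
  lt <- ac_log_term(y, x, r)
  ls <- lt
  yy <- y
  repeat {
    # t(yy+1) = t(yy) * r * (x+yy+1) / ((yy+1) * (1+r))
    lt <- lt + log(r) + log(x + yy + 1) - log(yy + 1) - log1p(r)
    ls <- ls + log1p(exp(lt - ls))
    if (lt - ls < log(1e-18)) break
    yy <- yy + 1
  }
  ls
}

#' Two-sided Audic-Claverie p-value
#'
#' Tail probabilities are built by summing [ac_term()] terms (the smaller tail
#' directly, away from the distribution mode, truncated when a term falls
#' below 1e-18 of the running sum; the other tail by complement), then doubled
#' and capped at 1 — the conservative two-sided convention for this exact
#' statistic. Vectorized.
#'
#' @inheritParams ac_term
#' @return p-value in (0, 1].
#' @export
#' @examples
#' ac_pvalue(5, 5, 1e6, 1e6)  # 1: identical relative abundance
ac_pvalue <- function(x, y, N1, N2) {
  check_ac_args(x, y, N1, N2)
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i) {
    ac_pvalue_scalar(x[i], y[i], N1[i], N2[i])
  }, numeric(1))
}

ac_pvalue_scalar <- function(x, y, N1, N2) {
  r <- N2 / N1
  mode <- floor(x * r)  # mode of the conditional distribution of Y given x
  if (y <= mode) {
    lower <- exp(ac_lower_log(x, y, r))
    upper <- 1 - lower + exp(ac_log_term(y, x, r))
  } else {
    upper <- exp(ac_upper_log(x, y, r))
    lower <- 1 - upper + exp(ac_log_term(y, x, r))
  }
  p <- min(1, 2 * min(lower, upper))
  max(p, .Machine$double.xmin)  # p in (0, 1]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjusted values (via [stats::p.adjust()]) with enforced
#' monotonicity, clipped at 1; input order preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Combined significance call
#'
#' A unigene is differentially regulated when its FDR passes the cutoff *and*
#' the absolute log2 RPKM ratio passes the fold-change cutoff (defaults:
#' FDR 0.001, |log2 ratio| >= 1). The ratio is oriented library 2 over
#' library 1, so `up_in_2` means higher relative abundance in library 2;
#' zero-vs-nonzero RPKM gives an infinite ratio and can be significant.
#'
#' @param q FDR-adjusted p-values.
#' @param log2_ratio log2(RPKM2 / RPKM1); may be +/-Inf.
#' @param fdr_cutoff,lfc_cutoff significance cutoffs.
#' @return character vector over `up_in_1`, `up_in_2`, `not_significant`.
#' @export
classify_direction <- function(q, log2_ratio, fdr_cutoff = 0.001,
                               lfc_cutoff = 1) {
  out <- rep("not_significant", length(q))
  sig <- !is.na(q) & q <= fdr_cutoff & !is.na(log2_ratio)
  out[sig & log2_ratio >= lfc_cutoff] <- "up_in_2"
  out[sig & log2_ratio <= -lfc_cutoff] <- "up_in_1"
  out
}

#' Two-library differential expression table
#'
#' Fits the Audic-Claverie exact test to every unigene of two un-replicated
#' count libraries, adjusts by Benjamini-Hochberg, computes RPKM in each
#' library and calls direction with the combined FDR + fold-change rule.
#' Unigenes with zero counts in both libraries are retained with `p = 1`,
#' ratio 0 and are never significant.
#'
#' @param countsA,countsB counts for libraries 1 and 2 over the same unigene
#'   set (named vectors or `unigene_id`/`count` data.frames).
#' @param lengths named unigene lengths in bp (or named sequences).
#' @param fdr_cutoff,lfc_cutoff significance cutoffs (defaults 0.001 and 1).
#' @return an object of class `"dge_result"`: list with `table` (one
#'   DGE record per unigene), `summary` (total / up-in-1 / up-in-2),
#'   `library_sizes`, `cutoffs`. Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`.
#' @export
dge_table <- function(countsA, countsB, lengths, fdr_cutoff = 0.001,
                      lfc_cutoff = 1) {
  a <- as_count_vector(countsA, "countsA")
  b <- as_count_vector(countsB, "countsB")
  if (!setequal(names(a), names(b))) {
    stop("countsA and countsB cover different unigene sets")
  }
  b <- b[names(a)]
  N1 <- sum(a); N2 <- sum(b)
  if (N1 == 0 || N2 == 0) stop("a library has zero total counts")
  ta <- rpkm_table(a, lengths, N = N1)
  tb <- rpkm_table(b, lengths, N = N2)
  log2_ratio <- log2(tb$rpkm / ta$rpkm)
  both_zero <- a == 0 & b == 0
  log2_ratio[both_zero] <- 0
  p <- ac_pvalue(a, b, N1, N2)
  p[both_zero] <- 1
  q <- bh_fdr(p)
  direction <- classify_direction(q, log2_ratio, fdr_cutoff, lfc_cutoff)
  direction[both_zero] <- "not_significant"
  tab <- data.frame(unigene_id = names(a), length = ta$length,
                    x = as.integer(a), y = as.integer(b),
                    rpkm1 = ta$rpkm, rpkm2 = tb$rpkm,
                    log2_ratio = log2_ratio, p = p, q = q,
                    direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  summ <- c(total = sum(direction != "not_significant"),
            up_in_1 = sum(direction == "up_in_1"),
            up_in_2 = sum(direction == "up_in_2"))
  structure(list(table = tab, summary = summ,
                 library_sizes = c(N1 = N1, N2 = N2),
                 cutoffs = c(fdr = fdr_cutoff, lfc = lfc_cutoff)),
            class = "dge_result")
}

#' @export
print.dge_result <- function(x, ...) {
  cat("Two-library exact-test differential expression\n")
  cat(sprintf("  unigenes: %d   N1 = %d   N2 = %d\n", nrow(x$table),
              x$library_sizes[1], x$library_sizes[2]))
  cat(sprintf("  cutoffs: FDR <= %g, |log2 ratio| >= %g\n",
              x$cutoffs["fdr"], x$cutoffs["lfc"]))
  cat(sprintf("  differentially regulated: %d (up in 1: %d, up in 2: %d)\n",
              x$summary["total"], x$summary["up_in_1"], x$summary["up_in_2"]))
  invisible(x)
}

#' @export
summary.dge_result <- function(object, ...) object$summary

#' @export
as.data.frame.dge_result <- function(x, ...) x$table

#' Expression scatter of a two-library comparison
#'
#' log10 RPKM of library 2 against library 1; red points are up-regulated in
#' library 2, green up-regulated in library 1, blue not significant. A small
#' floor replaces zero RPKM so all unigenes are drawn.
#'
#' @param x a `"dge_result"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dge_result <- function(x, ...) {
  t <- x$table
  floor_val <- min(t$rpkm1[t$rpkm1 > 0], t$rpkm2[t$rpkm2 > 0], 1) / 10
  r1 <- log10(pmax(t$rpkm1, floor_val))
  r2 <- log10(pmax(t$rpkm2, floor_val))
  col <- c(up_in_1 = "green3", up_in_2 = "red",
           not_significant = "blue")[t$direction]
  plot(r1, r2, col = col, pch = 20, cex = 0.5,
       xlab = "log10 RPKM (library 1)", ylab = "log10 RPKM (library 2)", ...)
  legend("topleft", pch = 20, col = c("red", "green3", "blue"),
         legend = c("up in library 2", "up in library 1", "not significant"),
         bty = "n", cex = 0.8)
  invisible(x)
}
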