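# independent reference implementations used to validate the package code;
# each deliberately takes a different route than the function it checks

# random DNA without going through the package generator
rand_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# --- Audic-Claverie: negative-binomial reparameterization ------------------
# Conditional on x, Y follows NB(size = x + 1, prob = N1 / (N1 + N2)); tails
# via pnbinom give an exact-arithmetic-quality reference for the summed form.
oracle_ac_term <- function(x, y, N1, N2) {
  dnbinom(y, size = x + 1, prob = N1 / (N1 + N2))
}

oracle_ac_pvalue <- function(x, y, N1, N2) {
  pr <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = pr)
  upper <- if (y == 0) 1 else pnbinom(y - 1, size = x + 1, prob = pr,
                                      lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

# --- Benjamini-Hochberg: hand-run step-up rule -----------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

# --- hypergeometric: exhaustive enumeration of the mass --------------------
oracle_hyper <- function(N, n, M, m) {
  i <- m:min(n, M)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# --- motif classes: Moebius / aperiodic-necklace closed form ---------------
oracle_necklace_count <- function(k, alphabet = 4) {
  mobius <- function(d) {
    if (d == 1) return(1)
    pf <- integer(0); x <- d; p <- 2
    while (x > 1) {
      if (x %% p == 0) {
        cnt <- 0
        while (x %% p == 0) { x <- x / p; cnt <- cnt + 1 }
        if (cnt > 1) return(0)
        pf <- c(pf, p)
      }
      p <- p + 1
    }
    (-1)^length(pf)
  }
  divs <- which(k %% seq_len(k) == 0)
  sum(vapply(divs, function(d) mobius(d) * alphabet^(k / d), numeric(1))) / k
}

# --- SSR: PCRE backreference scan ------------------------------------------
oracle_ssr <- function(s, min_repeats = 5) {
  cand <- list()
  for (k in 2:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, min_repeats - 1)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length")
    for (j in seq_along(m)) {
      unit <- substr(s, m[j], m[j] + k - 1)
      prim <- TRUE
      for (d in seq_len(k - 1)) {
        if (k %% d == 0 && strrep(substr(unit, 1, d), k / d) == unit) {
          prim <- FALSE; break
        }
      }
      if (!prim) next
      cand[[length(cand) + 1]] <- data.frame(
        start = m[j] - 1L, end = m[j] - 1L + lens[j], k = k, unit = unit,
        n_repeats = lens[j] %/% k, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), n_repeats = integer(0)))
  }
  cd <- do.call(rbind, cand)
  cd <- cd[order(-(cd$end - cd$start), cd$start, cd$k), , drop = FALSE]
  chosen <- cd[0, ]
  for (j in seq_len(nrow(cd))) {
    if (!any(cd$start[j] < chosen$end & cd$end[j] > chosen$start)) {
      chosen <- rbind(chosen, cd[j, ])
    }
  }
  chosen <- chosen[order(chosen$start), c("start", "end", "unit", "n_repeats")]
  rownames(chosen) <- NULL
  chosen
}

# --- ORF: explicit per-frame codon walk ------------------------------------
oracle_complement <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_best_orf_len <- function(s, min_len_codons = 1) {
  stops <- c("TAA", "TAG", "TGA")
  best <- 0
  for (str in c(s, oracle_complement(s))) {
    for (off in 0:2) {
      run <- 0
      i <- off + 1
      while (i + 2 <= nchar(str)) {
        cod <- substr(str, i, i + 2)
        if (cod %in% stops) {
          best <- max(best, run)
          run <- 0
        } else {
          run <- run + 1
        }
        i <- i + 3
      }
      best <- max(best, run)
    }
  }
  3 * best
}
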