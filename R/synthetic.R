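# seeded synthetic-data generator: unigenes with planted SSRs and ORFs,
# two-library counts, short reads and term maps with known ground truth

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Specification of a synthetic transcriptome experiment
#'
#' Bundles every parameter of the generator into one validated object.
#' Defaults describe the simulated study conditions used throughout the test
#' suite: 2,000 unigenes with log-normally distributed lengths clamped to
#' 100-3,000 bp, two un-replicated libraries of 5e5 reads each, 10% of
#' unigenes differentially expressed at |log2 fold change| = 3 (split evenly
#' up/down), Poisson counts (`dispersion = 0`), and one planted enriched
#' annotation term of 50 members sampled with 8:1 odds toward DE unigenes
#' among 50 terms overall.
#'
#' @param n_unigenes number of unigenes to simulate.
#' @param length_meanlog,length_sdlog log-normal parameters of unigene length.
#' @param length_range inclusive bp bounds applied after drawing lengths.
#' @param gc GC fraction of the background sequence.
#' @param planted_ssrs optional list of planted microsatellites, each a list
#'   with elements `unigene` (1-based index), `unit` (motif string), `n_repeats`
#'   and `offset` (0-based insertion offset; the repeat overwrites the
#'   sequence at `[offset, offset + nchar(unit) * n_repeats)`).
#' @param planted_orf_fraction probability that an eligible unigene carries a
#'   planted in-frame ATG..stop open reading frame.
#' @param planted_orf_bp planted CDS length in bp (multiple of 3, excludes the
#'   stop codon; default 306 so planted ORFs exceed the 300 bp coding
#'   threshold).
#' @param library_sizes target total read counts `c(N1, N2)`.
#' @param de_fraction fraction of unigenes differentially expressed.
#' @param de_log2fc absolute log2 fold change of DE unigenes (symmetric
#'   up/down).
#' @param dispersion negative-binomial dispersion; 0 gives Poisson counts.
#' @param n_terms number of annotation terms.
#' @param term_size_range member-count range of the unplanted terms.
#' @param enriched_term list with `term_id`, `size` (member count M) and
#'   `odds` (sampling odds of DE vs non-DE unigenes for membership).
#' @param seed integer seed; identical spec + seed reproduces every artifact
#'   byte for byte.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_unigenes = 2000,
                           length_meanlog = log(600), length_sdlog = 0.6,
                           length_range = c(100L, 3000L),
                           gc = 0.45,
                           planted_ssrs = NULL,
                           planted_orf_fraction = 0.1,
                           planted_orf_bp = 306L,
                           library_sizes = c(5e5, 5e5),
                           de_fraction = 0.1,
                           de_log2fc = 3,
                           dispersion = 0,
                           n_terms = 50L,
                           term_size_range = c(10L, 80L),
                           enriched_term = list(term_id = "T0001", size = 50L,
                                                odds = 8),
                           seed = 1L) {
  spec <- list(n_unigenes = as.integer(n_unigenes),
               length_meanlog = length_meanlog, length_sdlog = length_sdlog,
               length_range = as.integer(length_range), gc = gc,
               planted_ssrs = planted_ssrs,
               planted_orf_fraction = planted_orf_fraction,
               planted_orf_bp = as.integer(planted_orf_bp),
               library_sizes = library_sizes,
               de_fraction = de_fraction, de_log2fc = de_log2fc,
               dispersion = dispersion,
               n_terms = as.integer(n_terms),
               term_size_range = as.integer(term_size_range),
               enriched_term = enriched_term,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (n_unigenes < 0) stop("n_unigenes must be >= 0")
    probs <- c(gc = gc, planted_orf_fraction = planted_orf_fraction,
               de_fraction = de_fraction)
    bad <- probs < 0 | probs > 1
    if (any(bad)) stop("probabilities outside [0,1]: ",
                       paste(names(probs)[bad], collapse = ", "))
    if (length_range[1] < 1 || length_range[2] < length_range[1]) {
      stop("invalid length_range")
    }
    if (any(library_sizes <= 0)) stop("library_sizes must be positive")
    if (de_log2fc < 0) stop("de_log2fc must be >= 0")
    if (dispersion < 0) stop("dispersion must be >= 0")
    if (planted_orf_bp %% 3 != 0 || planted_orf_bp < 6) {
      stop("planted_orf_bp must be a positive multiple of 3")
    }
    for (p in planted_ssrs %||% list()) {
      if (!all(c("unigene", "unit", "n_repeats", "offset") %in% names(p))) {
        stop("each planted SSR needs unigene, unit, n_repeats, offset")
      }
      if (p$unigene < 1 || p$unigene > n_unigenes) stop("planted SSR unigene index out of range")
      span <- nchar(p$unit) * p$n_repeats
      # conservative check against the lower length bound; the per-unigene
      # check after drawing lengths rejects genuine overflows
      if (p$offset < 0 || span < 1) stop("invalid planted SSR geometry")
    }
  })
  invisible(spec)
}

random_dna <- function(n, gc = 0.5) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# codons that are neither stops (keeps planted frames open)
non_stop_codons <- function() {
  all3 <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 3)))
  setdiff(all3, STOP_CODONS)
}

#' Generate a synthetic unigene set with ground truth
#'
#' Draws random background sequence at the requested GC and length law, plants
#' open reading frames (in-frame `ATG ... stop` spans free of internal stops)
#' in a `planted_orf_fraction` of sufficiently long unigenes, then overwrites
#' user-requested microsatellites verbatim at their stated offsets. Baseline
#' expression levels and differential-expression status are also assigned here
#' so that repeated count draws share one truth.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `unigenes` (named character vector), and `truth`
#'   (list of data.frames `genes`, `ssrs`, `orfs`; coordinates are 0-based
#'   half-open on the forward strand).
#' @export
generate_unigenes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_unigenes
  ids <- if (n) sprintf("UG%05d", seq_len(n)) else character(0)

  lens <- as.integer(pmin(pmax(round(rlnorm(n, spec$length_meanlog,
                                            spec$length_sdlog)),
                               spec$length_range[1]), spec$length_range[2]))
  seqs <- vapply(lens, random_dna, character(1), gc = spec$gc)
  names(seqs) <- ids

  # expression truth: log-normal baseline, DE flags with symmetric direction
  base_expr <- rlnorm(n, meanlog = 0, sdlog = 1)
  is_de <- runif(n) < spec$de_fraction
  dir <- ifelse(is_de, sample(c(-1, 1), n, replace = TRUE), 0)
  e1 <- base_expr
  e2 <- base_expr * 2^(dir * spec$de_log2fc)

  # plant ORFs (skipped in unigenes carrying user-planted SSRs)
  ssr_targets <- vapply(spec$planted_ssrs %||% list(),
                        function(p) as.integer(p$unigene), integer(1))
  orf_total <- spec$planted_orf_bp + 3L
  eligible <- which(lens >= orf_total & !(seq_len(n) %in% ssr_targets))
  carriers <- eligible[runif(length(eligible)) < spec$planted_orf_fraction]
  codons <- non_stop_codons()
  orf_rows <- lapply(carriers, function(i) {
    body <- paste(sample(codons, spec$planted_orf_bp / 3 - 1, replace = TRUE),
                  collapse = "")
    orf <- paste0("ATG", body, sample(STOP_CODONS, 1))
    strand <- sample(c("+", "-"), 1)
    ins <- if (strand == "+") orf else revcomp(orf)
    off <- sample.int(lens[i] - orf_total + 1L, 1) - 1L
    substr(seqs[[i]], off + 1L, off + orf_total) <<- ins
    data.frame(unigene_id = ids[i], start = off, end = off + spec$planted_orf_bp,
               strand = strand, length = spec$planted_orf_bp,
               stringsAsFactors = FALSE)
  })

  ssr_rows <- lapply(spec$planted_ssrs %||% list(), function(p) {
    i <- as.integer(p$unigene)
    span <- nchar(p$unit) * p$n_repeats
    if (p$offset + span > lens[i]) {
      stop("planted SSR overflows unigene ", ids[i], " (length ", lens[i], ")")
    }
    substr(seqs[[i]], p$offset + 1L, p$offset + span) <<-
      strrep(p$unit, p$n_repeats)
    data.frame(unigene_id = ids[i], start = as.integer(p$offset),
               end = as.integer(p$offset + span), unit = p$unit,
               n_repeats = as.integer(p$n_repeats), stringsAsFactors = FALSE)
  })

  genes <- data.frame(unigene_id = ids, length = lens, is_de = is_de,
                      direction = dir, expr1 = e1, expr2 = e2,
                      stringsAsFactors = FALSE)
  truth <- list(genes = genes,
                ssrs = if (length(ssr_rows)) do.call(rbind, ssr_rows)
                       else data.frame(unigene_id = character(0),
                                       start = integer(0), end = integer(0),
                                       unit = character(0),
                                       n_repeats = integer(0)),
                orfs = if (length(orf_rows)) do.call(rbind, orf_rows)
                       else data.frame(unigene_id = character(0),
                                       start = integer(0), end = integer(0),
                                       strand = character(0),
                                       length = integer(0)))
  list(unigenes = seqs, truth = truth)
}

#' Generate two-library read counts from a synthetic truth
#'
#' Expected counts are proportional to unigene length times true expression,
#' scaled so that each library's expected total equals its target size.
#' Counts are Poisson when `dispersion = 0`, otherwise negative binomial with
#' `size = 1/dispersion`.
#'
#' @param spec a [synthetic_spec()].
#' @param sim result of [generate_unigenes()] on the same spec.
#' @param seed seed for the count draw; defaults to `spec$seed + 1` so counts
#'   can be re-drawn (replicate experiments) from one fixed truth.
#' @return data.frame with columns `unigene_id`, `count1`, `count2` and
#'   attributes `library_sizes` (realized totals), `mu` (expected-count
#'   matrix).
#' @export
generate_counts <- function(spec, sim, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- sim$truth$genes
  set.seed(seed)
  if (nrow(g) == 0) {
    out <- data.frame(unigene_id = character(0), count1 = integer(0),
                      count2 = integer(0))
    attr(out, "library_sizes") <- c(N1 = 0, N2 = 0)
    return(out)
  }
  w1 <- g$length * g$expr1
  w2 <- g$length * g$expr2
  mu1 <- spec$library_sizes[1] * w1 / sum(w1)
  mu2 <- spec$library_sizes[2] * w2 / sum(w2)
  draw <- function(mu) {
    if (spec$dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion)
  }
  c1 <- draw(mu1); c2 <- draw(mu2)
  out <- data.frame(unigene_id = g$unigene_id, count1 = c1, count2 = c2,
                    stringsAsFactors = FALSE)
  attr(out, "library_sizes") <- c(N1 = sum(c1), N2 = sum(c2))
  attr(out, "mu") <- cbind(mu1 = mu1, mu2 = mu2)
  out
}

#' Generate error-bearing short reads with true origin labels
#'
#' Each read is a uniformly placed substring of its origin unigene (reverse
#' complemented for minus-strand reads) with i.i.d. substitution errors.
#' Unigenes shorter than the read length are skipped with a warning.
#'
#' @param unigenes named character vector of unigene sequences.
#' @param n_reads total number of reads to emit.
#' @param read_length read length in bp (default 75).
#' @param error_rate per-base substitution probability.
#' @param weights optional per-unigene sampling weights (e.g. length times
#'   expression); default proportional to unigene length.
#' @param stranded if `FALSE` (default) reads are drawn from both strands.
#' @param seed integer seed.
#' @return data.frame with columns `read_id`, `seq`, `origin`, `start`
#'   (0-based on the forward strand), `strand`.
#' @export
generate_reads <- function(unigenes, n_reads, read_length = 75L,
                           error_rate = 0, weights = NULL, stranded = FALSE,
                           seed = 1L) {
  unigenes <- as_sequences(unigenes, "unigenes")
  set.seed(seed)
  lens <- nchar(unigenes)
  ok <- lens >= read_length
  if (!all(ok)) {
    warning(sum(!ok), " unigene(s) shorter than read_length skipped: ",
            paste(utils::head(names(unigenes)[!ok], 5), collapse = ", "))
  }
  pool <- which(ok)
  empty <- data.frame(read_id = character(0), seq = character(0),
                      origin = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (n_reads == 0 || length(pool) == 0) return(empty)
  w <- if (is.null(weights)) lens[pool] else weights[pool]
  origin <- pool[sample.int(length(pool), n_reads, replace = TRUE,
                            prob = w / sum(w))]
  start <- vapply(lens[origin] - read_length + 1L,
                  function(m) sample.int(m, 1L), integer(1)) - 1L
  seqs <- substr(unigenes[origin], start + 1L, start + read_length)
  strand <- if (stranded) rep("+", n_reads) else sample(c("+", "-"), n_reads,
                                                        replace = TRUE)
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  if (error_rate > 0) {
    chars <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                    nrow = read_length)
    hit <- which(runif(length(chars)) < error_rate)
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      chars[hit] <- vapply(chars[hit],
                           function(b) sample(setdiff(bases, b), 1),
                           character(1))
      seqs <- apply(chars, 2, paste, collapse = "")
    }
  }
  data.frame(read_id = sprintf("read%06d", seq_len(n_reads)),
             seq = unname(seqs), origin = names(unigenes)[origin],
             start = start, strand = strand, stringsAsFactors = FALSE)
}

#' Generate a term-to-gene annotation map with one planted enriched term
#'
#' All terms except the planted one receive uniformly sampled members; the
#' planted term's members are sampled without replacement with odds
#' `enriched_term$odds` favouring truly DE unigenes, creating a known
#' over-represented term against the DE set.
#'
#' @param spec a [synthetic_spec()].
#' @param sim result of [generate_unigenes()] on the same spec.
#' @param seed integer seed; defaults to `spec$seed + 2`.
#' @return data.frame with columns `term_id`, `category`, `unigene_id`.
#' @export
generate_term_map <- function(spec, sim, seed = spec$seed + 2L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- sim$truth$genes
  set.seed(seed)
  ids <- g$unigene_id
  n <- length(ids)
  if (n == 0 || spec$n_terms == 0) {
    return(data.frame(term_id = character(0), category = character(0),
                      unigene_id = character(0)))
  }
  term_ids <- sprintf("T%04d", seq_len(spec$n_terms))
  planted <- spec$enriched_term
  if (!is.null(planted)) term_ids[1] <- planted$term_id
  rows <- lapply(seq_len(spec$n_terms), function(j) {
    if (j == 1 && !is.null(planted)) {
      size <- min(planted$size, n)
      w <- ifelse(g$is_de, planted$odds, 1)
      members <- sample(ids, size, prob = w / sum(w))
    } else {
      size <- sample(seq(spec$term_size_range[1],
                         min(spec$term_size_range[2], n)), 1)
      members <- sample(ids, size)
    }
    data.frame(term_id = term_ids[j], category = "pathway",
               unigene_id = members, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
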