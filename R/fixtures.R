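# packaged reference tables from a giant freshwater prawn (Macrobrachium
# rosenbergii) de novo transcriptome survey; used as worked-example fixtures

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "txmine")
  if (!nzchar(p)) stop("missing packaged fixture: ", file)
  p
}

#' Packaged reference tables
#'
#' Machine-readable transcriptions of published summary tables from a
#' *M. rosenbergii* transcriptome survey, used as worked examples and
#' integrity checks:
#'
#' * `load_table1()` — 23 PCR-validated EST-SSR loci with motif unit, repeat
#'   number and polymorphism status (`YES` polymorphic, `NO` monomorphic,
#'   `NULL` null alleles).
#' * `load_table2()` — repetitive-element tallies (element counts, bp occupied
#'   and percent of 57,891,795 non-ambiguous bp). The simple-repeat bp figure
#'   was printed with a misplaced comma; both the raw string and the
#'   interpreted value are stored.
#' * `load_table3()` — pairwise two-library differential-expression totals and
#'   directional counts for three tissues.
#' * `headline_counts()` — assembly-wide headline counts (unigene total,
#'   BLAST-annotated, ORF-predicted and total coding unigenes, repeat bp).
#'
#' All invariants (row counts, status domain, directional counts summing to
#' totals) are asserted at load time.
#'
#' @return a data.frame (`headline_counts()` returns a named numeric vector).
#' @export
load_table1 <- function() {
  df <- read.delim(fixture_path("table1_ssr_loci.tsv"), comment.char = "#",
                   stringsAsFactors = FALSE,
                   colClasses = c(polymorphic = "character"))
  if (nrow(df) != 23) stop("Table 1 fixture must have 23 rows, found ", nrow(df))
  if (!all(df$polymorphic %in% c("YES", "NO", "NULL"))) {
    stop("Table 1 fixture has malformed polymorphic status")
  }
  if (!all(nchar(df$motif_unit) %in% 2:6) || any(df$n_repeats < 5)) {
    stop("Table 1 fixture has malformed motif columns")
  }
  df
}

#' @rdname load_table1
#' @export
load_table2 <- function() {
  df <- read.delim(fixture_path("table2_repeats.tsv"), comment.char = "#",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("class", "n_elements", "length_bp_raw", "length_bp",
                  "percent") %in% names(df)))
  # the interpreted bp must be the raw string with separators removed
  clean <- as.numeric(gsub("[ ,]", "", df$length_bp_raw))
  if (!all(clean == df$length_bp)) {
    stop("Table 2 fixture: interpreted bp does not match the printed string")
  }
  df
}

#' @rdname load_table1
#' @export
load_table3 <- function() {
  df <- read.delim(fixture_path("table3_dge_totals.tsv"), comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!all(df$total == df$up_in_t1 + df$up_in_t2)) {
    stop("Table 3 fixture: directional counts do not sum to the totals")
  }
  df
}

#' @rdname load_table1
#' @export
headline_counts <- function() {
  df <- read.delim(fixture_path("headline_counts.tsv"), comment.char = "#",
                   stringsAsFactors = FALSE)
  setNames(as.numeric(df$value), df$quantity)
}
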