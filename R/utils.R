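# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up (printed-table convention); base round() is banker's
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over `A,C,G,T,N` (case preserved).
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s))))
  }, character(1), USE.NAMES = FALSE)
}

# coerce counts input (named vector or data.frame with unigene_id/count) to a
# named non-negative integer-valued vector
as_count_vector <- function(x, arg = "counts") {
  if (is.data.frame(x)) {
    if (!all(c("unigene_id", "count") %in% names(x))) {
      stop(arg, " data.frame must have columns 'unigene_id' and 'count'")
    }
    x <- setNames(x$count, as.character(x$unigene_id))
  }
  if (is.null(names(x)) || anyNA(names(x))) {
    stop(arg, " must be a named vector or a unigene_id/count data.frame")
  }
  if (anyDuplicated(names(x))) stop(arg, " has duplicated unigene ids")
  v <- as.numeric(x)
  if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
    stop(arg, " must be non-negative integers")
  }
  setNames(v, names(x))
}

# coerce a sequence set (named character vector or DNAStringSet) to a named
# character vector of upper-case sequences
as_sequences <- function(x, arg = "sequences") {
  if (methods::is(x, "DNAStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x)) stop(arg, " must be a named character vector or DNAStringSet")
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x))))) {
    stop(arg, " must be named")
  }
  if (anyDuplicated(names(x))) {
    stop(arg, " has duplicated ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  toupper(x)
}

empty_locus_frame <- function() {
  data.frame(unigene_id = character(0), start = integer(0), end = integer(0),
             unit = character(0), canonical = character(0),
             n_repeats = integer(0), stringsAsFactors = FALSE)
}
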