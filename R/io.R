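# sequence and table I/O plus printed-percentage bookkeeping

#' Read a FASTA file into a named character vector
#'
#' Thin validating wrapper around [Biostrings::readDNAStringSet()]. Record ids
#' are the first whitespace-delimited token of each header. Duplicate ids and
#' empty sequences are rejected; non-IUPAC characters are rejected by the
#' underlying parser.
#'
#' @param path path to a FASTA file.
#' @return named character vector of upper-case sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(Biostrings::width(x) == 0)) {
    stop("empty sequence for id: ", paste(ids[Biostrings::width(x) == 0], collapse = ", "))
  }
  setNames(toupper(as.character(x)), ids)
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_sequences(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read/write short reads
#'
#' `read_reads()` accepts FASTA or FASTQ (auto-detected from the first byte);
#' `write_fastq()` emits Phred+33 FASTQ with a constant quality character.
#'
#' @param path file path.
#' @return `read_reads()`: named character vector of read sequences.
#' @export
read_reads <- function(path) {
  first <- readChar(path, 1L)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname read_reads
#' @param reads named character vector of read sequences.
#' @param quality_char single quality character applied to every base
#'   (default "I", Phred 40).
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  reads <- as_sequences(reads, "reads")
  stopifnot(nchar(quality_char) == 1)
  lines <- character(4L * length(reads))
  if (length(reads)) {
    lines[seq(1, by = 4, length.out = length(reads))] <- paste0("@", names(reads))
    lines[seq(2, by = 4, length.out = length(reads))] <- unname(reads)
    lines[seq(3, by = 4, length.out = length(reads))] <- "+"
    lines[seq(4, by = 4, length.out = length(reads))] <-
      strrep(quality_char, nchar(reads))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write headered TSV count tables
#'
#' Tables are tab-separated, UTF-8, with a header line and `#` comment lines.
#'
#' @param path file path.
#' @return `read_counts_tsv()`: data.frame with columns `unigene_id`, `count`.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("unigene_id", "count") %in% names(df))) {
    stop("count table must have columns 'unigene_id' and 'count': ", path)
  }
  as_count_vector(df)  # validates
  df[c("unigene_id", "count")]
}

#' @rdname read_counts_tsv
#' @param counts named count vector or unigene_id/count data.frame.
#' @export
write_counts_tsv <- function(counts, path) {
  v <- as_count_vector(counts)
  write_tsv(data.frame(unigene_id = names(v), count = as.integer(v)), path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a term-to-gene annotation map
#'
#' Accepts a long TSV with columns `term_id`, `unigene_id` and optionally
#' `category` (one pair per line), or GMT (`.gmt` extension: term, description,
#' then member ids, tab-separated).
#'
#' @param path file path.
#' @return data.frame with columns `term_id`, `category`, `unigene_id`.
#' @export
read_term_map <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    rows <- lapply(readLines(path), function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) return(NULL)
      data.frame(term_id = f[1], category = f[2], unigene_id = f[-(1:2)],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else {
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    if (!"category" %in% names(df)) df$category <- "term"
  }
  if (is.null(df) || !all(c("term_id", "unigene_id") %in% names(df))) {
    stop("term map must provide term_id and unigene_id: ", path)
  }
  df[c("term_id", "category", "unigene_id")]
}

#' Printed-percentage bookkeeping
#'
#' Computes `100 * part / whole` rounded half-up, the convention used when
#' tabulating annotation and repeat fractions (e.g. 24476 of 102230 unigenes
#' prints as 23.94).
#'
#' @param part,whole non-negative counts with `0 <= part <= whole`, `whole > 0`.
#' @param decimals decimal places to keep (default 2).
#' @return numeric percentage.
#' @export
#' @examples
#' percent_of(24476, 102230)
percent_of <- function(part, whole, decimals = 2) {
  if (any(whole <= 0)) stop("whole must be > 0")
  if (any(part < 0) || any(part > whole)) stop("need 0 <= part <= whole")
  round_half_up(100 * part / whole, decimals)
}
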