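# Shared helpers: rounding, sequence string utilities, FASTQ/TSV I/O.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used wherever a fold ratio or percent
#' is reported at a fixed precision. Base `round()` rounds half to even,
#' which would turn a 7.5-fold ratio into 8 or 7 depending on parity;
#' reported fold changes here always round 0.5 upwards.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(7.5)   # 8
#' round_half_up(6.047) # 6
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single non-missing number", call. = FALSE)
  }
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# reverse complement of a plain character string (delegates to Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  if (grepl("[^ACGTacgt]", x)) {
    stop(what, " contains non-ACGT characters; only unambiguous IUPAC DNA is supported",
         call. = FALSE)
  }
  invisible(toupper(x))
}

#' Write sequences as FASTQ
#'
#' Thin wrapper around [Biostrings::writeXStringSet()] emitting constant
#' high base qualities (the simulator does not model quality).
#'
#' @param seqs named character vector of read sequences.
#' @param path output file; a `.gz` suffix triggers compression.
#' @param quality_char single character used for every base quality.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  dna <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(strrep(quality_char, width(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#'
#' @param path FASTQ file (plain or gzipped).
#' @return named character vector; names are read ids truncated at the
#'   first whitespace.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# Write a data.frame as TSV with '#key=value' provenance header lines.
write_report_tsv <- function(df, path, meta = list()) {
  meta <- c(list(tool = "demedit",
                 version = as.character(packageVersion("demedit"))), meta)
  hdr <- sprintf("#%s=%s", names(meta), vapply(meta, as.character, ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read back a TSV written by write_report_tsv()
read_report_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}
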