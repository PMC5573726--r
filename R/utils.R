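# Internal sequence helpers. All sequences are handled as RNA (U) internally;
# T is accepted on input and converted once at the boundary.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases the input and converts `T` to `U`. Errors if any character
#' outside `A/C/G/U` remains after conversion.
#'
#' @param x Character vector of nucleotide sequences (DNA or RNA).
#' @return Character vector over the alphabet `A/C/G/U`.
#' @examples
#' as_rna(c("acgt", "ACGU"))
#' @export
as_rna <- function(x) {
  out <- chartr("Tt", "Uu", toupper(as.character(x)))
  out <- toupper(out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    abort(sprintf(
      "invalid nucleotide alphabet in %d sequence(s); first offender: '%s'",
      sum(bad), out[which(bad)[1]]
    ))
  }
  out
}

#' Reverse complement in RNA space
#'
#' @param x Character vector of RNA sequences (T accepted, converted to U).
#' @return Reverse complement, RNA alphabet.
#' @examples
#' rna_revcomp("AGGCA") # "UGCCU"
#' @export
rna_revcomp <- function(x) {
  x <- as_rna(x)
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Split sequences into character vectors once; used by mapper and generator.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

# Read a FASTA/FASTQ file into a named character vector (RNA alphabet).
# miRBase dialect: the id is the first whitespace-delimited token of the header.
read_seq_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) first <- ""
  set <- if (startsWith(first, "@")) {
    Biostrings::readBStringSet(path, format = "fastq")
  } else {
    Biostrings::readBStringSet(path, format = "fasta")
  }
  ids <- sub("\\s.*$", "", names(set))
  setNames(as_rna(as.character(set)), ids)
}

# U/T output choice shared by the FASTA writers.
format_alphabet <- function(x, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "dna") chartr("U", "T", x) else x
}

write_fasta <- function(seqs, path, alphabet = "rna", width = 70L) {
  stopifnot(!is.null(names(seqs)))
  out <- format_alphabet(unname(seqs), alphabet)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(out)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- out[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

write_fastq <- function(seqs, path, alphabet = "rna", quality_char = "I") {
  stopifnot(!is.null(names(seqs)))
  out <- format_alphabet(unname(seqs), alphabet)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(out)) {
    writeLines(c(
      paste0("@", names(seqs)[i]),
      out[i],
      "+",
      strrep(quality_char, nchar(out[i]))
    ), con)
  }
  invisible(path)
}
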