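#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings. Sequences are returned as a named character
#' vector of uppercase DNA strings; lowercase (soft-masked) bases are
#' uppercased on read, and any character outside the IUPAC DNA alphabet is
#' rejected.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  # Biostrings silently drops invalid one-letter codes; reject them instead.
  raw <- readLines(path, warn = FALSE)
  seq_lines <- raw[!startsWith(raw, ">")]
  bad <- grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn \t-]", seq_lines)
  if (any(bad)) {
    abort(sprintf("malformed FASTA %s: invalid sequence characters on line %d",
                  path, which(!startsWith(raw, ">"))[which(bad)[1]]))
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA %s: %s", path,
                                      conditionMessage(e)))
  )
  if (!length(set)) abort(sprintf("FASTA %s contains no records", path))
  out <- toupper(as.character(set))
  bad <- grepl("[^ACGTRYSWKMBDHVN]", out)
  if (any(bad)) {
    abort(sprintf("malformed FASTA %s: non-IUPAC characters in record %s",
                  path, names(out)[bad][1]))
  }
  # Keep only the first whitespace-delimited token of each header.
  names(out) <- sub("\\s.*$", "", names(out))
  if (any(!nzchar(names(out)))) abort("FASTA record with empty header")
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of DNA sequences.
#' @param width Line-wrap width.
#' @return `write_fasta()`: the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("`seqs` must be a named character vector")
  }
  set <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
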