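# Shared helpers. All genomic coordinates in this package are 0-based,
# half-open, as in BED/bedGraph. A position column `pos` is the 0-based
# coordinate of a single base (the last transcribed base for 3' ends).

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over character input; non-ACGT letters (e.g. N) are preserved
#' through complementation where IUPAC-defined.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, uppercase).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAATTTGC")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

# Coerce a genome argument (synthetic_genome, named character vector, or
# Biostrings::DNAStringSet) to a named character vector of chromosome strings.
as_genome_seq <- function(genome) {
  if (inherits(genome, "synthetic_genome")) {
    return(genome$seq)
  }
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    if (is.null(names(out))) {
      abort("DNAStringSet genome must have named sequences")
    }
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
      abort("character genome must be a named vector of chromosome sequences")
    }
    return(toupper(genome))
  }
  abort("`genome` must be a synthetic_genome, named character vector, or DNAStringSet")
}

# Extract reference bases [start, end) (0-based half-open) from one chromosome.
seq_slice <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  invisible(x)
}

check_strand <- function(strand) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf(
      "invalid strand value(s): %s (must be '+' or '-')",
      paste(unique(strand[bad]), collapse = ", ")
    ))
  }
  invisible(strand)
}

# TU sense-coordinate helpers. `tss0()` is the 0-based first transcribed base,
# `tes0()` the 0-based position one past the last body base in sense direction
# is not needed; we keep the reference interval [start, end) plus strand and
# convert offsets explicitly.
recycle_args <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, n)
}

tss0 <- function(start, end, strand) {
  a <- recycle_args(start = start, end = end, strand = strand)
  ifelse(a$strand == "+", a$start, a$end - 1L)
}

# Map a sense offset (0 at the TSS, increasing 5'->3' along the TU) to a
# genomic 0-based position.
offset_to_pos <- function(start, end, strand, offset) {
  a <- recycle_args(start = start, end = end, strand = strand,
                    offset = offset)
  ifelse(a$strand == "+", a$start + a$offset, (a$end - 1L) - a$offset)
}

# Inverse of offset_to_pos.
pos_to_offset <- function(start, end, strand, pos) {
  a <- recycle_args(start = start, end = end, strand = strand, pos = pos)
  ifelse(a$strand == "+", a$pos - a$start, (a$end - 1L) - a$pos)
}
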