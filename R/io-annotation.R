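ANNOT_COLS <- c("chrom", "start", "end", "tu_id", "score", "strand",
                "biotype", "exon_count")

#' Read and write transcription-unit annotations (BED6+2)
#'
#' The annotation contract is a BED6 file with two extra columns: column 7 is
#' the biotype and column 8 the exon count; an optional ninth column carries
#' a PAS strength score in `[0, 1]`. Coordinates are 0-based half-open; the
#' TSS is `start` on the plus strand and `end - 1` on the minus strand, the
#' TES the opposite edge. The score column is unused and written as 0.
#'
#' @param path File path.
#' @return `read_annotation()`: tibble with columns `tu_id`, `chrom`,
#'   `start`, `end`, `strand`, `biotype`, `exon_count`, `pas_score` (NA when
#'   the file has no ninth column).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE, comment = "#")
  if (!ncol(raw) %in% c(8L, 9L)) {
    abort(sprintf("annotation must have 8 or 9 columns (BED6+2[+1]), got %d",
                  ncol(raw)))
  }
  names(raw)[1:8] <- ANNOT_COLS
  if (ncol(raw) == 9L) names(raw)[9] <- "pas_score" else raw$pas_score <- NA_real_
  check_strand(raw$strand)
  if (any(raw$start < 0) || any(raw$end <= raw$start)) {
    abort("annotation intervals must satisfy 0 <= start < end")
  }
  if (any(raw$exon_count < 1)) abort("exon_count must be >= 1")
  if (any(!is.na(raw$pas_score) & (raw$pas_score < 0 | raw$pas_score > 1))) {
    abort("pas_score must lie in [0, 1]")
  }
  tibble(
    tu_id = as.character(raw$tu_id), chrom = as.character(raw$chrom),
    start = as.integer(raw$start), end = as.integer(raw$end),
    strand = raw$strand, biotype = as.character(raw$biotype),
    exon_count = as.integer(raw$exon_count), pas_score = raw$pas_score
  )
}

#' @rdname read_annotation
#' @param tus Annotation tibble as returned by [read_annotation()].
#' @return `write_annotation()`: the path, invisibly.
#' @export
write_annotation <- function(tus, path) {
  need <- c("tu_id", "chrom", "start", "end", "strand", "biotype",
            "exon_count")
  if (!all(need %in% names(tus))) {
    abort(sprintf("`tus` needs columns %s", paste(need, collapse = ", ")))
  }
  out <- tibble(
    chrom = tus$chrom, start = tus$start, end = tus$end, name = tus$tu_id,
    score = 0L, strand = tus$strand, biotype = tus$biotype,
    exon_count = tus$exon_count
  )
  if ("pas_score" %in% names(tus) && any(!is.na(tus$pas_score))) {
    out$pas_score <- tus$pas_score
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
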