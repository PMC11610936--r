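#' Read and write stranded bedGraph pairs as end-count profiles
#'
#' A sample's track is stored as two plain bedGraph files (UCSC dialect,
#' 0-based half-open, no track line), one per strand. On read, intervals are
#' expanded to per-base integer counts; overlapping intervals within one
#' file, negative values and non-integer values are rejected rather than
#' repaired. On write, runs of consecutive equal counts are collapsed back
#' into intervals, so the round trip is exact.
#'
#' @param plus_path,minus_path Paths of the plus- and minus-strand files.
#' @param flavor,epap,sample_id,condition Profile metadata (see
#'   [end_profile()]).
#' @return `read_bedgraph_pair()`: an [end_profile()].
#' @export
read_bedgraph_pair <- function(plus_path, minus_path,
                               flavor = "three_prime", epap = TRUE,
                               sample_id = "sample",
                               condition = NA_character_) {
  plus <- read_bedgraph_one(plus_path, "+")
  minus <- read_bedgraph_one(minus_path, "-")
  end_profile(bind_rows(plus, minus), flavor = flavor, epap = epap,
              sample_id = sample_id, condition = condition)
}

read_bedgraph_one <- function(path, strand) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) abort(sprintf("malformed bedGraph %s: %s", path,
                                      conditionMessage(e)))
  )
  if (!length(gr)) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  count = integer()))
  }
  tb <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,   # back to 0-based
    end = BiocGenerics::end(gr),
    value = gr$score
  )
  if (any(tb$value < 0)) abort(sprintf("negative value in bedGraph %s", path))
  if (any(tb$value != round(tb$value))) {
    abort(sprintf("non-integer count in bedGraph %s", path))
  }
  tb <- arrange(tb, .data$chrom, .data$start)
  same <- tb$chrom[-1L] == tb$chrom[-nrow(tb)]
  if (nrow(tb) > 1L && any(same & tb$start[-1L] < tb$end[-nrow(tb)])) {
    abort(sprintf("overlapping intervals in bedGraph %s", path))
  }
  tb <- tb[tb$value > 0, , drop = FALSE]
  if (!nrow(tb)) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  count = integer()))
  }
  widths <- tb$end - tb$start
  tibble(
    chrom = rep(tb$chrom, widths),
    pos = unlist(map2(tb$start, tb$end, function(s, e) seq.int(s, e - 1L))),
    strand = strand,
    count = as.integer(rep(tb$value, widths))
  )
}

#' @rdname read_bedgraph_pair
#' @param profile An [end_profile()].
#' @return `write_bedgraph_pair()`: invisibly, the two paths.
#' @export
write_bedgraph_pair <- function(profile, plus_path, minus_path) {
  if (!inherits(profile, "end_profile")) {
    abort("`profile` must be an end_profile")
  }
  write_bedgraph_one(profile[profile$strand == "+", ], plus_path)
  write_bedgraph_one(profile[profile$strand == "-", ], minus_path)
  invisible(c(plus_path, minus_path))
}

write_bedgraph_one <- function(tb, path) {
  tb <- tibble(chrom = tb$chrom, pos = tb$pos, count = tb$count)
  if (!nrow(tb)) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  tb <- arrange(tb, .data$chrom, .data$pos)
  # Collapse runs of adjacent positions with equal counts.
  new_run <- c(TRUE, !(tb$chrom[-1L] == tb$chrom[-nrow(tb)] &
                         tb$pos[-1L] == tb$pos[-nrow(tb)] + 1L &
                         tb$count[-1L] == tb$count[-nrow(tb)]))
  tb$run <- cumsum(new_run)
  out <- tb |>
    group_by(.data$run) |>
    summarise(chrom = .data$chrom[1L], start = min(.data$pos),
              end = max(.data$pos) + 1L, value = .data$count[1L],
              .groups = "drop") |>
    select("chrom", "start", "end", "value")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
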