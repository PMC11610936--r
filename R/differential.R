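# Normalisation, per-base log2 differentials, stabilised-end calling,
# region aggregation and the condition-comparison statistics.

#' Per-base CPM normalisation
#'
#' Scales per-base end counts to counts per million mapped ends:
#' `cpm = count * 1e6 / library_size`.
#'
#' @param profile An [end_profile()].
#' @return Tibble with columns `chrom`, `pos`, `strand`, `count`, `cpm`.
#' @export
normalize_cpm <- function(profile) {
  if (!inherits(profile, "end_profile")) {
    abort("`profile` must be an end_profile")
  }
  lib <- attr(profile, "library_size")
  if (!isTRUE(lib > 0)) abort("profile has zero library size")
  as_tibble(profile) |> mutate(cpm = .data$count * 1e6 / lib)
}

#' Region RPKM
#'
#' `rpkm = (region count sum * 1e9) / (library_size * region length)`.
#'
#' @param count_sum Total counts in the region.
#' @param length_bp Region length in bases.
#' @param library_size Total mapped ends in the library.
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(count_sum, length_bp, library_size) {
  if (any(library_size <= 0)) abort("`library_size` must be > 0")
  if (any(length_bp <= 0)) abort("`length_bp` must be > 0")
  count_sum * 1e9 / (library_size * length_bp)
}

check_paired <- function(treatment, control) {
  for (p in list(treatment, control)) {
    if (!inherits(p, "end_profile")) {
      abort("treatment and control must be end_profile objects")
    }
  }
  tm <- profile_meta(treatment)
  cm <- profile_meta(control)
  if (!identical(tm$flavor, cm$flavor) || !identical(tm$epap, cm$epap)) {
    abort(sprintf(
      "treatment (%s, %sEPAP) and control (%s, %sEPAP) are not a valid pair",
      tm$flavor, if (tm$epap) "+" else "-",
      cm$flavor, if (cm$epap) "+" else "-"
    ))
  }
  invisible(list(treatment = tm, control = cm))
}

#' Per-base log2 fold-change track
#'
#' At every position where either sample has a nonzero count, computes
#' `log2((cpm_t + pseudocount) / (cpm_c + pseudocount))`. The pseudocount is
#' in CPM units and is recorded on the result; swapping treatment and
#' control negates every value exactly.
#'
#' @param treatment,control Paired [end_profile()]s of identical flavor and
#'   EPAP status.
#' @param pseudocount Pseudocount in CPM units, > 0.
#' @return An `fc_track` tibble with columns `chrom`, `pos`, `strand`,
#'   `count_t`, `count_c`, `cpm_t`, `cpm_c`, `log2fc`.
#' @export
log2_ratio_track <- function(treatment, control, pseudocount = 1) {
  meta <- check_paired(treatment, control)
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("`pseudocount` must be > 0")
  }
  t_cpm <- normalize_cpm(treatment) |>
    rename(count_t = "count", cpm_t = "cpm")
  c_cpm <- normalize_cpm(control) |>
    rename(count_c = "count", cpm_c = "cpm")
  merged <- dplyr::full_join(t_cpm, c_cpm,
                             by = c("chrom", "pos", "strand")) |>
    mutate(
      count_t = dplyr::coalesce(.data$count_t, 0L),
      count_c = dplyr::coalesce(.data$count_c, 0L),
      cpm_t = dplyr::coalesce(.data$cpm_t, 0),
      cpm_c = dplyr::coalesce(.data$cpm_c, 0),
      log2fc = log2((.data$cpm_t + pseudocount) /
                      (.data$cpm_c + pseudocount))
    ) |>
    arrange(.data$chrom, .data$strand, .data$pos)
  structure(
    merged,
    class = c("fc_track", class(merged)),
    pseudocount = pseudocount,
    treatment = meta$treatment$sample_id,
    control = meta$control$sample_id,
    flavor = meta$treatment$flavor,
    epap = meta$treatment$epap
  )
}

#' Call 3' ends stabilised by a depletion
#'
#' Returns exactly the positions whose per-base log2 fold change (treatment
#' vs. control, CPM scale with pseudocount) is at least `min_log2` and whose
#' raw treatment count is at least `min_count`. Thresholds are recorded on
#' the result.
#'
#' @inheritParams log2_ratio_track
#' @param min_log2 Minimal log2 fold change (>= 0).
#' @param min_count Minimal raw treatment count.
#' @return An `end_call_set` tibble with columns `chrom`, `pos`, `strand`,
#'   `count_t`, `count_c`, `log2fc`.
#' @export
call_stabilized_ends <- function(treatment, control, min_log2 = 1.0,
                                 min_count = 1L, pseudocount = 1) {
  if (min_log2 < 0) abort("`min_log2` must be >= 0")
  fc <- log2_ratio_track(treatment, control, pseudocount = pseudocount)
  calls <- fc |>
    filter(.data$log2fc >= min_log2, .data$count_t >= min_count) |>
    select("chrom", "pos", "strand", "count_t", "count_c", "log2fc")
  structure(
    calls,
    class = c("end_call_set", class(calls)),
    min_log2 = min_log2, min_count = as.integer(min_count),
    pseudocount = attr(fc, "pseudocount"),
    treatment = attr(fc, "treatment"), control = attr(fc, "control")
  )
}

#' @export
print.end_call_set <- function(x, ...) {
  cat(sprintf(
    "<end_call_set> %d stabilised ends (%s vs %s; log2fc >= %g, count >= %d)\n",
    nrow(x), attr(x, "treatment"), attr(x, "control"),
    attr(x, "min_log2"), attr(x, "min_count")
  ))
  NextMethod()
}

tu_regions <- function(tus, downstream_window) {
  tibble(
    tu_id = tus$tu_id, chrom = tus$chrom, strand = tus$strand,
    body_start = tus$start, body_end = tus$end,
    down_start = ifelse(tus$strand == "+", tus$end,
                        tus$start - downstream_window),
    down_end = ifelse(tus$strand == "+", tus$end + downstream_window,
                      tus$start)
  )
}

region_sum <- function(tb, chrom, strand, start, end, value_col) {
  hit <- tb$chrom == chrom & tb$strand == strand &
    tb$pos >= start & tb$pos < end
  sum(tb[[value_col]][hit])
}

#' Body and downstream region signal per TU
#'
#' Strand-aware CPM-scaled sums over each TU's gene body `[TSS, TES)` and
#' the `downstream_window` bases 3' of the TES, for a paired
#' treatment/control, with per-region log2 changes using the same
#' pseudocount convention as [log2_ratio_track()].
#'
#' @inheritParams log2_ratio_track
#' @param tus Annotation tibble (see [read_annotation()]).
#' @param downstream_window Window length in bases (> 0) 3' of the TES.
#' @return A `region_signal_table` tibble with per-TU columns
#'   `body_cpm_t`, `body_cpm_c`, `down_cpm_t`, `down_cpm_c`, raw-count
#'   equivalents, `body_log2fc` and `down_log2fc`.
#' @export
region_signal <- function(treatment, control, tus, downstream_window = 3000,
                          pseudocount = 1) {
  check_paired(treatment, control)
  if (downstream_window <= 0) abort("`downstream_window` must be > 0")
  t_cpm <- normalize_cpm(treatment)
  c_cpm <- normalize_cpm(control)
  reg <- tu_regions(tus, downstream_window)
  res <- map(seq_len(nrow(reg)), function(i) {
    r <- reg[i, ]
    tibble(
      tu_id = r$tu_id,
      body_count_t = region_sum(t_cpm, r$chrom, r$strand, r$body_start,
                                r$body_end, "count"),
      body_count_c = region_sum(c_cpm, r$chrom, r$strand, r$body_start,
                                r$body_end, "count"),
      down_count_t = region_sum(t_cpm, r$chrom, r$strand, r$down_start,
                                r$down_end, "count"),
      down_count_c = region_sum(c_cpm, r$chrom, r$strand, r$down_start,
                                r$down_end, "count"),
      body_cpm_t = region_sum(t_cpm, r$chrom, r$strand, r$body_start,
                              r$body_end, "cpm"),
      body_cpm_c = region_sum(c_cpm, r$chrom, r$strand, r$body_start,
                              r$body_end, "cpm"),
      down_cpm_t = region_sum(t_cpm, r$chrom, r$strand, r$down_start,
                              r$down_end, "cpm"),
      down_cpm_c = region_sum(c_cpm, r$chrom, r$strand, r$down_start,
                              r$down_end, "cpm")
    )
  }) |> list_rbind()
  res <- res |>
    mutate(
      body_log2fc = log2((.data$body_cpm_t + pseudocount) /
                           (.data$body_cpm_c + pseudocount)),
      down_log2fc = log2((.data$down_cpm_t + pseudocount) /
                           (.data$down_cpm_c + pseudocount))
    )
  structure(
    res,
    class = c("region_signal_table", class(res)),
    pseudocount = pseudocount, downstream_window = downstream_window,
    treatment = attr(treatment, "sample_id"),
    control = attr(control, "sample_id")
  )
}

#' Select TUs with flank-only stabilisation
#'
#' Returns the TUs whose downstream (flank) signal increases by at least
#' `flank_min_log2` upon depletion without a corresponding gene-body
#' increase above `body_max_log2` — the short-TU selection used to isolate
#' protein-coding genes terminated by the DNA-directed mechanism.
#'
#' @param table A `region_signal_table` from [region_signal()].
#' @param flank_min_log2 Minimal downstream log2 change (default 1.5).
#' @param body_max_log2 Maximal gene-body log2 change (default 0.5).
#' @return The selected subset of `table`.
#' @export
select_flank_stabilized_tus <- function(table, flank_min_log2 = 1.5,
                                        body_max_log2 = 0.5) {
  if (!inherits(table, "region_signal_table")) {
    abort("`table` must be a region_signal_table")
  }
  filter(as_tibble(table), .data$down_log2fc >= flank_min_log2,
         .data$body_log2fc <= body_max_log2)
}

#' Strand-aware region windows around TUs
#'
#' `downstream_regions()` returns the `window` bases 3' of each TU's TES in
#' sense orientation (the post-PAS flank when restricted to PAS-bearing
#' TUs); `filter_calls()` subsets a call set (or any positional tibble) to
#' positions falling inside a region tibble, strand-aware.
#'
#' @param tus Annotation tibble.
#' @param window Window size in bases.
#' @return Tibble `tu_id`, `chrom`, `start`, `end`, `strand`.
#' @export
downstream_regions <- function(tus, window = 3000L) {
  reg <- tu_regions(tus, window)
  tibble(tu_id = reg$tu_id, chrom = reg$chrom, start = reg$down_start,
         end = reg$down_end, strand = reg$strand)
}

#' @rdname downstream_regions
#' @param calls Tibble with `chrom`, `pos`, `strand`.
#' @param regions Region tibble with `chrom`, `start`, `end`, `strand`.
#' @export
filter_calls <- function(calls, regions) {
  tb <- as_tibble(calls)
  keep <- rep(FALSE, nrow(tb))
  for (i in seq_len(nrow(regions))) {
    keep <- keep | (tb$chrom == regions$chrom[i] &
                      tb$strand == regions$strand[i] &
                      tb$pos >= regions$start[i] & tb$pos < regions$end[i])
  }
  out <- tb[keep, , drop = FALSE]
  attributes(out) <- c(attributes(out),
                       attributes(calls)[c("min_log2", "min_count",
                                           "pseudocount", "treatment",
                                           "control")])
  class(out) <- class(calls)
  out
}

#' Positional concordance between two end call sets
#'
#' Directional percentage of positions in `a` having a same-strand position
#' in `b` within `tolerance` bases, the reverse direction, and their mean
#' (the symmetric variant). `mode = "binned"` instead compares positions
#' after binning at width `max(tolerance, 1)`.
#'
#' @param a,b `end_call_set` tibbles (any tibble with `chrom`, `pos`,
#'   `strand` works).
#' @param tolerance Non-negative tolerance in bases (default 0: exact
#'   position).
#' @param mode `"window"` (±tolerance) or `"binned"`.
#' @return One-row tibble: `a_to_b_pct`, `b_to_a_pct`, `symmetric_pct`,
#'   `n_a`, `n_b`, `tolerance`, `mode`.
#' @export
end_position_concordance <- function(a, b, tolerance = 0,
                                     mode = c("window", "binned")) {
  mode <- arg_match(mode)
  if (tolerance < 0) abort("`tolerance` must be >= 0")
  a <- distinct(as_tibble(a), .data$chrom, .data$pos, .data$strand)
  b <- distinct(as_tibble(b), .data$chrom, .data$pos, .data$strand)
  if (!nrow(a) || !nrow(b)) abort("both call sets must be non-empty")
  directional <- function(x, y) {
    if (mode == "binned") {
      w <- max(tolerance, 1)
      xk <- paste(x$chrom, x$strand, floor(x$pos / w))
      yk <- paste(y$chrom, y$strand, floor(y$pos / w))
      return(100 * mean(xk %in% yk))
    }
    hits <- map_lgl(seq_len(nrow(x)), function(i) {
      cand <- y$pos[y$chrom == x$chrom[i] & y$strand == x$strand[i]]
      length(cand) && min(abs(cand - x$pos[i])) <= tolerance
    })
    100 * mean(hits)
  }
  ab <- directional(a, b)
  ba <- directional(b, a)
  tibble(a_to_b_pct = ab, b_to_a_pct = ba, symmetric_pct = (ab + ba) / 2,
         n_a = nrow(a), n_b = nrow(b), tolerance = tolerance, mode = mode)
}

#' Correlation of body and downstream fold changes
#'
#' Pearson correlation across TUs of the gene-body log2 change against the
#' downstream log2 change. Near 1 when a depletion scales transcription of
#' body and downstream regions together (a flux increase, as under
#' Integrator loss) rather than shifting signal into the flank.
#'
#' @param table A `region_signal_table`.
#' @return Single numeric correlation coefficient.
#' @export
body_downstream_fc_correlation <- function(table) {
  if (!inherits(table, "region_signal_table")) {
    abort("`table` must be a region_signal_table")
  }
  if (nrow(table) < 3) abort("need at least 3 TUs for a correlation")
  cor(table$body_log2fc, table$down_log2fc, method = "pearson")
}

#' Last position of detectable transcription downstream of a TES
#'
#' Operationalises the transcription "end" as the most 3' position within
#' `max_extension` bases past the TES whose smoothed CPM (running mean over
#' `smooth_width` bases) exceeds `floor_cpm`.
#'
#' @param profile An [end_profile()] (typically a depletion sample).
#' @param tus Annotation tibble.
#' @param max_extension Search window past the TES in bases.
#' @param smooth_width Running-mean width in bases (odd).
#' @param floor_cpm Detection floor in CPM.
#' @return Tibble `tu_id`, `end_pos` (NA when nothing exceeds the floor).
#' @export
detect_transcription_end <- function(profile, tus, max_extension = 10000,
                                     smooth_width = 21, floor_cpm = 0.1) {
  cpm <- normalize_cpm(profile)
  reg <- tu_regions(tus, max_extension)
  out <- map(seq_len(nrow(reg)), function(i) {
    r <- reg[i, ]
    w <- seq.int(r$down_start, r$down_end - 1L)
    v <- numeric(length(w))
    hit <- cpm$chrom == r$chrom & cpm$strand == r$strand &
      cpm$pos >= r$down_start & cpm$pos < r$down_end
    v[cpm$pos[hit] - r$down_start + 1L] <- cpm$cpm[hit]
    sm <- as.numeric(stats::filter(v, rep(1 / smooth_width, smooth_width),
                                   sides = 2))
    ok <- which(!is.na(sm) & sm > floor_cpm)
    end_pos <- if (!length(ok)) NA_integer_ else if (r$strand == "+") {
      w[max(ok)]
    } else {
      w[min(ok)]
    }
    tibble(tu_id = r$tu_id, end_pos = end_pos)
  })
  list_rbind(out)
}
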