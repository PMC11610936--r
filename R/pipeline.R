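# End-to-end orchestration: simulate -> analyze -> compare.

stage_log <- function(stage, obj) {
  message(sprintf("[ttract] %s (hash %s)", stage,
                  substr(rlang::hash(obj), 1, 8)))
}

#' Simulate a fixture bundle to disk
#'
#' Convenience wrapper: build the default (or supplied) configuration,
#' simulate all requested samples, and write an analysis-ready bundle.
#'
#' @param out_dir Output directory for the bundle.
#' @param config A [sim_config()]; the default mixed reference panel when
#'   `NULL`.
#' @param conditions,flavors,epap,depth Passed to [simulate_bundle()].
#' @param seed Seed used when building the default config (ignored when
#'   `config` is supplied).
#' @param overwrite Passed to [write_fixture_bundle()].
#' @return Path of the written manifest, invisibly.
#' @export
run_simulate <- function(out_dir, config = NULL,
                         conditions = c("CTRL", "dEXOSC3"),
                         flavors = "three_prime", epap = TRUE, depth = 1L,
                         seed = 1L, overwrite = FALSE) {
  if (is.null(config)) {
    config <- sim_config(tu_panel_default(), seed = seed)
  }
  bundle <- simulate_bundle(config, conditions = conditions,
                            flavors = flavors, epap = epap, depth = depth)
  stage_log("simulate", bundle$samples)
  man <- write_fixture_bundle(bundle, out_dir, overwrite = overwrite)
  invisible(man)
}

#' Analysis thresholds and windows
#'
#' Bundles every tunable of [run_analyze()]: the stabilised-end calling
#' thresholds (`min_log2`, `min_count`, `pseudocount`), the region windows
#' (`downstream_window` for body/flank aggregation, `search_downstream` for
#' T-run and terminal-motif search past the TES), the TU selection
#' thresholds (`flank_min_log2`, `body_max_log2`), the k-mer length `k`,
#' the minimal T-run length `min_run`, the TSS distance `bins` (kb), and
#' the meta-curve geometry (`flank`, `body_bins`).
#'
#' @param min_log2,min_count,pseudocount See [call_stabilized_ends()].
#' @param downstream_window,flank_min_log2,body_max_log2 See
#'   [region_signal()] and [select_flank_stabilized_tus()].
#' @param k,min_run,search_downstream,bins,flank,body_bins See
#'   [count_terminal_kmers()], [find_t_runs()], [motif_distance_bins()],
#'   [fc_over_motifs()] and [scaled_metaprofile()].
#' @return Named list of parameters.
#' @export
analysis_params <- function(min_log2 = 1.0, min_count = 1L, pseudocount = 1,
                            downstream_window = 3000L,
                            flank_min_log2 = 1.5, body_max_log2 = 0.5,
                            k = 6L, min_run = 6L, search_downstream = 5000L,
                            bins = list(c(0, 1), c(1, 2), c(2, 3), c(3, 4)),
                            flank = 10L, body_bins = 100L) {
  list(min_log2 = min_log2, min_count = min_count, pseudocount = pseudocount,
       downstream_window = downstream_window,
       flank_min_log2 = flank_min_log2, body_max_log2 = body_max_log2,
       k = k, min_run = min_run, search_downstream = search_downstream,
       bins = bins, flank = flank, body_bins = body_bins)
}

#' Analyze a sample bundle into a report directory
#'
#' Runs the full analysis for every depletion/control pair in the manifest:
#' per-base log2 fold-change track, stabilised-end calling, terminal-hexamer
#' table, background-corrected terminal T fraction, T-run location and
#' distance-binned fold-change meta-curves, body/downstream region signal
#' with the flank-stabilised TU selection, scaled metaprofile mean curves,
#' and pairwise call-set concordance. Every stage writes a TSV; a
#' machine-readable `run_summary.json` records all thresholds, the
#' pseudocount, the genome hash and the package version. Reruns on identical
#' inputs produce byte-identical TSVs.
#'
#' @param manifest Path to a manifest YAML (see [load_manifest()]).
#' @param out_dir Report directory (created; must be empty unless
#'   `overwrite`).
#' @param params A list from [analysis_params()].
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with the per-pair results and the summary.
#' @export
run_analyze <- function(manifest, out_dir, params = analysis_params(),
                        overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    abort(sprintf("out_dir %s exists and is not empty (set overwrite = TRUE)",
                  out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ss <- load_manifest(manifest)
  stage_log("load", ss$samples)
  pairs <- ss$samples[!is.na(ss$samples$control), ]
  if (!nrow(pairs)) abort("no depletion pairs in manifest")

  write_stage <- function(tb, name) {
    readr::write_tsv(as_tibble(tb), file.path(out_dir, name),
                     progress = FALSE)
  }

  results <- list()
  call_sets <- list()
  for (i in seq_len(nrow(pairs))) {
    s <- pairs[i, ]
    trt <- ss$profiles[[s$sample_id]]
    ctl <- ss$profiles[[s$control]]
    tag <- s$sample_id

    fc <- log2_ratio_track(trt, ctl, pseudocount = params$pseudocount)
    stage_log(paste0("fc:", tag), fc)
    write_stage(fc, sprintf("fc_%s.tsv", tag))

    calls <- call_stabilized_ends(trt, ctl, min_log2 = params$min_log2,
                                  min_count = params$min_count,
                                  pseudocount = params$pseudocount)
    stage_log(paste0("calls:", tag), calls)
    write_stage(calls, sprintf("calls_%s.tsv", tag))
    call_sets[[tag]] <- calls

    kt <- count_terminal_kmers(calls, ss$seq, k = params$k)
    write_stage(kt, sprintf("kmers_%s.tsv", tag))

    tfr <- tryCatch(
      t_fraction_statistic(calls, ss$seq, search_regions(
        ss$tus, params$search_downstream)),
      error = function(e) tibble(end_t_fraction = NA_real_,
                                 genomic_t_fraction = NA_real_,
                                 diff = NA_real_, se_diff = NA_real_,
                                 z = NA_real_, n_ends = 0L, n_bases = 0L)
    )
    write_stage(tfr, sprintf("tfraction_%s.tsv", tag))

    runs <- find_t_runs(ss$seq, ss$tus, min_run = params$min_run,
                        downstream_bp = params$search_downstream)
    binned <- motif_distance_bins(runs, bins = params$bins)
    curve <- fc_over_motifs(fc, binned, flank = params$flank)
    write_stage(curve, sprintf("motif_meta_%s.tsv", tag))

    regions <- region_signal(trt, ctl, ss$tus,
                             downstream_window = params$downstream_window,
                             pseudocount = params$pseudocount)
    write_stage(regions, sprintf("regions_%s.tsv", tag))
    selected <- select_flank_stabilized_tus(
      regions, flank_min_log2 = params$flank_min_log2,
      body_max_log2 = params$body_max_log2)
    write_stage(selected, sprintf("selected_tus_%s.tsv", tag))

    meta <- scaled_metaprofile(fc, ss$tus, upstream_bp = 200L,
                               body_bins = params$body_bins,
                               downstream_bp = params$downstream_window)
    write_stage(
      tibble(metapos = meta$axis$metapos, segment = meta$axis$segment,
             mean_value = colMeans(meta$matrix)),
      sprintf("metaprofile_%s.tsv", tag)
    )

    results[[tag]] <- list(fc = fc, calls = calls, kmers = kt,
                           t_fraction = tfr, motif_meta = curve,
                           regions = regions, selected = selected)
  }

  if (length(call_sets) >= 1) {
    cc <- list()
    nms <- names(call_sets)
    for (a in nms) for (b in nms) {
      cc[[length(cc) + 1L]] <- end_position_concordance(
        call_sets[[a]], call_sets[[b]]) |>
        mutate(set_a = a, set_b = b, .before = 1)
    }
    write_stage(list_rbind(cc), "concordance.tsv")
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("ttract")),
    genome_hash = rlang::hash(ss$seq),
    n_samples = nrow(ss$samples), n_pairs = nrow(pairs),
    params = params[setdiff(names(params), "bins")],
    bins = map(params$bins, as.numeric)
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, summary = summary, sample_set = ss))
}

# TU search windows [TSS, TES + downstream) in reference coordinates.
search_regions <- function(tus, downstream_bp) {
  tibble(
    tu_id = tus$tu_id, chrom = tus$chrom,
    start = ifelse(tus$strand == "+", tus$start,
                   pmax(tus$start - downstream_bp, 0L)),
    end = ifelse(tus$strand == "+", tus$end + downstream_bp, tus$end),
    strand = tus$strand
  )
}

#' Compare call sets of two report directories
#'
#' Pairwise positional concordance between the stabilised-end call sets of
#' two [run_analyze()] reports. Reports generated against different genomes
#' (by hash) are rejected.
#'
#' @param report_a,report_b Report directories.
#' @param tolerance Concordance tolerance in bases.
#' @return Tibble of pairwise concordance rows.
#' @export
run_compare <- function(report_a, report_b, tolerance = 0) {
  read_report <- function(dir) {
    sj <- file.path(dir, "run_summary.json")
    if (!file.exists(sj)) abort(sprintf("%s is not a report directory", dir))
    summ <- jsonlite::read_json(sj)
    files <- list.files(dir, pattern = "^calls_.*\\.tsv$", full.names = TRUE)
    calls <- setNames(
      map(files, readr::read_tsv, col_types = readr::cols(),
          progress = FALSE),
      sub("^calls_(.*)\\.tsv$", "\\1", basename(files))
    )
    list(summary = summ, calls = calls)
  }
  a <- read_report(report_a)
  b <- read_report(report_b)
  if (!identical(a$summary$genome_hash, b$summary$genome_hash)) {
    abort("reports were generated against different genomes")
  }
  out <- list()
  for (na in names(a$calls)) for (nb in names(b$calls)) {
    out[[length(out) + 1L]] <- end_position_concordance(
      a$calls[[na]], b$calls[[nb]], tolerance = tolerance) |>
      mutate(set_a = na, set_b = nb, .before = 1)
  }
  list_rbind(out)
}
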