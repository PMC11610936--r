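#' Simulate a complete multi-condition experiment
#'
#' Builds the genome once, simulates polymerases per condition (each
#' condition on its own derived random stream), and renders one profile per
#' (condition, flavor, EPAP) combination. Adding a sample does not perturb
#' the streams of existing samples.
#'
#' @param config A [sim_config()].
#' @param conditions Conditions to simulate.
#' @param flavors Assay flavors to render per condition.
#' @param epap Logical vector of EPAP states for `three_prime` profiles
#'   (other flavors are rendered without EPAP).
#' @param depth Depth multiplier passed to [render_end_profile()].
#' @return A `sim_bundle`: list with `genome`, `truths` (named by
#'   condition), `profiles` (named list of [end_profile()]s) and `samples`
#'   (plan tibble with control linkage).
#' @export
simulate_bundle <- function(config,
                            conditions = c("CTRL", "dEXOSC3"),
                            flavors = "three_prime",
                            epap = TRUE,
                            depth = 1L) {
  genome <- build_synthetic_genome(config)
  truths <- setNames(
    map(seq_along(conditions), function(i) {
      simulate_polymerases(genome, conditions[i],
                           seed = config$seed + 1000L * match(conditions[i],
                                                              CONDITIONS))
    }),
    conditions
  )
  plan <- list()
  for (cond in conditions) {
    for (fl in flavors) {
      ep_states <- if (fl == "three_prime") unique(epap) else FALSE
      for (ep in ep_states) {
        plan[[length(plan) + 1L]] <- tibble(
          condition = cond, flavor = fl, epap = ep,
          sample_id = sprintf("%s_%s_%s", cond, fl,
                              if (ep) "plusEPAP" else "minusEPAP")
        )
      }
    }
  }
  plan <- list_rbind(plan)
  profiles <- setNames(
    map(seq_len(nrow(plan)), function(i) {
      cond <- plan$condition[i]
      render_end_profile(
        truths[[cond]], flavor = plan$flavor[i], epap = plan$epap[i],
        depth = depth,
        seed = config$seed + 1000L * match(cond, CONDITIONS) +
          10L * match(plan$flavor[i], c("three_prime", "five_prime",
                                        "active_site")) +
          as.integer(plan$epap[i]) + 1L,
        sample_id = plan$sample_id[i]
      )
    }),
    plan$sample_id
  )
  # Control linkage: the CTRL sample of matching flavor and EPAP status.
  plan$control <- map_chr(seq_len(nrow(plan)), function(i) {
    if (plan$condition[i] == "CTRL") return(NA_character_)
    hit <- plan$sample_id[plan$condition == "CTRL" &
                            plan$flavor == plan$flavor[i] &
                            plan$epap == plan$epap[i]]
    if (length(hit)) hit[1] else NA_character_
  })
  structure(
    list(genome = genome, truths = truths, profiles = profiles,
         samples = plan),
    class = "sim_bundle"
  )
}

#' Write a simulated experiment to disk as analysis-ready fixtures
#'
#' Writes the genome FASTA, the BED6+2 annotation, per-sample stranded
#' bedGraph pairs, the planted-element registry, per-condition ground-truth
#' event tables and a YAML manifest that [load_manifest()] reads back
#' bit-exactly.
#'
#' @param bundle A `sim_bundle` from [simulate_bundle()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return The manifest path, invisibly.
#' @export
write_fixture_bundle <- function(bundle, out_dir, overwrite = FALSE) {
  if (!inherits(bundle, "sim_bundle")) {
    abort("`bundle` must be a sim_bundle")
  }
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    abort(sprintf("out_dir %s exists and is not empty (set overwrite = TRUE)",
                  out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$genome$seq, file.path(out_dir, "genome.fa"))
  write_annotation(bundle$genome$tus, file.path(out_dir, "annotation.bed"))
  readr::write_tsv(bundle$genome$registry,
                   file.path(out_dir, "registry.tsv"), progress = FALSE)
  for (cond in names(bundle$truths)) {
    readr::write_tsv(bundle$truths[[cond]]$events,
                     file.path(out_dir, sprintf("ground_truth_%s.tsv", cond)),
                     progress = FALSE)
  }
  man_samples <- list()
  for (i in seq_len(nrow(bundle$samples))) {
    s <- bundle$samples[i, ]
    plus <- sprintf("%s.plus.bedgraph", s$sample_id)
    minus <- sprintf("%s.minus.bedgraph", s$sample_id)
    write_bedgraph_pair(bundle$profiles[[s$sample_id]],
                        file.path(out_dir, plus), file.path(out_dir, minus))
    man_samples[[i]] <- list(
      sample_id = s$sample_id, condition = s$condition, flavor = s$flavor,
      epap = s$epap, plus = plus, minus = minus,
      control = if (is.na(s$control)) NULL else s$control
    )
  }
  manifest <- list(genome = "genome.fa", annotation = "annotation.bed",
                   samples = man_samples)
  man_path <- file.path(out_dir, "manifest.yml")
  yaml::write_yaml(manifest, man_path)
  invisible(man_path)
}
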