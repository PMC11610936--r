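# Shared fixtures. Heavy simulations are built once per session and cached.

the_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = the_cache)) {
    assign(key, fn(), envir = the_cache)
  }
  get(key, envir = the_cache)
}

# Reference study conditions: mixed panel, planted T6 terminators,
# p_term_per_t = 0.15, exosome_survival = 0.2.
default_world <- function() {
  cached("default_world", function() {
    cfg <- sim_config(tu_panel_default(), seed = 1)
    genome <- build_synthetic_genome(cfg)
    truth_ctrl <- simulate_polymerases(genome, "CTRL")
    truth_exo <- simulate_polymerases(genome, "dEXOSC3", seed = 2001)
    truth_xrn <- simulate_polymerases(genome, "dXRN2", seed = 3001)
    list(
      cfg = cfg, genome = genome,
      truth_ctrl = truth_ctrl, truth_exo = truth_exo, truth_xrn = truth_xrn,
      ctrl_3p = render_end_profile(truth_ctrl, "three_prime", epap = TRUE),
      exo_3p = render_end_profile(truth_exo, "three_prime", epap = TRUE),
      ctrl_as = render_end_profile(truth_ctrl, "active_site", epap = FALSE),
      xrn_as = render_end_profile(truth_xrn, "active_site", epap = FALSE)
    )
  })
}

# Matched null: identical panel and seeds, DNA-directed termination off.
null_world <- function() {
  cached("null_world", function() {
    cfg <- sim_config(tu_panel_default(), p_term_per_t = 0, seed = 1)
    genome <- build_synthetic_genome(cfg)
    truth_ctrl <- simulate_polymerases(genome, "CTRL")
    truth_exo <- simulate_polymerases(genome, "dEXOSC3", seed = 2001)
    list(
      cfg = cfg, genome = genome,
      ctrl_3p = render_end_profile(truth_ctrl, "three_prime", epap = TRUE),
      exo_3p = render_end_profile(truth_exo, "three_prime", epap = TRUE)
    )
  })
}

# Distance panel: maturation_halfdist 1 kb, one T6 tract per kb bin,
# >= 5000 polymerases in total.
distance_world <- function() {
  cached("distance_world", function() {
    cfg <- sim_config(tu_panel_distance(), n_polymerases_per_tu = 120L,
                      maturation_halfdist = 1000, seed = 1)
    genome <- build_synthetic_genome(cfg)
    truth_ctrl <- simulate_polymerases(genome, "CTRL")
    truth_exo <- simulate_polymerases(genome, "dEXOSC3", seed = 2001)
    list(
      cfg = cfg, genome = genome, truth_exo = truth_exo,
      ctrl_3p = render_end_profile(truth_ctrl, "three_prime", epap = TRUE),
      exo_3p = render_end_profile(truth_exo, "three_prime", epap = TRUE)
    )
  })
}

# A profile with a chosen library size: counts at given positions plus one
# filler position on an unused contig to pad the library.
make_profile <- function(pos, count, strand = "+", chrom = "chr1",
                         library_size = NULL, flavor = "three_prime",
                         epap = TRUE, sample_id = "s",
                         condition = NA_character_) {
  tb <- tibble::tibble(chrom = chrom, pos = pos, strand = strand,
                       count = count)
  if (!is.null(library_size)) {
    pad <- library_size - sum(count)
    stopifnot(pad >= 0)
    if (pad > 0) {
      tb <- dplyr::bind_rows(tb, tibble::tibble(
        chrom = "chrPAD", pos = 0L, strand = "+", count = pad))
    }
  }
  end_profile(tb, flavor = flavor, epap = epap, sample_id = sample_id,
              condition = condition)
}

# Minimal hand-built ground truth for detection-model unit tests.
make_truth <- function(rna_ends, condition, config,
                       events = NULL, five_ends = NULL,
                       pause_visits = NULL, seed = 7L) {
  empty_events <- tibble::tibble(
    tu_id = character(), polymerase = integer(), mechanism = character(),
    chrom = character(), pos = integer(), sense_offset = integer(),
    strand = character(), released = logical(), cleaved_pas = logical())
  structure(
    list(
      events = if (is.null(events)) empty_events else events,
      rna_ends = rna_ends,
      five_ends = if (is.null(five_ends)) tibble::tibble(
        tu_id = character(), chrom = character(), pos = integer(),
        strand = character(), kind = character(), n_rna = integer())
        else five_ends,
      pause_visits = if (is.null(pause_visits)) tibble::tibble(
        tu_id = character(), chrom = character(), pos = integer(),
        strand = character(), weight = integer()) else pause_visits,
      condition = condition, seed = seed, config = config, chrom = "chr1"
    ),
    class = "ground_truth"
  )
}

tiny_config <- function(..., intergenic_gap = 500L,
                        runoff_extension = 2000L) {
  sim_config(list(tu_spec("mono_nc", 800, planted_terminators =
    tibble::tibble(offset = 400L, run_length = 6L))),
    intergenic_gap = intergenic_gap,
    runoff_extension = runoff_extension, ...)
}

# Attribute-free view of a profile/track for byte-level comparisons.
plain <- function(p) {
  tibble::tibble(chrom = p$chrom, pos = p$pos, strand = p$strand,
                 count = p$count)
}
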