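# Simulation configuration: the study conditions for the synthetic data.
#
# The generative model is a quantitative rendering of the qualitative
# mechanism the analysis is designed to detect: RNAPII initiates at a TU's
# TSS, may be attenuated promoter-proximally by Integrator, walks 5'->3'
# and, at every coding-strand T-run of length L at sense distance d from
# the TSS, terminates with probability
#     1 - (1 - p_term_per_t * 2^(-d / maturation_halfdist))^L,
# i.e. a per-T hazard that decays as the elongation complex matures.
# Cleavage at a PAS (probability `pas_strength`) arms the XRN2 torpedo,
# which chases the polymerase over a geometric distance and terminates it,
# snapping to planted G-rich pause sites. snRNA-like TUs are cleaved at a
# 3' box just past the TES without terminating transcription.

#' Describe one transcription unit for the simulator
#'
#' @param biotype One of `"snRNA_like"`, `"mono_nc"`, `"multiexonic_long"`,
#'   `"short_coding"`, `"rdh_like"`.
#' @param body_length Gene body length in bases (TSS to TES).
#' @param strand `"+"` or `"-"`.
#' @param start 0-based reference start of the body interval `[start,
#'   start + body_length)`. On the minus strand the TSS is the last base of
#'   that interval.
#' @param exon_count Number of exons (>= 1); `1` marks the TU monoexonic.
#' @param has_three_prime_box Whether an Integrator-cleaved 3' box sits just
#'   downstream of the TES (snRNA-like processing).
#' @param pas_strength Probability in `[0, 1]` that the polyadenylation site
#'   at the TES is cleaved, arming the torpedo.
#' @param planted_terminators Data frame (or NULL) with columns `offset`
#'   (sense distance of the first T from the TSS, bases) and `run_length`
#'   (number of Ts, >= 4); written onto the coding strand at genome build.
#' @param planted_pause_sites Integer vector of sense distances downstream of
#'   the TES at which a G-rich pause element is planted.
#' @param tu_id Optional identifier; assigned by the panel builder otherwise.
#' @return A `tu_spec` list.
#' @export
tu_spec <- function(biotype, body_length, strand = "+", start = NA_integer_,
                    exon_count = 1L, has_three_prime_box = FALSE,
                    pas_strength = 0, planted_terminators = NULL,
                    planted_pause_sites = integer(), tu_id = NA_character_) {
  biotypes <- c("snRNA_like", "mono_nc", "multiexonic_long", "short_coding",
                "rdh_like")
  if (!is.character(biotype) || length(biotype) != 1L ||
      !biotype %in% biotypes) {
    abort(sprintf("unknown biotype %s; must be one of %s",
                  deparse(biotype), paste(biotypes, collapse = ", ")))
  }
  check_strand(strand)
  if (!is.numeric(body_length) || body_length < 1) {
    abort("`body_length` must be a positive number of bases")
  }
  if (!is.numeric(exon_count) || exon_count < 1) {
    abort("`exon_count` must be an integer >= 1")
  }
  stopifnot_scalar_prob(pas_strength, "pas_strength")
  if (is.null(planted_terminators)) {
    planted_terminators <- tibble(offset = integer(), run_length = integer())
  }
  planted_terminators <- as_tibble(planted_terminators)
  if (!all(c("offset", "run_length") %in% names(planted_terminators))) {
    abort("`planted_terminators` needs columns `offset` and `run_length`")
  }
  if (any(planted_terminators$run_length < 4)) {
    abort("terminator run_length must be >= 4 (minimal functional T-tract)")
  }
  structure(
    list(
      tu_id = tu_id,
      biotype = biotype,
      body_length = as.integer(body_length),
      strand = strand,
      start = as.integer(start),
      exon_count = as.integer(exon_count),
      has_three_prime_box = isTRUE(has_three_prime_box),
      pas_strength = pas_strength,
      planted_terminators = planted_terminators,
      planted_pause_sites = as.integer(planted_pause_sites)
    ),
    class = "tu_spec"
  )
}

#' Simulation configuration
#'
#' Bundles the genome layout and all stochastic parameters of the nascent
#' transcription/termination simulator. Defaults are the package's reference
#' study conditions; see the methods vignette for the rationale behind each
#' value.
#'
#' @param tu_specs List of [tu_spec()] objects. TUs with `start = NA` are laid
#'   out left to right with `intergenic_gap` bases between footprints.
#' @param genome_length Total genome length in bases; computed from the layout
#'   when `NULL`.
#' @param base_composition Named probabilities over A, C, G, T (sum 1) for the
#'   random background sequence.
#' @param n_polymerases_per_tu Polymerases initiated per TU per condition.
#' @param p_term_per_t Per-T termination probability at sense distance 0.
#' @param maturation_halfdist Distance (bases) over which the per-T hazard
#'   halves as the elongation complex matures.
#' @param torpedo_mean_dist Mean (bases) of the geometric chase distance of
#'   the XRN2 torpedo beyond a cleaved PAS.
#' @param attenuation_p Probability that an initiated polymerase is terminated
#'   promoter-proximally by Integrator attenuation (0 under `dINT`).
#' @param attenuation_mean_dist Mean sense distance (bases) from the TSS of
#'   attenuation release points (geometric).
#' @param attenuation_max_dist Upper bound (bases) on attenuation release
#'   points: Integrator targets polymerases paused within the
#'   promoter-proximal zone, so release positions are truncated here.
#' @param exosome_survival Detection probability of released nonadenylated 3'
#'   ends while the exosome is active (1 under `dEXOSC3`).
#' @param pas5_survival Detection probability of PAS cleavage-product 5' ends
#'   while XRN2 is active (the torpedo degrades them; 1 under `dXRN2`).
#' @param min_run Minimal T-run length (>= 4) at which the termination hazard
#'   applies; runs are read from the realised sequence, planted or not.
#' @param box_offset Sense distance (bases) from the TES of the 3'-box
#'   cleavage site on snRNA-like TUs.
#' @param box_cleavage_p Probability of cotranscriptional 3'-box cleavage
#'   (0 under `dINT`).
#' @param pause_seq G-rich element written at planted pause sites.
#' @param pause_snap_window Torpedo termination positions within this many
#'   bases of a planted pause site snap to it.
#' @param pause_dwell_trapped Relative active-site dwell weight at pause sites
#'   crossed by a PAS-cleaved polymerase when XRN2 is absent ("sitting duck").
#' @param runoff_extension Hard runoff cap: polymerases that never terminate
#'   stop `runoff_extension` bases past the TES.
#' @param intergenic_gap Gap between consecutive TU footprints in the default
#'   layout.
#' @param seed Integer seed; every simulation routine derives its stream from
#'   it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(tu_specs,
                       genome_length = NULL,
                       base_composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                       n_polymerases_per_tu = 300L,
                       p_term_per_t = 0.15,
                       maturation_halfdist = 1000,
                       torpedo_mean_dist = 300,
                       attenuation_p = 0.3,
                       attenuation_mean_dist = 150,
                       attenuation_max_dist = 250L,
                       exosome_survival = 0.2,
                       pas5_survival = 0.2,
                       min_run = 4L,
                       box_offset = 12L,
                       box_cleavage_p = 0.9,
                       pause_seq = "GGGAGGGGGG",
                       pause_snap_window = 100L,
                       pause_dwell_trapped = 8L,
                       runoff_extension = 5000L,
                       intergenic_gap = 6000L,
                       seed = 1L) {
  if (!is.list(tu_specs) || !length(tu_specs) ||
      !all(map_lgl(tu_specs, inherits, "tu_spec"))) {
    abort("`tu_specs` must be a non-empty list of tu_spec objects")
  }
  cfg <- structure(
    list(
      tu_specs = tu_specs,
      genome_length = genome_length,
      base_composition = base_composition,
      n_polymerases_per_tu = as.integer(n_polymerases_per_tu),
      p_term_per_t = p_term_per_t,
      maturation_halfdist = maturation_halfdist,
      torpedo_mean_dist = torpedo_mean_dist,
      attenuation_p = attenuation_p,
      attenuation_mean_dist = attenuation_mean_dist,
      attenuation_max_dist = as.integer(attenuation_max_dist),
      exosome_survival = exosome_survival,
      pas5_survival = pas5_survival,
      min_run = as.integer(min_run),
      box_offset = as.integer(box_offset),
      box_cleavage_p = box_cleavage_p,
      pause_seq = toupper(pause_seq),
      pause_snap_window = as.integer(pause_snap_window),
      pause_dwell_trapped = as.integer(pause_dwell_trapped),
      runoff_extension = as.integer(runoff_extension),
      intergenic_gap = as.integer(intergenic_gap),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  cfg <- layout_tus(cfg)
  validate_sim_config(cfg)
}

# Assign genomic starts to TUs lacking one, and derive genome_length.
layout_tus <- function(cfg) {
  cursor <- cfg$intergenic_gap
  for (i in seq_along(cfg$tu_specs)) {
    spec <- cfg$tu_specs[[i]]
    if (is.na(spec$tu_id)) {
      spec$tu_id <- sprintf("TU%03d", i)
    }
    # Footprint: body plus runoff extension on the sense side plus a small
    # upstream margin, measured on the reference.
    foot <- spec$body_length + cfg$runoff_extension
    if (is.na(spec$start)) {
      spec$start <- if (spec$strand == "+") cursor else cursor + cfg$runoff_extension
      cursor <- cursor + foot + cfg$intergenic_gap
    } else {
      cursor <- max(cursor, spec$start + foot + cfg$intergenic_gap)
    }
    cfg$tu_specs[[i]] <- spec
  }
  if (is.null(cfg$genome_length)) {
    cfg$genome_length <- as.integer(cursor)
  }
  cfg$genome_length <- as.integer(cfg$genome_length)
  cfg
}

#' @rdname sim_config
#' @param cfg A `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  bc <- cfg$base_composition
  if (is.null(names(bc)) || !setequal(names(bc), DNA_BASES)) {
    abort("`base_composition` must be named over A, C, G, T")
  }
  if (abs(sum(bc) - 1) > 1e-9) {
    abort("`base_composition` must sum to 1 (tolerance 1e-9)")
  }
  for (nm in c("p_term_per_t", "attenuation_p", "exosome_survival",
               "pas5_survival", "box_cleavage_p")) {
    stopifnot_scalar_prob(cfg[[nm]], nm)
  }
  if (any(bc < 0 | bc > 1)) abort("base composition entries must be in [0, 1]")
  if (cfg$maturation_halfdist <= 0) abort("`maturation_halfdist` must be > 0")
  if (cfg$torpedo_mean_dist <= 0) abort("`torpedo_mean_dist` must be > 0")
  if (cfg$min_run < 4) abort("`min_run` must be >= 4")
  for (spec in cfg$tu_specs) {
    sense_max <- spec$body_length + cfg$runoff_extension
    offs <- spec$planted_terminators$offset
    ends <- offs + spec$planted_terminators$run_length
    pause_ends <- spec$body_length + spec$planted_pause_sites +
      nchar(cfg$pause_seq)
    if (any(ends > sense_max) || any(pause_ends > sense_max)) {
      abort(sprintf("TU %s: planted element extends beyond its runoff window",
                    spec$tu_id))
    }
    lo <- offset_to_pos(spec$start, spec$start + spec$body_length,
                        spec$strand, c(0L, sense_max - 1L))
    if (min(lo) < 0 || max(lo) >= cfg$genome_length) {
      abort(sprintf("TU %s: footprint outside genome bounds", spec$tu_id))
    }
  }
  total_foot <- sum(map_dbl(cfg$tu_specs, function(s) {
    s$body_length + cfg$runoff_extension
  }))
  if (cfg$genome_length < total_foot) {
    abort("`genome_length` is smaller than the combined TU footprints")
  }
  cfg
}

#' Reference TU panels
#'
#' `tu_panel_default()` builds the package's mixed reference panel: snRNA-like
#' TUs with a 3' box and downstream T6 terminators, monoexonic noncoding TUs,
#' short protein-coding TUs with strong PASs and downstream G-rich pause
#' sites plus post-PAS T6 tracts, long multiexonic TUs with promoter-proximal
#' tracts only, and replication-dependent-histone-like short TUs.
#' `tu_panel_distance()` builds a uniform panel of long TUs carrying one T6
#' tract per kilobase bin at sense distances 500, 1500, 2500 and 3500 bases
#' from the TSS, for distance-dependence analyses.
#'
#' @param n_tu Number of TUs in the panel.
#' @return List of [tu_spec()] objects.
#' @export
tu_panel_default <- function(n_tu = 24L) {
  if (n_tu < 10L) abort("`n_tu` must be >= 10 for the mixed panel")
  classes <- rep(c("snRNA_like", "mono_nc", "short_coding",
                   "multiexonic_long", "rdh_like"), length.out = n_tu)
  strands <- rep(c("+", "-"), length.out = n_tu)
  specs <- vector("list", n_tu)
  for (i in seq_len(n_tu)) {
    specs[[i]] <- switch(
      classes[i],
      snRNA_like = tu_spec(
        "snRNA_like", body_length = 200, strand = strands[i],
        exon_count = 1L, has_three_prime_box = TRUE, pas_strength = 0,
        planted_terminators = tibble(offset = c(320L, 520L),
                                     run_length = c(6L, 6L))
      ),
      mono_nc = tu_spec(
        "mono_nc", body_length = 800, strand = strands[i], exon_count = 1L,
        planted_terminators = tibble(offset = c(400L, 950L),
                                     run_length = c(6L, 7L))
      ),
      short_coding = tu_spec(
        "short_coding", body_length = 2000, strand = strands[i],
        exon_count = 3L, pas_strength = 0.9,
        planted_terminators = tibble(offset = c(450L, 2350L),
                                     run_length = c(6L, 6L)),
        planted_pause_sites = c(600L, 1500L)
      ),
      multiexonic_long = tu_spec(
        "multiexonic_long", body_length = 4000, strand = strands[i],
        exon_count = 8L, pas_strength = 0.95,
        planted_terminators = tibble(offset = 600L, run_length = 6L),
        planted_pause_sites = 800L
      ),
      rdh_like = tu_spec(
        "rdh_like", body_length = 500, strand = strands[i], exon_count = 1L,
        planted_terminators = tibble(offset = c(650L, 900L),
                                     run_length = c(6L, 6L))
      )
    )
  }
  specs
}

#' @rdname tu_panel_default
#' @export
tu_panel_distance <- function(n_tu = 42L) {
  strands <- rep(c("+", "-"), length.out = n_tu)
  lapply(seq_len(n_tu), function(i) {
    tu_spec(
      "multiexonic_long", body_length = 4200, strand = strands[i],
      exon_count = 5L,
      planted_terminators = tibble(offset = c(500L, 1500L, 2500L, 3500L),
                                   run_length = rep(6L, 4))
    )
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d TUs, genome %d bp, %d polymerases/TU, seed %d\n",
    length(x$tu_specs), x$genome_length, x$n_polymerases_per_tu, x$seed
  ))
  cat(sprintf(
    "  p_term_per_t=%.3g halfdist=%g torpedo=%g atten=%.2g exo_survival=%.2g\n",
    x$p_term_per_t, x$maturation_halfdist, x$torpedo_mean_dist,
    x$attenuation_p, x$exosome_survival
  ))
  invisible(x)
}
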