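CONDITIONS <- c("CTRL", "dEXOSC3", "dXRN2", "dINT", "dINT_dEXOSC3")

condition_flags <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% CONDITIONS) {
    abort(sprintf("unknown condition %s; must be one of %s",
                  deparse(condition), paste(CONDITIONS, collapse = ", ")))
  }
  list(
    exosome_active = !condition %in% c("dEXOSC3", "dINT_dEXOSC3"),
    xrn2_active = condition != "dXRN2",
    int_active = !condition %in% c("dINT", "dINT_dEXOSC3")
  )
}

# Maximal T-runs of length >= min_run in a sense-oriented sequence.
# Returns a tibble of sense offsets (0-based, first T) and run lengths.
sense_t_runs <- function(sense_seq, min_run) {
  m <- gregexpr(sprintf("T{%d,}", min_run), sense_seq)[[1]]
  if (m[1] == -1L) {
    return(tibble(offset = integer(), run_length = integer()))
  }
  tibble(offset = as.integer(m) - 1L,
         run_length = as.integer(attr(m, "match.length")))
}

#' Simulate polymerase trajectories and termination events
#'
#' Walks `n_polymerases_per_tu` polymerases down every TU under one
#' experimental condition. Each polymerase may be attenuated
#' promoter-proximally (Integrator; off under `dINT`), terminates at each
#' coding-strand T-run of length L at sense distance d with probability
#' `1 - (1 - p_term_per_t * 2^(-d/maturation_halfdist))^L`, is cleaved at the
#' PAS with probability `pas_strength` (arming the XRN2 torpedo, whose
#' geometric chase distance snaps to planted pause sites; disabled under
#' `dXRN2`), is cleaved without terminating at the 3' box of snRNA-like TUs
#' (off under `dINT`), and otherwise runs off at `TES + runoff_extension`.
#'
#' @param genome A `synthetic_genome` from [build_synthetic_genome()].
#' @param condition One of `"CTRL"`, `"dEXOSC3"`, `"dXRN2"`, `"dINT"`,
#'   `"dINT_dEXOSC3"`. The condition controls the termination machinery here
#'   and the detection model in [render_end_profile()].
#' @param seed Integer seed for this simulation's private stream; defaults to
#'   the config seed.
#' @param n_polymerases Polymerases per TU; defaults to the config value.
#' @return A `ground_truth` object: list of tibbles `events` (one termination
#'   event per polymerase, with mechanism tag and released flag), `rna_ends`
#'   (every RNA 3' end with adenylation and exosome-substrate flags),
#'   `five_ends` (capped TSS and cleavage-product 5' ends) and `pause_visits`
#'   (dwell-weighted crossings of planted pause sites), plus the condition
#'   and config.
#' @export
simulate_polymerases <- function(genome, condition, seed = NULL,
                                 n_polymerases = NULL) {
  if (!inherits(genome, "synthetic_genome")) {
    abort("`genome` must be a synthetic_genome")
  }
  flags <- condition_flags(condition)
  cfg <- genome$config
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(n_polymerases)) n_polymerases <- cfg$n_polymerases_per_tu
  chrom <- names(genome$seq)[1]
  gseq <- genome$seq[[1]]

  atten_p <- if (flags$int_active) cfg$attenuation_p else 0
  box_p <- if (flags$int_active) cfg$box_cleavage_p else 0

  out <- withr::with_seed(seed, {
    res <- lapply(seq_len(nrow(genome$tus)), function(i) {
      tu <- genome$tus[i, ]
      spec <- cfg$tu_specs[[i]]
      simulate_one_tu(tu, spec, gseq, chrom, cfg, flags, atten_p, box_p,
                      n_polymerases)
    })
    list(
      events = list_rbind(map(res, "events")),
      rna_ends = list_rbind(map(res, "rna_ends")),
      five_ends = list_rbind(map(res, "five_ends")),
      pause_visits = list_rbind(map(res, "pause_visits"))
    )
  })

  structure(
    c(out, list(condition = condition, seed = as.integer(seed),
                config = cfg, chrom = chrom)),
    class = "ground_truth"
  )
}

simulate_one_tu <- function(tu, spec, gseq, chrom, cfg, flags, atten_p,
                            box_p, n) {
  body <- spec$body_length
  cap_off <- body + cfg$runoff_extension - 1L
  # Sense-oriented sequence over [TSS, TES + runoff).
  if (tu$strand == "+") {
    sense_seq <- seq_slice(gseq, tu$start, tu$start + cap_off + 1L)
  } else {
    sense_seq <- revcomp(seq_slice(gseq, tu$end - 1L - cap_off, tu$end))
  }
  runs <- sense_t_runs(sense_seq, cfg$min_run)
  runs <- runs[order(runs$offset), , drop = FALSE]

  stop_off <- rep(NA_integer_, n)
  mech <- rep(NA_character_, n)
  cleaved <- rep(FALSE, n)

  # Integrator attenuation: early release within the promoter-proximal zone.
  atten <- runif(n) < atten_p
  if (any(atten)) {
    k <- sum(atten)
    off <- 20L + rgeom(k, 1 / cfg$attenuation_mean_dist)
    stop_off[atten] <- pmin(off, cfg$attenuation_max_dist, cap_off)
    mech[atten] <- "attenuation"
  }
  alive <- !atten

  hazard_pass <- function(run_rows, alive, stop_off, mech) {
    for (j in seq_len(nrow(run_rows))) {
      if (!any(alive)) break
      o <- run_rows$offset[j]
      L <- run_rows$run_length[j]
      q <- cfg$p_term_per_t * 2^(-o / cfg$maturation_halfdist)
      p_run <- 1 - (1 - q)^L
      hit <- alive & (runif(n) < p_run)
      k <- sum(hit)
      if (k) {
        w <- (1 - q)^(seq_len(L) - 1L)
        jstar <- sample.int(L, k, replace = TRUE, prob = w)
        stop_off[hit] <- o + jstar - 1L
        mech[hit] <- "dna_directed"
        alive <- alive & !hit
      }
    }
    list(alive = alive, stop_off = stop_off, mech = mech)
  }

  pre <- runs[runs$offset < body, , drop = FALSE]
  st <- hazard_pass(pre, alive, stop_off, mech)
  alive <- st$alive; stop_off <- st$stop_off; mech <- st$mech

  # PAS cleavage at the TES (last body base, sense offset body - 1).
  if (spec$pas_strength > 0) {
    cleaved <- alive & (runif(n) < spec$pas_strength)
  }

  pause_anchor <- integer()
  if (length(spec$planted_pause_sites)) {
    pause_anchor <- body + spec$planted_pause_sites +
      nchar(cfg$pause_seq) - 1L
  }

  if (any(cleaved) && flags$xrn2_active) {
    k <- sum(cleaved)
    d <- 1L + rgeom(k, 1 / cfg$torpedo_mean_dist)
    t_off <- pmin(body - 1L + d, cap_off)
    if (length(pause_anchor)) {
      near <- vapply(t_off, function(x) {
        dd <- abs(pause_anchor - x)
        if (min(dd) <= cfg$pause_snap_window) pause_anchor[which.min(dd)]
        else x
      }, integer(1))
      t_off <- near
    }
    stop_off[cleaved] <- t_off
    mech[cleaved] <- "torpedo"
    alive <- alive & !cleaved
  }

  post <- runs[runs$offset >= body, , drop = FALSE]
  st <- hazard_pass(post, alive, stop_off, mech)
  alive <- st$alive; stop_off <- st$stop_off; mech <- st$mech

  stop_off[alive] <- cap_off
  mech[alive] <- "runoff"

  # 3' box cleavage on snRNA-like TUs: processes the RNA, does not stop the
  # polymerase. Only polymerases that transcribed past the box can be cut.
  box_site <- body - 1L + cfg$box_offset
  boxed <- rep(FALSE, n)
  if (spec$has_three_prime_box && box_p > 0) {
    past <- stop_off >= box_site
    boxed <- past & (runif(n) < box_p)
  }

  to_pos <- function(off) {
    as.integer(offset_to_pos(tu$start, tu$end, tu$strand, off))
  }

  events <- tibble(
    tu_id = tu$tu_id, polymerase = seq_len(n), mechanism = mech,
    chrom = chrom, pos = to_pos(stop_off), sense_offset = stop_off,
    strand = tu$strand,
    released = mech != "torpedo", cleaved_pas = cleaved
  )

  released <- events[events$released, ]
  rna_ends <- bind_rows(
    tibble(
      tu_id = released$tu_id, polymerase = released$polymerase,
      chrom = chrom, pos = released$pos, strand = tu$strand,
      mechanism = released$mechanism, adenylated = FALSE,
      exosome_substrate = TRUE
    ),
    if (any(cleaved)) tibble(
      tu_id = tu$tu_id, polymerase = which(cleaved), chrom = chrom,
      pos = to_pos(body - 1L), strand = tu$strand,
      mechanism = "pas_cleavage", adenylated = TRUE,
      exosome_substrate = FALSE
    ),
    if (any(boxed)) tibble(
      tu_id = tu$tu_id, polymerase = which(boxed), chrom = chrom,
      pos = to_pos(box_site - 1L), strand = tu$strand,
      mechanism = "three_prime_box_cleavage", adenylated = FALSE,
      exosome_substrate = FALSE
    )
  )

  five_ends <- bind_rows(
    tibble(tu_id = tu$tu_id, chrom = chrom, pos = to_pos(0L),
           strand = tu$strand, kind = "tss", n_rna = n),
    if (any(boxed)) tibble(tu_id = tu$tu_id, chrom = chrom,
                           pos = to_pos(box_site), strand = tu$strand,
                           kind = "box_cs", n_rna = sum(boxed)),
    if (any(cleaved)) tibble(tu_id = tu$tu_id, chrom = chrom,
                             pos = to_pos(body), strand = tu$strand,
                             kind = "pas_cs", n_rna = sum(cleaved))
  )

  pause_visits <- NULL
  if (length(pause_anchor)) {
    pv <- lapply(pause_anchor, function(a) {
      crossed <- stop_off >= a
      if (!any(crossed)) return(NULL)
      trapped <- crossed & cleaved & !flags$xrn2_active
      tibble(
        tu_id = tu$tu_id, chrom = chrom, pos = to_pos(a), strand = tu$strand,
        weight = sum(crossed & !trapped) +
          sum(trapped) * cfg$pause_dwell_trapped
      )
    })
    pause_visits <- list_rbind(pv[!map_lgl(pv, is.null)])
  }
  if (is.null(pause_visits)) {
    pause_visits <- tibble(tu_id = character(), chrom = character(),
                           pos = integer(), strand = character(),
                           weight = integer())
  }

  list(events = events, rna_ends = rna_ends, five_ends = five_ends,
       pause_visits = pause_visits)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> condition %s: %d polymerases, %d RNA 3' ends\n",
    x$condition, nrow(x$events), nrow(x$rna_ends)
  ))
  print(count(x$events, .data$mechanism))
  invisible(x)
}

#' @export
tidy.ground_truth <- function(x, ...) {
  as_tibble(x$events)
}
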