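#' Construct an end-count profile from a tibble of per-base counts
#'
#' The canonical container for stranded single-nucleotide end-count tracks:
#' a tibble with columns `chrom`, `pos` (0-based), `strand` and `count`
#' (non-negative integers), carrying the sample's flavor, EPAP status, id and
#' library size as attributes.
#'
#' @param counts Tibble with columns `chrom`, `pos`, `strand`, `count`.
#' @param flavor One of `"three_prime"`, `"five_prime"`, `"active_site"`.
#' @param epap Logical EPAP (in vitro polyadenylation) status.
#' @param sample_id Sample identifier.
#' @param condition Optional condition label.
#' @return An `end_profile` tibble.
#' @export
end_profile <- function(counts, flavor = "three_prime", epap = TRUE,
                        sample_id = "sample", condition = NA_character_) {
  flavor <- arg_match0(flavor, c("three_prime", "five_prime", "active_site"))
  counts <- as_tibble(counts)
  need <- c("chrom", "pos", "strand", "count")
  if (!all(need %in% names(counts))) {
    abort(sprintf("`counts` needs columns %s", paste(need, collapse = ", ")))
  }
  if (any(counts$count < 0)) abort("counts must be non-negative")
  check_strand(counts$strand)
  counts <- counts |>
    filter(.data$count > 0) |>
    group_by(.data$chrom, .data$pos, .data$strand) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$chrom, .data$strand, .data$pos)
  counts$pos <- as.integer(counts$pos)
  counts$count <- as.integer(counts$count)
  structure(
    counts,
    class = c("end_profile", class(counts)),
    flavor = flavor, epap = isTRUE(epap), sample_id = sample_id,
    condition = condition, library_size = sum(counts$count)
  )
}

#' @export
as_tibble.end_profile <- function(x, ...) {
  tibble::new_tibble(list(chrom = x$chrom, pos = x$pos, strand = x$strand,
                          count = x$count), nrow = nrow(x))
}

profile_meta <- function(p) {
  list(flavor = attr(p, "flavor"), epap = attr(p, "epap"),
       sample_id = attr(p, "sample_id"), condition = attr(p, "condition"),
       library_size = attr(p, "library_size"))
}

#' @export
print.end_profile <- function(x, ...) {
  m <- profile_meta(x)
  cat(sprintf("<end_profile> %s [%s, %sEPAP] library %d, %d positions\n",
              m$sample_id, m$flavor, if (isTRUE(m$epap)) "+" else "-",
              m$library_size, nrow(x)))
  NextMethod()
}

#' Render an end-count profile from simulated ground truth
#'
#' Applies the detection model of the assay to a [simulate_polymerases()]
#' ground truth:
#'
#' * `three_prime` (3'-seq): polyadenylated ends are detected with or without
#'   EPAP; nonadenylated ends only with EPAP; released exosome substrates are
#'   detected with probability `exosome_survival` while the exosome is active
#'   and with probability 1 when it is depleted.
#' * `five_prime` (POINT5-analog): capped TSS 5' ends, 3'-box
#'   cleavage-product 5' ends, and PAS cleavage-product 5' ends (the latter
#'   degraded by the XRN2 torpedo, so detected at `pas5_survival` while XRN2
#'   is active). EPAP does not apply; `epap = TRUE` is rejected.
#' * `active_site` (mNET-analog): an occupancy snapshot of
#'   chromatin-engaged polymerases — one uniformly drawn position along each
#'   trajectory plus dwell-weighted counts at crossed pause sites
#'   ("sitting ducks" when the PAS was cleaved and XRN2 is absent).
#'   Polymerases released by termination have left the template and are not
#'   captured, so fast DNA-directed termination leaves no active-site
#'   footprint. EPAP is irrelevant and ignored.
#'
#' @param truth A `ground_truth` object.
#' @param flavor `"three_prime"`, `"five_prime"` or `"active_site"`.
#' @param epap Logical; EPAP treatment of the library.
#' @param depth Integer depth multiplier: each event is emitted as a
#'   `Binomial(depth, p_detect)` count.
#' @param seed Seed for the rendering stream; defaults to `truth$seed + 1`.
#' @param sample_id Optional sample id; constructed from condition, flavor
#'   and EPAP status otherwise.
#' @return An [end_profile()].
#' @export
render_end_profile <- function(truth, flavor = "three_prime", epap = TRUE,
                               depth = 1L, seed = NULL, sample_id = NULL) {
  if (!inherits(truth, "ground_truth")) {
    abort("`truth` must be a ground_truth object")
  }
  flavor <- arg_match0(flavor, c("three_prime", "five_prime", "active_site"))
  if (flavor == "five_prime" && isTRUE(epap)) {
    abort("five_prime + EPAP is undefined: 5' ends are not polyadenylated")
  }
  flags <- condition_flags(truth$condition)
  cfg <- truth$config
  if (is.null(seed)) seed <- truth$seed + 1L
  if (is.null(sample_id)) {
    sample_id <- sprintf("%s_%s_%s", truth$condition, flavor,
                         if (isTRUE(epap)) "plusEPAP" else "minusEPAP")
  }
  depth <- as.integer(depth)

  counts <- withr::with_seed(seed, {
    switch(
      flavor,
      three_prime = {
        re <- truth$rna_ends
        p <- ifelse(
          re$adenylated, 1,
          ifelse(!isTRUE(epap), 0,
                 ifelse(re$exosome_substrate & flags$exosome_active,
                        cfg$exosome_survival, 1))
        )
        tibble(chrom = re$chrom, pos = re$pos, strand = re$strand,
               count = rbinom(nrow(re), depth, p))
      },
      five_prime = {
        fe <- truth$five_ends
        p <- case_when(
          fe$kind == "pas_cs" & flags$xrn2_active ~ cfg$pas5_survival,
          .default = 1
        )
        tibble(chrom = fe$chrom, pos = fe$pos, strand = fe$strand,
               count = rbinom(nrow(fe), fe$n_rna * depth, p))
      },
      active_site = {
        ev <- truth$events
        body_off <- as.integer(floor(runif(nrow(ev)) * (ev$sense_offset + 1L)))
        # Map body-occupancy offsets back to the reference per event's TU.
        tu_tbl <- tibble(tu_id = map_chr(cfg$tu_specs, "tu_id"),
                         start = map_int(cfg$tu_specs, "start"),
                         body = map_int(cfg$tu_specs, "body_length"))
        ev2 <- left_join(ev, tu_tbl, by = "tu_id")
        occ_pos <- as.integer(offset_to_pos(ev2$start, ev2$start + ev2$body,
                                            ev2$strand, body_off))
        pv <- truth$pause_visits
        bind_rows(
          tibble(chrom = ev$chrom, pos = occ_pos, strand = ev$strand,
                 count = rbinom(nrow(ev), depth, 1)),
          if (nrow(pv)) tibble(chrom = pv$chrom, pos = pv$pos,
                               strand = pv$strand,
                               count = rbinom(nrow(pv), pv$weight * depth, 1))
        )
      }
    )
  })

  end_profile(counts, flavor = flavor, epap = isTRUE(epap),
              sample_id = sample_id, condition = truth$condition)
}
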