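# Synthetic genome construction and the polymerase walk.

test_that("planted terminators are written onto the coding strand", {
  cfg <- sim_config(list(tu_spec("mono_nc", 800, strand = "+", start = 0L,
    planted_terminators = tibble::tibble(offset = 500L, run_length = 6L))),
    seed = 1)
  g <- build_synthetic_genome(cfg)
  expect_identical(substr(g$seq[[1]], 501, 506), "TTTTTT")
  reg <- g$registry[g$registry$type == "terminator", ]
  expect_identical(reg$start, 500L)
  expect_identical(reg$end, 506L)

  # Minus-strand TU at the same sense offset: an A-run on the reference at
  # the mirrored coordinates (TSS at end - 1, sense runs towards lower
  # reference positions).
  cfg_m <- sim_config(list(tu_spec("mono_nc", 800, strand = "-",
    start = 600L,
    planted_terminators = tibble::tibble(offset = 500L, run_length = 6L))),
    runoff_extension = 500L, seed = 1)
  g_m <- build_synthetic_genome(cfg_m)
  reg_m <- g_m$registry[g_m$registry$type == "terminator", ]
  tss_m <- 600L + 800L - 1L
  expect_identical(reg_m$end, tss_m - 500L + 1L)
  expect_identical(
    substr(g_m$seq[[1]], reg_m$start + 1L, reg_m$end), "AAAAAA")
})

test_that("overlapping planted elements of one TU are rejected", {
  cfg <- sim_config(list(tu_spec("mono_nc", 800,
    planted_terminators = tibble::tibble(offset = c(500L, 503L),
                                         run_length = c(6L, 6L)))))
  expect_error(build_synthetic_genome(cfg), "overlap")
})

test_that("genome build and simulation are deterministic for a fixed seed", {
  cfg <- tiny_config(seed = 11)
  g1 <- build_synthetic_genome(cfg)
  g2 <- build_synthetic_genome(cfg)
  expect_identical(g1$seq, g2$seq)
  t1 <- simulate_polymerases(g1, "dEXOSC3")
  t2 <- simulate_polymerases(g2, "dEXOSC3")
  expect_identical(t1$events, t2$events)
  p1 <- render_end_profile(t1, "three_prime", epap = TRUE)
  p2 <- render_end_profile(t2, "three_prime", epap = TRUE)
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))
})

test_that("parameter extremes force the expected mechanisms", {
  # No T hazard, certain PAS cleavage, torpedo on: every survivor of the
  # (disabled) attenuation step terminates by torpedo.
  cfg <- sim_config(list(tu_spec("short_coding", 2000, pas_strength = 1,
                                 planted_pause_sites = 500L)),
                    p_term_per_t = 0, attenuation_p = 0, seed = 3)
  g <- build_synthetic_genome(cfg)
  tr <- simulate_polymerases(g, "CTRL")
  expect_true(all(tr$events$mechanism == "torpedo"))

  # Certain per-T hazard at distance 0: everyone stops at the first tract.
  cfg2 <- sim_config(list(tu_spec("mono_nc", 800, planted_terminators =
    tibble::tibble(offset = 0L, run_length = 6L))),
    p_term_per_t = 1, attenuation_p = 0, seed = 3)
  g2 <- build_synthetic_genome(cfg2)
  tr2 <- simulate_polymerases(g2, "CTRL")
  expect_true(all(tr2$events$mechanism == "dna_directed"))
  expect_true(all(tr2$events$sense_offset == 0L))
})

test_that("per-run termination frequency matches the closed form", {
  # P(terminate in a run of 6 at d = 0) = 1 - (1 - 0.1)^6.
  cfg <- sim_config(list(tu_spec("mono_nc", 800, planted_terminators =
    tibble::tibble(offset = 0L, run_length = 6L))),
    p_term_per_t = 0.1, attenuation_p = 0,
    maturation_halfdist = 1e9, n_polymerases_per_tu = 10000L, seed = 5)
  g <- build_synthetic_genome(cfg)
  tr <- simulate_polymerases(g, "CTRL")
  frac <- mean(tr$events$mechanism == "dna_directed" &
                 tr$events$sense_offset < 6L)
  p_expected <- 1 - (1 - 0.1)^6        # 0.468559
  se <- sqrt(p_expected * (1 - p_expected) / 10000)
  expect_lt(abs(frac - p_expected), 4 * se)
})

test_that("condition switches disable the right machinery", {
  w <- default_world()
  expect_false(any(w$truth_xrn$events$mechanism == "torpedo"))
  expect_gt(sum(w$truth_ctrl$events$mechanism == "torpedo"), 0)
  tr_int <- simulate_polymerases(w$genome, "dINT", seed = 4001)
  expect_false(any(tr_int$events$mechanism == "attenuation"))
  expect_false(any(tr_int$rna_ends$mechanism == "three_prime_box_cleavage"))
  expect_gt(sum(w$truth_ctrl$rna_ends$mechanism ==
                  "three_prime_box_cleavage"), 0)
  expect_error(simulate_polymerases(w$genome, "dNONSENSE"), "condition")
})

test_that("DNA-directed termination decays with distance from the TSS", {
  w <- distance_world()
  ev <- w$truth_exo$events
  dd <- ev[ev$mechanism == "dna_directed", ]
  bins <- cut(dd$sense_offset, breaks = c(0, 1000, 2000, 3000, 4000),
              right = TRUE)
  counts <- as.integer(table(bins))
  expect_true(all(diff(counts) < 0))
})

test_that("EPAP gates nonadenylated ends and exosome loss lifts detection", {
  cfg <- tiny_config(seed = 2)
  ends <- tibble::tibble(
    tu_id = "TU001", polymerase = 1:200, chrom = "chr1", pos = 100L,
    strand = "+", mechanism = "dna_directed", adenylated = FALSE,
    exosome_substrate = TRUE)
  tr_ctrl <- make_truth(ends, "CTRL", cfg)
  tr_exo <- make_truth(ends, "dEXOSC3", cfg)

  # Released nonadenylated ends are invisible without EPAP.
  p_no <- render_end_profile(tr_ctrl, "three_prime", epap = FALSE)
  expect_identical(nrow(p_no), 0L)
  expect_identical(attr(p_no, "library_size"), 0L)

  # Lossless rendering when the exosome is depleted and depth = 1.
  p_exo <- render_end_profile(tr_exo, "three_prime", epap = TRUE)
  expect_identical(p_exo$count, 200L)

  # Detection ratio approaches 1 / exosome_survival = 5 at high depth.
  depth <- 500L
  c_ctrl <- sum(render_end_profile(tr_ctrl, "three_prime", TRUE,
                                   depth = depth)$count)
  c_exo <- sum(render_end_profile(tr_exo, "three_prime", TRUE,
                                  depth = depth)$count)
  ratio <- c_exo / c_ctrl
  expect_lt(abs(ratio - 5), 0.35)

  # Conservation: emitted counts never exceed events x depth.
  expect_lte(c_exo, 200L * depth)
  expect_lte(c_ctrl, 200L * depth)
})

test_that("five_prime + EPAP is rejected and flavors render distinct ends", {
  w <- default_world()
  expect_error(render_end_profile(w$truth_ctrl, "five_prime", epap = TRUE),
               "EPAP")
  p5 <- render_end_profile(w$truth_ctrl, "five_prime", epap = FALSE)
  tus <- w$genome$tus
  tss <- ifelse(tus$strand == "+", tus$start, tus$end - 1L)
  expect_true(all(tss %in% p5$pos))
})

test_that("invalid configurations are rejected", {
  expect_error(tiny_config(base_composition = c(A = .5, C = .5, G = .1,
                                                T = -.1)),
               "sum|\\[0, 1\\]")
  expect_error(tiny_config(p_term_per_t = 1.2), "probability")
  expect_error(tu_spec("mono_nc", 800, planted_terminators =
    tibble::tibble(offset = 1L, run_length = 3L)), "run_length")
  expect_error(tu_spec("nonsense_type", 100), "biotype")
})
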