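# CPM scaling, fold-change tracks, stabilised-end calling, region signal,
# TU selection and the comparison statistics.

test_that("CPM and RPKM follow their unit definitions", {
  p <- make_profile(100L, 5L, library_size = 1e6L)
  cpm <- normalize_cpm(p)
  expect_equal(cpm$cpm[cpm$pos == 100L], 5.0)
  expect_equal(rpkm(100, 1000, 1e6), 100)
  empty <- end_profile(tibble::tibble(chrom = character(), pos = integer(),
                                      strand = character(),
                                      count = integer()))
  expect_error(normalize_cpm(empty), "library")
})

test_that("log2 tracks are zero on identity, exact on arithmetic, and
           antisymmetric under swap", {
  a <- make_profile(c(10L, 20L), c(4L, 7L), library_size = 1000L,
                    sample_id = "a")
  expect_true(all(log2_ratio_track(a, a)$log2fc == 0))

  t <- make_profile(50L, 3L, library_size = 1e6L, sample_id = "t")
  c <- make_profile(51L, 1L, library_size = 1e6L, sample_id = "c")
  fc <- log2_ratio_track(t, c, pseudocount = 1)
  expect_equal(fc$log2fc[fc$pos == 50L], 2.0)   # log2((3+1)/(0+1))

  b <- make_profile(c(10L, 30L), c(9L, 2L), library_size = 1000L,
                    sample_id = "b")
  ab <- log2_ratio_track(a, b)
  ba <- log2_ratio_track(b, a)
  merged <- dplyr::inner_join(tibble::as_tibble(ab), tibble::as_tibble(ba),
                              by = c("chrom", "pos", "strand"))
  expect_equal(merged$log2fc.x, -merged$log2fc.y)
})

test_that("mismatched flavor or EPAP pairing is rejected", {
  t <- make_profile(1L, 1L, flavor = "three_prime", epap = TRUE)
  c <- make_profile(1L, 1L, flavor = "three_prime", epap = FALSE)
  expect_error(log2_ratio_track(t, c), "pair")
  c2 <- make_profile(1L, 1L, flavor = "active_site", epap = TRUE)
  expect_error(log2_ratio_track(t, c2), "pair")
})

test_that("stabilised-end calling applies both thresholds exactly", {
  t <- make_profile(100L, 8L, library_size = 1e6L, sample_id = "t")
  c <- make_profile(100L, 1L, library_size = 1e6L, sample_id = "c")
  calls <- call_stabilized_ends(t, c)
  expect_identical(nrow(calls), 1L)
  expect_equal(calls$log2fc, log2(9 / 2), tolerance = 1e-12)

  expect_identical(nrow(call_stabilized_ends(t, t)), 0L)
  expect_error(call_stabilized_ends(t, c, min_log2 = -1), "min_log2")
})

test_that("calling on a planted fixture recovers exactly the planted
           positions, checked against a per-position brute force", {
  stab_pos <- seq(100L, 1000L, by = 100L)     # 10 planted stabilised ends
  flat_pos <- seq(5000L, 5900L, by = 100L)    # 10 unchanged
  ctrl <- make_profile(c(stab_pos, flat_pos), rep(20L, 20),
                       library_size = 1e6L, sample_id = "ctrl")
  trt <- make_profile(c(stab_pos, flat_pos), c(rep(100L, 10), rep(20L, 10)),
                      library_size = 1e6L, sample_id = "trt")
  calls <- call_stabilized_ends(trt, ctrl)
  expect_setequal(calls$pos, stab_pos)

  # Independent brute force over every covered position.
  brute <- vapply(c(stab_pos, flat_pos), function(p) {
    tt <- 100 * (p %in% stab_pos) + 20 * !(p %in% stab_pos)
    log2((tt + 1) / (20 + 1)) >= 1 && tt >= 1
  }, logical(1))
  expect_setequal(calls$pos, c(stab_pos, flat_pos)[brute])
})

test_that("region signal equals hand-summed values, strand-aware", {
  tus <- tibble::tibble(
    tu_id = c("A", "B", "C"), chrom = "chr1",
    start = c(0L, 3000L, 6000L), end = c(1000L, 4000L, 7000L),
    strand = c("+", "-", "+"), biotype = "mono_nc", exon_count = 1L,
    pas_score = NA_real_)
  # A: body counts only. B (minus): downstream lies below start.
  trt <- make_profile(
    pos = c(100L, 900L, 2800L, 6100L, 7600L),
    count = c(5L, 3L, 7L, 2L, 4L),
    strand = c("+", "+", "-", "+", "+"),
    library_size = 1e6L, sample_id = "t")
  ctl <- make_profile(pos = 100L, count = 1L, library_size = 1e6L,
                      sample_id = "c")
  rs <- region_signal(trt, ctl, tus, downstream_window = 500L)
  expect_equal(rs$body_count_t, c(8, 0, 2))
  expect_equal(rs$down_count_t, c(0, 7, 0))      # B's flank at 2800 (< TES)
  expect_equal(rs$body_count_c, c(1, 0, 0))
  # 7600 is beyond C's 500-base window: counted nowhere.
  expect_equal(sum(rs$down_count_t), 7)
  expect_error(region_signal(trt, ctl, tus, downstream_window = 0), "> 0")
})

test_that("flank-stabilised TU selection recovers exactly the planted
           class and honors limit behavior", {
  fx <- fixture_flank_panel()
  rs <- region_signal(fx$treatment, fx$control, fx$tus,
                      downstream_window = 3000L)
  sel <- select_flank_stabilized_tus(rs)
  planted <- fx$truth$tu_id[fx$truth$class == "flank_only"]
  expect_setequal(sel$tu_id, planted)

  expect_identical(nrow(select_flank_stabilized_tus(
    rs, flank_min_log2 = Inf)), 0L)
  all_pos <- select_flank_stabilized_tus(rs, flank_min_log2 = 0,
                                         body_max_log2 = Inf)
  expect_setequal(all_pos$tu_id,
                  rs$tu_id[rs$down_log2fc >= 0])
})

test_that("concordance is 100% on identity, 0% beyond tolerance, and
           matches the analytic null expectation", {
  a <- tibble::tibble(chrom = "chr1", pos = c(10L, 50L, 90L), strand = "+")
  self <- end_position_concordance(a, a)
  expect_equal(self$symmetric_pct, 100)
  b <- tibble::tibble(chrom = "chr1", pos = c(200L, 400L), strand = "+")
  expect_equal(end_position_concordance(a, b, tolerance = 5)$symmetric_pct, 0)
  # Strand-aware: same coordinates on the other strand never match.
  a_minus <- dplyr::mutate(a, strand = "-")
  expect_equal(end_position_concordance(a, a_minus)$symmetric_pct, 0)
  expect_error(end_position_concordance(a, b, tolerance = -1), ">= 0")

  # Null calibration: two independent uniform call sets of 100 positions on
  # [0, 1e6) at tolerance 5. P(match) = 1 - (1 - 11/1e6)^100 per position.
  set.seed(42)
  reps <- 300
  obs <- vapply(seq_len(reps), function(i) {
    x <- tibble::tibble(chrom = "chr1", strand = "+",
                        pos = sample.int(1e6, 100) - 1L)
    y <- tibble::tibble(chrom = "chr1", strand = "+",
                        pos = sample.int(1e6, 100) - 1L)
    end_position_concordance(x, y, tolerance = 5)$a_to_b_pct
  }, numeric(1))
  p_match <- 1 - (1 - 11 / 1e6)^100
  se <- sqrt(p_match * (1 - p_match) / (100 * reps)) * 100
  expect_lt(abs(mean(obs) - 100 * p_match), 4 * se)
})

test_that("body/downstream correlation hits the exact limits", {
  base <- fixture_flank_panel()
  rs <- region_signal(base$treatment, base$control, base$tus)
  fake <- rs
  fake$down_log2fc <- fake$body_log2fc * 2 + 1
  expect_equal(body_downstream_fc_correlation(fake), 1.0)
  fake$down_log2fc <- -fake$body_log2fc
  expect_equal(body_downstream_fc_correlation(fake), -1.0)
  expect_error(body_downstream_fc_correlation(fake[1:2, ]), "3 TUs")
})

test_that("CPM fold changes are invariant to joint library scaling", {
  t <- make_profile(c(5L, 9L), c(6L, 2L), library_size = 500L,
                    sample_id = "t")
  c <- make_profile(c(5L, 7L), c(1L, 3L), library_size = 500L,
                    sample_id = "c")
  scale_profile <- function(p, f) {
    tb <- tibble::as_tibble(p)
    tb$count <- tb$count * f
    end_profile(tb, flavor = attr(p, "flavor"), epap = attr(p, "epap"),
                sample_id = attr(p, "sample_id"))
  }
  fc1 <- log2_ratio_track(t, c)
  fc2 <- log2_ratio_track(scale_profile(t, 7L), scale_profile(c, 7L))
  expect_equal(fc1$log2fc, fc2$log2fc)
})

test_that("transcription end detection finds the last smoothed signal", {
  tus <- tibble::tibble(tu_id = "A", chrom = "chr1", start = 0L, end = 1000L,
                        strand = "+", biotype = "mono_nc", exon_count = 1L,
                        pas_score = NA_real_)
  p <- make_profile(c(1200:1260, 2000L), c(rep(50L, 61), 1L),
                    library_size = 1e5L)
  # At the default 0.1-CPM floor even the lone end at 2000 (10 CPM, smoothed
  # 10/21) is detected; the 21-base window reaches 10 bases past it.
  res <- detect_transcription_end(p, tus, max_extension = 5000)
  expect_identical(res$end_pos, 2010L)
  # A 1-CPM floor suppresses it; the dense block ends the detected region.
  res2 <- detect_transcription_end(p, tus, max_extension = 5000,
                                   floor_cpm = 1)
  expect_identical(res2$end_pos, 1270L)
})
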