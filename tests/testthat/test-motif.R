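# Terminal k-mer extraction, enrichment ranking, background T fraction,
# T-run location and distance binning.

test_that("terminal k-mers read the coding strand ending at the call", {
  g <- c(chr1 = "AAATTTTTT")
  # Plus-strand call at the last base.
  expect_identical(terminal_kmer(g, "chr1", 8L, "+"), "TTTTTT")
  # Minus-strand call where the forward window is A-rich.
  expect_identical(terminal_kmer(g, "chr1", 0L, "-", k = 3L), "TTT")
  # Boundary: a 6-mer cannot end at position 2.
  expect_true(is.na(terminal_kmer(g, "chr1", 2L, "+")))
  # Ambiguous bases are skipped, never imputed.
  gn <- c(chr1 = "AANTTTTTT")
  expect_true(is.na(terminal_kmer(gn, "chr1", 7L, "+")))
})

test_that("terminal k-mers agree with a Biostrings slice oracle at every
           position of a small genome, both strands", {
  cfg <- tiny_config(seed = 21, genome_length = 8000L)
  g <- build_synthetic_genome(cfg)
  len <- nchar(g$seq[[1]])
  dna <- Biostrings::DNAString(g$seq[[1]])
  k <- 6L
  pos <- seq.int(0L, len - 1L)

  got_plus <- terminal_kmer(g, rep("chrS", len), pos, rep("+", len), k)
  got_minus <- terminal_kmer(g, rep("chrS", len), pos, rep("-", len), k)

  oracle_plus <- rep(NA_character_, len)
  ok <- pos - k + 1L >= 0L
  oracle_plus[ok] <- vapply(pos[ok], function(p) {
    as.character(Biostrings::subseq(dna, p - k + 2L, p + 1L))
  }, character(1))
  oracle_minus <- rep(NA_character_, len)
  ok2 <- pos + k <= len
  oracle_minus[ok2] <- vapply(pos[ok2], function(p) {
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(dna, p + 1L, p + k)))
  }, character(1))

  expect_identical(got_plus, oracle_plus)
  expect_identical(got_minus, oracle_minus)
})

test_that("k-mer tables conserve totals and match a brute-force tally", {
  w <- default_world()
  calls <- call_stabilized_ends(w$exo_3p, w$ctrl_3p)
  kt <- count_terminal_kmers(calls, w$genome)
  expect_identical(sum(kt$count) + attr(kt, "n_skipped"),
                   as.numeric(nrow(calls)))

  km <- terminal_kmer(w$genome, calls$chrom, calls$pos, calls$strand)
  brute <- sort(table(km[!is.na(km)]), decreasing = TRUE)
  expect_identical(sum(kt$count), as.numeric(sum(brute)))
  got <- setNames(kt$count, kt$kmer)
  expect_equal(unname(got[names(brute)]), as.numeric(brute))

  # Weighted mode totals equal the summed treatment counts.
  ktw <- count_terminal_kmers(calls, w$genome, weight = "count_weighted")
  expect_equal(sum(ktw$count), sum(calls$count_t[!is.na(km)]))

  # Empty call set: empty table, not an error.
  kt0 <- count_terminal_kmers(calls[0, ], w$genome)
  expect_identical(nrow(kt0), 0L)
})

test_that("ties in k-mer counts break lexicographically", {
  g <- c(chr1 = strrep("A", 10))
  calls <- tibble::tibble(chrom = "chr1", pos = c(6L, 7L), strand = "+")
  kt <- count_terminal_kmers(calls, g, k = 2L)
  expect_identical(kt$kmer, "AA")
  g2 <- c(chr1 = "AAACCC")
  calls2 <- tibble::tibble(chrom = "chr1", pos = c(2L, 5L), strand = "+")
  kt2 <- count_terminal_kmers(calls2, g2, k = 3L)
  expect_identical(kt2$kmer, c("AAA", "CCC"))   # equal counts, A first
})

test_that("T-fraction statistic matches the null and planted designs", {
  set.seed(33)
  bases <- sample(c("A", "C", "G", "T"), 40000, replace = TRUE)
  g <- c(chr1 = paste(bases, collapse = ""))
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 40000L,
                            strand = "+")
  calls <- tibble::tibble(chrom = "chr1",
                          pos = sample.int(40000, 800) - 1L, strand = "+")
  res <- t_fraction_statistic(calls, g, regions)
  expect_lt(abs(res$end_t_fraction - 0.25), 0.06)
  expect_lt(abs(res$genomic_t_fraction - 0.25), 0.01)
  expect_lt(abs(res$z), 3)

  # All calls at planted T-run ends.
  w <- default_world()
  reg <- w$genome$registry
  term <- reg[reg$type == "terminator", ]
  end_pos <- ifelse(term$strand == "+", term$end - 1L, term$start)
  planted_calls <- tibble::tibble(chrom = term$chrom, pos = end_pos,
                                  strand = term$strand)
  res2 <- t_fraction_statistic(planted_calls, w$genome, w$genome$tus)
  expect_equal(res2$end_t_fraction, 1.0)
  expect_lt(res2$genomic_t_fraction, 1.0)

  expect_error(t_fraction_statistic(calls[0, ], g, regions), "empty")
  expect_error(t_fraction_statistic(calls, g, regions[0, ]), "empty")
})

test_that("T-run finding returns maximal runs and matches the registry", {
  g <- c(chr1 = "CCTTTTTTTCC")
  tus <- tibble::tibble(tu_id = "A", chrom = "chr1", start = 0L, end = 11L,
                        strand = "+", biotype = "mono_nc", exon_count = 1L,
                        pas_score = NA_real_)
  runs <- find_t_runs(g, tus, min_run = 6L, downstream_bp = 0L)
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$run_length, 7L)
  expect_identical(c(runs$start, runs$end), c(2L, 9L))

  g5 <- c(chr1 = "TTTTT")
  tus5 <- dplyr::mutate(tus, end = 5L)
  expect_identical(nrow(find_t_runs(g5, tus5, min_run = 6L,
                                    downstream_bp = 0L)), 0L)
  expect_error(find_t_runs(g, tus, min_run = 0L), "min_run")

  # On a T-free background every found run is a planted run.
  cfg <- sim_config(
    list(tu_spec("mono_nc", 800, planted_terminators = tibble::tibble(
      offset = c(200L, 500L), run_length = c(6L, 7L))),
      tu_spec("mono_nc", 800, strand = "-", planted_terminators =
        tibble::tibble(offset = 350L, run_length = 6L))),
    base_composition = c(A = 0, C = 0.5, G = 0.5, T = 0),
    seed = 13)
  gp <- build_synthetic_genome(cfg)
  found <- find_t_runs(gp, gp$tus, min_run = 6L)
  planted <- gp$registry[gp$registry$type == "terminator", ]
  expect_identical(nrow(found), nrow(planted))
  expect_setequal(paste(found$start, found$end, found$strand),
                  paste(planted$start, planted$end, planted$strand))
  expect_identical(sort(found$sense_offset), sort(planted$sense_offset))
})

test_that("distance binning assigns runs and drops distal ones with a
           count", {
  runs <- structure(
    tibble::tibble(tu_id = "A", chrom = "chr1",
                   start = c(500L, 1500L, 4500L), end = c(506L, 1506L, 4506L),
                   strand = "+", run_length = 6L,
                   sense_offset = c(500L, 1500L, 4500L)),
    class = c("t_run_set", class(tibble::tibble())), min_run = 6L)
  binned <- motif_distance_bins(runs)
  expect_identical(as.character(binned$bin), c("(0,1]kb", "(1,2]kb"))
  expect_identical(attr(binned, "n_dropped"), 1L)
  expect_error(motif_distance_bins(runs, bins = list(c(0, 2), c(1, 3))),
               "overlap")
})

test_that("fold-change meta-curves are flat zero for identical samples and
           peak only where stabilisation was planted", {
  w <- default_world()
  fc0 <- log2_ratio_track(w$ctrl_3p, w$ctrl_3p)
  runs <- find_t_runs(w$genome, w$genome$tus, min_run = 6L)
  binned <- motif_distance_bins(runs)
  curve0 <- fc_over_motifs(fc0, binned)
  expect_true(all(curve0$mean_log2fc[curve0$n_runs > 0] == 0))

  # Hand-built fold-change track stabilised only over (0,1]-kb run bodies.
  bin1 <- binned[binned$bin == "(0,1]kb", ]
  fc_pos <- purrr::list_rbind(purrr::map(seq_len(nrow(bin1)), function(i) {
    tibble::tibble(chrom = bin1$chrom[i],
                   pos = seq.int(bin1$start[i], bin1$end[i] - 1L),
                   strand = bin1$strand[i], log2fc = 3)
  }))
  curve <- fc_over_motifs(fc_pos, binned)
  b1 <- curve[curve$bin == "(0,1]kb" & curve$segment == "body", ]
  b4 <- curve[curve$bin == "(3,4]kb", ]
  expect_true(all(b1$mean_log2fc == 3))
  expect_true(all(b4$mean_log2fc[b4$n_runs > 0] == 0 |
                    is.na(b4$mean_log2fc)))
})

test_that("uniform random calls never beat the permutation null's tail", {
  cfg <- tiny_config(seed = 55, genome_length = 10000L)
  g <- build_synthetic_genome(cfg)
  len <- nchar(g$seq[[1]])
  set.seed(56)
  obs_calls <- tibble::tibble(
    chrom = "chrS", pos = sample.int(len - 6L, 300) + 5L, strand = "+")
  top_count <- function(pos) {
    km <- terminal_kmer(g, rep("chrS", length(pos)), pos,
                        rep("+", length(pos)))
    max(table(km))
  }
  observed <- top_count(obs_calls$pos)
  perm <- vapply(seq_len(1000), function(i) {
    top_count(sample.int(len - 6L, 300) + 5L)
  }, numeric(1))
  expect_lte(observed, stats::quantile(perm, 0.99))
})
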