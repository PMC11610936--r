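#' Constructed fixture for the flank-stabilisation TU filter
#'
#' Builds a deterministic 15-TU panel of paired end-count profiles with
#' known ground truth: 5 TUs whose downstream flank signal is stabilised
#' 8-fold in the treatment without any gene-body change, 5 TUs stabilised
#' 8-fold over body and flank alike, and 5 unchanged TUs. A large invariant
#' filler position keeps the two library sizes comparable so CPM-scale
#' region ratios reflect the planted count ratios. Synthetic by
#' construction; no sequence is involved.
#'
#' @param body_count,flank_count Per-TU control counts in body and flank.
#' @param fold Planted stabilisation factor.
#' @param filler Count at the shared invariant filler position.
#' @return List with `tus` (annotation tibble), `treatment` and `control`
#'   ([end_profile()]s) and `truth` (tibble of tu_id and planted class).
#' @export
fixture_flank_panel <- function(body_count = 100L, flank_count = 20L,
                                fold = 8L, filler = 100000L) {
  classes <- rep(c("flank_only", "body_and_flank", "unchanged"), each = 5)
  n <- length(classes)
  tu_len <- 1000L
  gap <- 5000L
  tus <- tibble(
    tu_id = sprintf("F%02d", seq_len(n)),
    chrom = "chrF",
    start = (seq_len(n) - 1L) * (tu_len + gap),
    end = (seq_len(n) - 1L) * (tu_len + gap) + tu_len,
    strand = rep(c("+", "-"), length.out = n),
    biotype = "short_coding", exon_count = 1L, pas_score = NA_real_
  )
  rows <- function(mult_body, mult_flank) {
    out <- list()
    for (i in seq_len(n)) {
      mb <- if (classes[i] == "body_and_flank") mult_body else 1L
      mf <- if (classes[i] != "unchanged") mult_flank else 1L
      body_pos <- tus$start[i] + 500L
      flank_pos <- if (tus$strand[i] == "+") tus$end[i] + 200L else
        tus$start[i] - 201L
      out[[i]] <- tibble(
        chrom = "chrF",
        pos = c(body_pos, flank_pos),
        strand = tus$strand[i],
        count = c(body_count * mb, flank_count * mf)
      )
    }
    out[[n + 1L]] <- tibble(chrom = "chrF", pos = 0L, strand = "+",
                            count = filler)
    bind_rows(out)
  }
  control <- end_profile(rows(1L, 1L), sample_id = "fixture_CTRL",
                         condition = "CTRL")
  treatment <- end_profile(rows(fold, fold), sample_id = "fixture_depletion",
                           condition = "dEXOSC3")
  list(tus = tus, treatment = treatment, control = control,
       truth = tibble(tu_id = tus$tu_id, class = classes))
}
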