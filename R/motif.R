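# Terminal k-mer extraction on the coding strand, enrichment ranking,
# background-corrected T-fraction statistic, T-run location and the
# distance-binned meta-analysis.

#' Coding-strand terminal k-mer at called 3'-end positions
#'
#' The k bases ending at (and including) a called 3'-end position, read on
#' the strand of the call: for a plus-strand call the reference bases
#' `[pos - k + 1, pos]`, for a minus-strand call the reverse complement of
#' `[pos, pos + k - 1]`. The result equals the last k nucleotides of the
#' transcript with U written as T. Windows that run off the sequence or
#' contain an ambiguous base return `NA` (skipped, never imputed).
#'
#' @param genome A `synthetic_genome`, named character vector or
#'   `DNAStringSet`.
#' @param chrom,pos,strand Parallel vectors of call coordinates (0-based
#'   `pos`).
#' @param k K-mer length.
#' @return Character vector of k-mers (NA where skipped).
#' @export
terminal_kmer <- function(genome, chrom, pos, strand, k = 6L) {
  seqs <- as_genome_seq(genome)
  check_strand(strand)
  if (k < 1) abort("`k` must be >= 1")
  n <- length(pos)
  lens <- nchar(seqs)
  out <- rep(NA_character_, n)
  for (cn in unique(chrom)) {
    if (!cn %in% names(seqs)) {
      abort(sprintf("chromosome %s not in genome", cn))
    }
    idx <- which(chrom == cn)
    len <- lens[[cn]]
    p <- pos[idx]
    s <- strand[idx]
    start <- ifelse(s == "+", p - k + 1L, p)
    ok <- start >= 0L & (start + k) <= len
    km <- rep(NA_character_, length(idx))
    if (any(ok)) {
      km[ok] <- substring(seqs[[cn]], start[ok] + 1L, start[ok] + k)
      minus <- ok & s == "-"
      if (any(minus)) km[minus] <- revcomp(km[minus])
      km[ok][grepl("[^ACGT]", km[ok])] <- NA_character_
    }
    out[idx] <- km
  }
  out
}

#' Count coding-strand terminal k-mers over a call set
#'
#' Ranks terminal k-mers at called stabilised 3'-end positions. With
#' `weight = "unique_positions"` (default) each called position counts once;
#' `"count_weighted"` weights each position by its raw treatment count (the
#' two modes exist because published motif counts do not state whether
#' multi-read ends were weighted). Ties in count are broken
#' lexicographically. Boundary or ambiguous windows are skipped and the skip
#' count recorded, so `sum(count[unweighted]) + skipped == nrow(calls)`.
#'
#' @param calls An `end_call_set` (or tibble with `chrom`, `pos`, `strand`,
#'   and `count_t` for the weighted mode).
#' @param genome Genome sequence (see [terminal_kmer()]).
#' @param k K-mer length (default 6: hexamers, conservative given that four
#'   or more Ts suffice to terminate RNAP III).
#' @param weight Weighting mode.
#' @return A `kmer_table` tibble: `kmer`, `count`, `rank`; attributes `k`,
#'   `n_calls`, `n_skipped`, `weight`.
#' @export
count_terminal_kmers <- function(calls, genome, k = 6L,
                                 weight = c("unique_positions",
                                            "count_weighted")) {
  weight <- arg_match(weight)
  calls <- as_tibble(calls)
  if (!nrow(calls)) {
    out <- tibble(kmer = character(), count = numeric(), rank = integer())
    return(structure(out, class = c("kmer_table", class(out)),
                     k = as.integer(k), n_calls = 0L, n_skipped = 0L,
                     weight = weight))
  }
  km <- terminal_kmer(genome, calls$chrom, calls$pos, calls$strand, k = k)
  w <- if (weight == "count_weighted") {
    if (!"count_t" %in% names(calls)) {
      abort("count_weighted mode needs a `count_t` column")
    }
    calls$count_t
  } else {
    rep(1, nrow(calls))
  }
  keep <- !is.na(km)
  tab <- tibble(kmer = km[keep], w = w[keep]) |>
    group_by(.data$kmer) |>
    summarise(count = sum(.data$w), .groups = "drop") |>
    arrange(desc(.data$count), .data$kmer) |>
    mutate(rank = row_number())
  structure(
    tab,
    class = c("kmer_table", class(tab)),
    k = as.integer(k), n_calls = nrow(calls),
    n_skipped = sum(!keep), weight = weight
  )
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table> k=%d, %d calls (%d skipped), weighting: %s\n",
              attr(x, "k"), attr(x, "n_calls"), attr(x, "n_skipped"),
              attr(x, "weight")))
  NextMethod()
}

#' Terminal-base T fraction versus genomic background
#'
#' Fraction of called 3' ends whose terminal coding-strand base is T,
#' against the coding-strand T frequency of the supplied regions
#' (strand-aware: T on the plus strand, A on the reference for minus-strand
#' regions). The z statistic is the difference over its combined binomial
#' standard error.
#'
#' @param calls An `end_call_set`.
#' @param genome Genome sequence.
#' @param regions Tibble with `chrom`, `start`, `end`, `strand` (e.g. the
#'   TU annotation, or search windows).
#' @return A one-row `t_fraction_result` tibble: `end_t_fraction`,
#'   `genomic_t_fraction`, `diff`, `se_diff`, `z`, `n_ends`, `n_bases`.
#' @export
t_fraction_statistic <- function(calls, genome, regions) {
  calls <- as_tibble(calls)
  regions <- as_tibble(regions)
  if (!nrow(calls)) abort("empty call set: end fraction undefined")
  if (!nrow(regions)) abort("empty region set: background undefined")
  seqs <- as_genome_seq(genome)
  base1 <- terminal_kmer(genome, calls$chrom, calls$pos, calls$strand, k = 1L)
  base1 <- base1[!is.na(base1)]
  if (!length(base1)) abort("all calls skipped: end fraction undefined")
  p_end <- mean(base1 == "T")
  n_end <- length(base1)

  t_bases <- 0
  n_bases <- 0
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    sl <- seq_slice(seqs[[r$chrom]], max(r$start, 0L),
                    min(r$end, nchar(seqs[[r$chrom]])))
    target <- if (r$strand == "+") "T" else "A"
    t_bases <- t_bases + sum(strsplit(sl, "", fixed = TRUE)[[1]] == target)
    n_bases <- n_bases + nchar(sl)
  }
  p_gen <- t_bases / n_bases
  se_end <- sqrt(p_end * (1 - p_end) / n_end)
  se_gen <- sqrt(p_gen * (1 - p_gen) / n_bases)
  se_diff <- sqrt(se_end^2 + se_gen^2)
  out <- tibble(
    end_t_fraction = p_end, genomic_t_fraction = p_gen,
    diff = p_end - p_gen, se_diff = se_diff,
    z = (p_end - p_gen) / se_diff, n_ends = n_end, n_bases = n_bases
  )
  structure(out, class = c("t_fraction_result", class(out)))
}

#' Locate maximal coding-strand T-runs within TU search windows
#'
#' Maximal runs of at least `min_run` consecutive coding-strand Ts within
#' each TU's sense window `[TSS, TES + downstream_bp)`; on minus-strand TUs
#' these are A-runs on the reference.
#'
#' @param genome Genome sequence.
#' @param tus Annotation tibble.
#' @param min_run Minimal run length (>= 1; default 6).
#' @param downstream_bp Search extension past the TES (default 5000).
#' @return A `t_run_set` tibble: `tu_id`, `chrom`, `start`, `end`, `strand`,
#'   `run_length`, `sense_offset` (distance of the run's first T from the
#'   TU's TSS).
#' @export
find_t_runs <- function(genome, tus, min_run = 6L, downstream_bp = 5000L) {
  if (min_run < 1) abort("`min_run` must be >= 1")
  seqs <- as_genome_seq(genome)
  out <- map(seq_len(nrow(tus)), function(i) {
    tu <- tus[i, ]
    len <- nchar(seqs[[tu$chrom]])
    sense_max <- (tu$end - tu$start) + downstream_bp
    if (tu$strand == "+") {
      win_start <- tu$start
      win_end <- min(tu$start + sense_max, len)
      sense_seq <- seq_slice(seqs[[tu$chrom]], win_start, win_end)
    } else {
      win_start <- max(tu$end - sense_max, 0L)
      win_end <- tu$end
      sense_seq <- revcomp(seq_slice(seqs[[tu$chrom]], win_start, win_end))
    }
    runs <- sense_t_runs(sense_seq, min_run)
    if (!nrow(runs)) return(NULL)
    first <- offset_to_pos(tu$start, tu$end, tu$strand, runs$offset)
    tibble(
      tu_id = tu$tu_id, chrom = tu$chrom,
      start = as.integer(if (tu$strand == "+") first else
        first - runs$run_length + 1L),
      end = as.integer(if (tu$strand == "+") first + runs$run_length else
        first + 1L),
      strand = tu$strand, run_length = runs$run_length,
      sense_offset = runs$offset
    )
  })
  out <- list_rbind(out[!map_lgl(out, is.null)])
  structure(out, class = c("t_run_set", class(out)),
            min_run = as.integer(min_run))
}

#' Assign T-runs to distance bins from their TU's TSS
#'
#' Each run goes to the bin containing its sense start distance from the
#' TU's TSS; runs beyond the last bin are dropped and counted.
#'
#' @param runs A `t_run_set` from [find_t_runs()].
#' @param bins List of `c(lo, hi)` pairs in kilobases, non-overlapping
#'   (default the four 1-kb bins from 0 to 4 kb).
#' @return The runs tibble with a `bin` factor column; attribute
#'   `n_dropped`.
#' @export
motif_distance_bins <- function(runs,
                                bins = list(c(0, 1), c(1, 2),
                                            c(2, 3), c(3, 4))) {
  bins_tb <- tibble(
    lo = map_dbl(bins, 1) * 1000,
    hi = map_dbl(bins, 2) * 1000
  ) |> arrange(.data$lo)
  if (any(bins_tb$hi <= bins_tb$lo)) abort("each bin needs lo < hi")
  if (nrow(bins_tb) > 1 &&
      any(bins_tb$lo[-1] < bins_tb$hi[-nrow(bins_tb)])) {
    abort("bins overlap")
  }
  labels <- sprintf("(%g,%g]kb", bins_tb$lo / 1000, bins_tb$hi / 1000)
  d <- runs$sense_offset
  bin_idx <- rep(NA_integer_, length(d))
  for (j in seq_len(nrow(bins_tb))) {
    inside <- if (j == 1L) {
      d >= bins_tb$lo[j] & d <= bins_tb$hi[j]
    } else {
      d > bins_tb$lo[j] & d <= bins_tb$hi[j]
    }
    bin_idx[is.na(bin_idx) & inside] <- j
  }
  out <- runs
  out$bin <- factor(labels[bin_idx], levels = labels)
  dropped <- sum(is.na(bin_idx))
  out <- out[!is.na(bin_idx), , drop = FALSE]
  structure(out, class = unique(c("binned_runs", class(out))),
            n_dropped = dropped, bin_labels = labels)
}

#' Fold-change meta-curve over binned T-runs
#'
#' For each distance bin, runs are length-normalised onto a common axis of
#' `body_bins` positions with `flank` fixed bases on each side, and the mean
#' log2 change per meta-position is returned. Positions absent from the
#' fold-change track contribute 0 (the log2 of pseudocount over
#' pseudocount). Empty bins yield NA curves, flagged by `n_runs = 0`.
#'
#' @param fc An `fc_track` from [log2_ratio_track()].
#' @param runs_binned Output of [motif_distance_bins()].
#' @param flank Fixed flank width in bases (default 10).
#' @param body_bins Number of normalised positions over the run body.
#' @return Tibble: `bin`, `metapos`, `segment`
#'   (`upstream`/`body`/`downstream`), `mean_log2fc`, `n_runs`.
#' @export
fc_over_motifs <- function(fc, runs_binned, flank = 10L, body_bins = 6L) {
  if (!inherits(runs_binned, "binned_runs")) {
    abort("`runs_binned` must come from motif_distance_bins()")
  }
  fc_tb <- as_tibble(fc) |> select("chrom", "pos", "strand", "log2fc")
  fc_map <- setNames(fc_tb$log2fc,
                     paste(fc_tb$chrom, fc_tb$pos, fc_tb$strand))
  labels <- attr(runs_binned, "bin_labels")
  n_meta <- 2L * flank + body_bins
  segment <- c(rep("upstream", flank), rep("body", body_bins),
               rep("downstream", flank))

  run_curve <- function(r) {
    L <- r$run_length
    # Sense-ordered genomic positions of the run body.
    body_pos <- if (r$strand == "+") seq.int(r$start, r$end - 1L) else
      seq.int(r$end - 1L, r$start)
    up_pos <- if (r$strand == "+") seq.int(r$start - flank, r$start - 1L) else
      seq.int(r$end + flank - 1L, r$end)
    dn_pos <- if (r$strand == "+") seq.int(r$end, r$end + flank - 1L) else
      seq.int(r$start - 1L, r$start - flank)
    lookup <- function(p) {
      v <- unname(fc_map[paste(r$chrom, p, r$strand)])
      v[is.na(v)] <- 0
      v
    }
    sizes <- rep(L %/% body_bins, body_bins)
    rem <- L %% body_bins
    if (rem) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    vals <- lookup(body_pos)
    idx_end <- cumsum(sizes)
    idx_start <- c(1L, head(idx_end, -1L) + 1L)
    body_vals <- map_dbl(seq_len(body_bins), function(b) {
      if (sizes[b] == 0L) return(NA_real_)
      mean(vals[idx_start[b]:idx_end[b]])
    })
    c(lookup(up_pos), body_vals, lookup(dn_pos))
  }

  out <- map(labels, function(lb) {
    rb <- runs_binned[runs_binned$bin == lb, , drop = FALSE]
    if (!nrow(rb)) {
      return(tibble(bin = lb, metapos = seq_len(n_meta), segment = segment,
                    mean_log2fc = NA_real_, n_runs = 0L))
    }
    curves <- vapply(seq_len(nrow(rb)), function(i) run_curve(rb[i, ]),
                     numeric(n_meta))
    tibble(bin = lb, metapos = seq_len(n_meta), segment = segment,
           mean_log2fc = rowMeans(curves, na.rm = TRUE), n_runs = nrow(rb))
  })
  out <- list_rbind(out)
  out$bin <- factor(out$bin, levels = labels)
  out
}
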