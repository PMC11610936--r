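# Scaled metagene and downstream-region matrices.

# Normalise any supported track to (chrom, pos, strand, value).
track_values <- function(track) {
  if (inherits(track, "end_profile")) {
    tb <- normalize_cpm(track)
    return(tibble(chrom = tb$chrom, pos = tb$pos, strand = tb$strand,
                  value = tb$cpm))
  }
  tb <- as_tibble(track)
  vcol <- if ("log2fc" %in% names(tb)) "log2fc"
    else if ("cpm" %in% names(tb)) "cpm"
    else if ("value" %in% names(tb)) "value"
    else if ("count" %in% names(tb)) "count"
    else abort("track needs a log2fc, cpm, value or count column")
  tibble(chrom = tb$chrom, pos = tb$pos, strand = tb$strand,
         value = as.numeric(tb[[vcol]]))
}

new_meta_matrix <- function(mat, axis, tu_ids, excluded = character()) {
  structure(
    list(matrix = mat, axis = axis, tu_ids = tu_ids, excluded = excluded),
    class = "meta_matrix"
  )
}

#' @export
print.meta_matrix <- function(x, ...) {
  cat(sprintf("<meta_matrix> %d TUs x %d meta-positions (%d excluded)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$excluded)))
  invisible(x)
}

#' @export
tidy.meta_matrix <- function(x, ...) {
  mat <- x$matrix
  tibble(
    tu_id = rep(rownames(mat), each = ncol(mat)),
    metapos = rep(x$axis$metapos, times = nrow(mat)),
    segment = rep(x$axis$segment, times = nrow(mat)),
    value = as.vector(t(mat))
  )
}

#' @export
glance.meta_matrix <- function(x, ...) {
  tibble(n_tus = nrow(x$matrix), n_meta = ncol(x$matrix),
         n_excluded = length(x$excluded),
         grand_mean = mean(x$matrix))
}

tu_sense_values <- function(vmap, chrom, strand, positions) {
  v <- unname(vmap[paste(chrom, positions, strand)])
  v[is.na(v)] <- 0
  v
}

#' Scaled metagene matrix over TU bodies and fixed flanks
#'
#' Sense-oriented per-TU signal: `upstream_bp` unscaled bases before the
#' TSS, the gene body length-normalised into `body_bins` bins (mean within
#' bin; bin edges by equal base partition, remainder spread left to right),
#' and `downstream_bp` unscaled bases past the TES. Positions absent from
#' the track contribute 0. TUs shorter than `body_bins` bases are excluded
#' from the matrix and the mean curve, and reported in `excluded`.
#'
#' @param track An [end_profile()] (scaled to CPM), an `fc_track`, or any
#'   tibble with `chrom`, `pos`, `strand` and a value column.
#' @param tus Annotation tibble.
#' @param upstream_bp,downstream_bp Unscaled flank widths in bases.
#' @param body_bins Number of length-normalised body bins.
#' @return A `meta_matrix` (rows = TUs, in input order) whose `axis` tibble
#'   labels each column; use [tidy()] for a long view and `colMeans` of
#'   `$matrix` (or [plot_metaprofile()]) for the mean curve.
#' @export
scaled_metaprofile <- function(track, tus, upstream_bp = 200L,
                               body_bins = 100L, downstream_bp = 3000L) {
  tb <- track_values(track)
  vmap <- setNames(tb$value, paste(tb$chrom, tb$pos, tb$strand))
  n_meta <- upstream_bp + body_bins + downstream_bp
  axis <- tibble(
    metapos = seq_len(n_meta),
    segment = c(rep("upstream", upstream_bp), rep("body", body_bins),
                rep("downstream", downstream_bp))
  )
  excluded <- character()
  rows <- matrix(NA_real_, nrow = nrow(tus), ncol = n_meta,
                 dimnames = list(tus$tu_id, NULL))
  for (i in seq_len(nrow(tus))) {
    tu <- tus[i, ]
    L <- tu$end - tu$start
    if (L < body_bins) {
      excluded <- c(excluded, tu$tu_id)
      next
    }
    sense_off <- seq.int(-upstream_bp, L + downstream_bp - 1L)
    pos <- offset_to_pos(tu$start, tu$end, tu$strand, sense_off)
    v <- tu_sense_values(vmap, tu$chrom, tu$strand, pos)
    up <- v[seq_len(upstream_bp)]
    body <- v[upstream_bp + seq_len(L)]
    down <- v[upstream_bp + L + seq_len(downstream_bp)]
    sizes <- rep(L %/% body_bins, body_bins)
    rem <- L %% body_bins
    if (rem) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    idx_end <- cumsum(sizes)
    idx_start <- c(1L, head(idx_end, -1L) + 1L)
    body_binned <- map_dbl(seq_len(body_bins), function(b) {
      mean(body[idx_start[b]:idx_end[b]])
    })
    rows[i, ] <- c(up, body_binned, down)
  }
  keep <- !tus$tu_id %in% excluded
  new_meta_matrix(rows[keep, , drop = FALSE], axis, tus$tu_id[keep],
                  excluded)
}

#' Per-TU downstream-of-TES signal matrix
#'
#' Per-base values over `[TES, TES + window)` in sense orientation, one row
#' per TU. With `sort_rows = TRUE` rows are ordered by decreasing row sum;
#' the sort is stable, so equal row sums keep input order.
#'
#' @inheritParams scaled_metaprofile
#' @param window Downstream window in bases (> 0).
#' @param sort_rows Order rows by decreasing row sum.
#' @return A `meta_matrix` with one column per downstream base.
#' @export
downstream_heatmap <- function(track, tus, window = 3000L,
                               sort_rows = FALSE) {
  if (window <= 0) abort("`window` must be > 0")
  tb <- track_values(track)
  vmap <- setNames(tb$value, paste(tb$chrom, tb$pos, tb$strand))
  axis <- tibble(metapos = seq_len(window),
                 segment = rep("downstream", window))
  mat <- matrix(NA_real_, nrow = nrow(tus), ncol = window,
                dimnames = list(tus$tu_id, NULL))
  for (i in seq_len(nrow(tus))) {
    tu <- tus[i, ]
    L <- tu$end - tu$start
    sense_off <- seq.int(L, L + window - 1L)
    pos <- offset_to_pos(tu$start, tu$end, tu$strand, sense_off)
    mat[i, ] <- tu_sense_values(vmap, tu$chrom, tu$strand, pos)
  }
  if (sort_rows) {
    mat <- mat[order(-rowSums(mat)), , drop = FALSE]
  }
  new_meta_matrix(mat, axis, rownames(mat))
}
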