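# broom-style views of result objects.

#' @export
tidy.end_call_set <- function(x, ...) as_tibble(x)

#' @export
glance.end_call_set <- function(x, ...) {
  tibble(
    n_calls = nrow(x), min_log2 = attr(x, "min_log2"),
    min_count = attr(x, "min_count"), pseudocount = attr(x, "pseudocount"),
    treatment = attr(x, "treatment"), control = attr(x, "control")
  )
}

#' @export
tidy.kmer_table <- function(x, ...) as_tibble(x)

#' @export
glance.kmer_table <- function(x, ...) {
  tibble(
    k = attr(x, "k"), n_kmers = nrow(x), n_calls = attr(x, "n_calls"),
    n_skipped = attr(x, "n_skipped"), weight = attr(x, "weight"),
    top_kmer = if (nrow(x)) x$kmer[1] else NA_character_
  )
}

#' @export
tidy.region_signal_table <- function(x, ...) as_tibble(x)

#' @export
glance.region_signal_table <- function(x, ...) {
  tibble(
    n_tus = nrow(x), pseudocount = attr(x, "pseudocount"),
    downstream_window = attr(x, "downstream_window"),
    body_down_cor = if (nrow(x) >= 3) body_downstream_fc_correlation(x)
      else NA_real_
  )
}

#' @export
glance.ground_truth <- function(x, ...) {
  mech <- table(x$events$mechanism)
  tibble(
    condition = x$condition, n_polymerases = nrow(x$events),
    n_rna_ends = nrow(x$rna_ends),
    n_dna_directed = sum(x$events$mechanism == "dna_directed"),
    n_torpedo = sum(x$events$mechanism == "torpedo"),
    n_attenuation = sum(x$events$mechanism == "attenuation"),
    n_runoff = sum(x$events$mechanism == "runoff")
  )
}
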