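#' Load a sample manifest and its tracks
#'
#' The manifest is a YAML file mapping samples to conditions, assay flavors,
#' EPAP status, bedGraph pairs and paired controls:
#'
#' ```yaml
#' genome: genome.fa
#' annotation: annotation.bed
#' samples:
#' - sample_id: CTRL_three_prime_plusEPAP
#'   condition: CTRL
#'   flavor: three_prime
#'   epap: yes
#'   plus: CTRL_three_prime_plusEPAP.plus.bedgraph
#'   minus: CTRL_three_prime_plusEPAP.minus.bedgraph
#'   control: ~
#' ```
#'
#' Relative paths are resolved against the manifest's directory. Every
#' depletion sample must name an existing control sample of matching flavor
#' and EPAP status; dangling or mismatched control references are rejected.
#'
#' @param path Path to the manifest YAML.
#' @return A `sample_set`: list with `seq` (genome sequences), `tus`
#'   (annotation tibble), `samples` (tibble: sample_id, condition, flavor,
#'   epap, control) and `profiles` (named list of [end_profile()]s).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (key in c("genome", "annotation", "samples")) {
    if (is.null(man[[key]])) abort(sprintf("manifest lacks `%s`", key))
  }
  samples <- map(man$samples, function(s) {
    for (key in c("sample_id", "condition", "flavor", "plus", "minus")) {
      if (is.null(s[[key]])) {
        abort(sprintf("manifest sample lacks `%s`", key))
      }
    }
    tibble(
      sample_id = s$sample_id, condition = s$condition, flavor = s$flavor,
      epap = isTRUE(s$epap),
      plus = resolve(s$plus), minus = resolve(s$minus),
      control = if (is.null(s$control)) NA_character_ else s$control
    )
  }) |> list_rbind()
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample_id in manifest")
  }
  for (p in c(resolve(man$genome), resolve(man$annotation),
              samples$plus, samples$minus)) {
    if (!file.exists(p)) abort(sprintf("manifest references missing file: %s", p))
  }
  # Control linkage: must resolve, and be flavor/EPAP-compatible.
  with_ctrl <- samples[!is.na(samples$control), ]
  for (i in seq_len(nrow(with_ctrl))) {
    ctrl <- samples[samples$sample_id == with_ctrl$control[i], ]
    if (!nrow(ctrl)) {
      abort(sprintf("sample %s names missing control %s",
                    with_ctrl$sample_id[i], with_ctrl$control[i]))
    }
    if (ctrl$flavor != with_ctrl$flavor[i] || ctrl$epap != with_ctrl$epap[i]) {
      abort(sprintf(
        "sample %s and its control %s differ in flavor or EPAP status",
        with_ctrl$sample_id[i], with_ctrl$control[i]
      ))
    }
  }
  profiles <- setNames(
    map(seq_len(nrow(samples)), function(i) {
      read_bedgraph_pair(samples$plus[i], samples$minus[i],
                         flavor = samples$flavor[i], epap = samples$epap[i],
                         sample_id = samples$sample_id[i],
                         condition = samples$condition[i])
    }),
    samples$sample_id
  )
  structure(
    list(
      seq = read_fasta(resolve(man$genome)),
      tus = read_annotation(resolve(man$annotation)),
      samples = select(samples, "sample_id", "condition", "flavor", "epap",
                       "control"),
      profiles = profiles
    ),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples, %d TUs, genome %s bp\n",
              nrow(x$samples), nrow(x$tus),
              paste(nchar(x$seq), collapse = "+")))
  print(x$samples)
  invisible(x)
}
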