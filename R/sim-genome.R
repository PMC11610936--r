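#' Build a synthetic genome with planted termination elements
#'
#' Draws a random background sequence from the configured base composition
#' and writes every planted element onto the coding strand of its TU:
#' T-tract terminators (appearing as A-runs on the reference for minus-strand
#' TUs), G-rich pause elements downstream of TESs, and an AATAAA hexamer
#' ending 20 bases upstream of the TES of PAS-bearing TUs. The annotation
#' records TSS, TES, strand, biotype and exon count for every TU; the
#' registry records the reference coordinates of every planted element with
#' its ground-truth label.
#'
#' @param config A [sim_config()] object.
#' @return A `synthetic_genome`: list with `seq` (named character vector of
#'   chromosome sequences), `tus` (tibble: tu_id, chrom, start, end, strand,
#'   biotype, exon_count, pas_score), `registry` (tibble of planted elements)
#'   and `config`.
#' @examples
#' cfg <- sim_config(list(tu_spec("mono_nc", 800,
#'   planted_terminators = tibble::tibble(offset = 500L, run_length = 6L))))
#' g <- build_synthetic_genome(cfg)
#' g$registry
#' @export
build_synthetic_genome <- function(config) {
  config <- validate_sim_config(config)
  chrom <- "chrS"
  bases <- withr::with_seed(config$seed, {
    sample(DNA_BASES, config$genome_length, replace = TRUE,
           prob = config$base_composition[DNA_BASES])
  })

  plant <- function(bases, start, width, sense_seq, strand) {
    # start: reference 0-based position of the sense-first base.
    if (strand == "+") {
      idx <- seq.int(start, length.out = width) + 1L
      bases[idx] <- strsplit(sense_seq, "", fixed = TRUE)[[1]]
    } else {
      idx <- seq.int(start - width + 1L, length.out = width) + 1L
      bases[idx] <- strsplit(revcomp(sense_seq), "", fixed = TRUE)[[1]]
    }
    bases
  }

  registry <- list()
  tus <- list()
  for (spec in config$tu_specs) {
    start <- spec$start
    end <- spec$start + spec$body_length
    elements <- list()

    if (nrow(spec$planted_terminators)) {
      term <- spec$planted_terminators
      elements[[length(elements) + 1L]] <- tibble(
        type = "terminator",
        offset = term$offset,
        width = term$run_length,
        sense_seq = strrep("T", term$run_length)
      )
    }
    if (length(spec$planted_pause_sites)) {
      elements[[length(elements) + 1L]] <- tibble(
        type = "pause",
        offset = spec$body_length + spec$planted_pause_sites,
        width = nchar(config$pause_seq),
        sense_seq = config$pause_seq
      )
    }
    if (spec$pas_strength > 0 && spec$body_length > 30) {
      elements[[length(elements) + 1L]] <- tibble(
        type = "pas_signal", offset = spec$body_length - 26L, width = 6L,
        sense_seq = "AATAAA"
      )
    }
    if (spec$has_three_prime_box) {
      elements[[length(elements) + 1L]] <- tibble(
        type = "three_prime_box", offset = spec$body_length + config$box_offset,
        width = 0L, sense_seq = ""
      )
    }
    el <- if (length(elements)) bind_rows(elements) else
      tibble(type = character(), offset = integer(), width = integer(),
             sense_seq = character())

    # Reject overlapping planted elements of the same TU.
    seq_el <- el[el$width > 0L, ]
    if (nrow(seq_el) > 1L) {
      o <- order(seq_el$offset)
      so <- seq_el$offset[o]
      se <- so + seq_el$width[o]
      if (any(so[-1L] < se[-length(se)])) {
        abort(sprintf("TU %s: planted elements overlap", spec$tu_id))
      }
    }

    for (j in seq_len(nrow(el))) {
      if (el$width[j] > 0L) {
        pos0 <- offset_to_pos(start, end, spec$strand, el$offset[j])
        bases <- plant(bases, pos0, el$width[j], el$sense_seq[j], spec$strand)
      }
    }

    sense_first <- offset_to_pos(start, end, spec$strand, el$offset)
    registry[[length(registry) + 1L]] <- tibble(
      tu_id = spec$tu_id,
      chrom = chrom,
      type = el$type,
      sense_offset = el$offset,
      start = if (spec$strand == "+") sense_first else
        sense_first - pmax(el$width - 1L, 0L),
      end = if (spec$strand == "+") sense_first + pmax(el$width, 1L) else
        sense_first + 1L,
      strand = spec$strand,
      run_length = ifelse(el$type == "terminator", el$width, NA_integer_)
    )
    tus[[length(tus) + 1L]] <- tibble(
      tu_id = spec$tu_id, chrom = chrom, start = start, end = end,
      strand = spec$strand, biotype = spec$biotype,
      exon_count = spec$exon_count, pas_score = spec$pas_strength
    )
  }

  structure(
    list(
      seq = setNames(paste(bases, collapse = ""), chrom),
      tus = bind_rows(tus),
      registry = if (length(registry)) bind_rows(registry) else
        tibble(tu_id = character(), chrom = character(), type = character(),
               sense_offset = integer(), start = integer(), end = integer(),
               strand = character(), run_length = integer()),
      config = config
    ),
    class = "synthetic_genome"
  )
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d bp (%s), %d TUs, %d planted elements\n",
              nchar(x$seq[[1]]), names(x$seq)[1], nrow(x$tus),
              nrow(x$registry)))
  invisible(x)
}
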