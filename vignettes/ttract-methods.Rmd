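---
title: "Detecting DNA-directed RNAPII termination from RNA 3' end profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting DNA-directed RNAPII termination from RNA 3' end profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttract)
library(dplyr)
```

## The problem

Mammalian RNA polymerase II terminates transcription by more than one
route. At most protein-coding genes, cleavage of the nascent RNA at the
polyadenylation site (PAS) lets the 5'→3' exonuclease XRN2 chase and
dislodge the polymerase — the *torpedo* mechanism. A second, *DNA-directed*
route needs no RNA cleavage at all: immature elongation complexes terminate
directly over runs of thymidines on the coding DNA strand (the nascent RNA
then carries a U-run, a thermodynamically weak dA:rU hybrid), the same
signal that terminates bacterial RNAP and eukaryotic RNAP III. The
DNA-directed route dominates promoter-proximally, at snRNA and other short
noncoding loci, and downstream of weak or uncleaved PASs; its released
products are nonadenylated and rapidly destroyed by the nuclear exosome, so
they become visible only when the exosome (EXOSC3) is depleted and when
3'-end libraries are tailed in vitro by *E. coli* poly(A) polymerase
(EPAP).

`ttract` implements the computational side of detecting this mechanism from
stranded single-nucleotide RNA 3'-end count tracks across factor-depletion
conditions, together with a stochastic simulator that generates complete
desk-scale inputs with ground truth. Everything downstream of read
alignment is covered: normalisation, per-base differential tracks,
stabilised-end calling, terminal-motif statistics, distance-binned
meta-analysis, region-level TU selection, and metagene profiles.

## The detection model

For a paired depletion/control library the pipeline works on counts per
million mapped ends (CPM). At every position covered in either sample the
per-base log2 change is

$$\mathrm{lfc}(i) = \log_2 \frac{\mathrm{cpm}_T(i) + c}{\mathrm{cpm}_C(i) + c},$$

with a pseudocount $c$ (default 1 CPM) recorded on every result. A position
is a *stabilised end* when $\mathrm{lfc} \ge 1$ (the depletion at least
doubles its normalised signal) and the raw treatment count reaches
`min_count`. No per-position hypothesis test is computed: the thresholds
are hard fold-change cuts, declared openly rather than dressed up as
p-values, which also keeps calls reproducible across library sizes
(jointly rescaling both libraries leaves CPM ratios unchanged, exactly).

Called ends are then summarised three ways:

* **Terminal k-mers** (`count_terminal_kmers()`): the k bases ending at
  (and including) each called position, read on the call's own strand —
  i.e. the last k nucleotides of the transcript with U written as T.
  Default k = 6, a deliberately conservative choice given that four or
  more Ts suffice for RNAP III termination. Each unique position counts
  once by default; a count-weighted mode exists because published motif
  counts do not state whether multi-read ends were weighted. N-containing
  or boundary windows are skipped, never imputed, and the skip count is
  recorded so totals are conserved.
* **Background-corrected T fraction** (`t_fraction_statistic()`): the
  fraction of called ends whose terminal base is T must be judged against
  the coding-strand T frequency of the searched regions; the package
  reports both fractions and the z statistic of their difference under
  independent binomial sampling.
* **Distance-binned meta-curves** (`find_t_runs()`,
  `motif_distance_bins()`, `fc_over_motifs()`): maximal coding-strand
  T-runs (default T6 and longer) are located inside each TU's search
  window, binned by sense distance from the TSS (0–1, 1–2, 2–3, 3–4 kb),
  and the mean log2 change is profiled over a length-normalised run axis
  with 10 fixed flanking bases. A decline of the curves with TSS distance
  is the signature of elongation-complex maturation.

Region-level statistics mirror the figure-style analyses: strand-aware
body (TSS–TES) and downstream (TES + 3 kb by default) CPM sums per TU
(`region_signal()`); the selection of TUs whose flank is stabilised
(log2 ≥ 1.5) *without* a gene-body increase (log2 ≤ 0.5,
`select_flank_stabilized_tus()`) — the filter that isolates short
protein-coding genes using DNA-directed termination downstream of their
PAS; the Pearson correlation of body versus downstream changes
(`body_downstream_fc_correlation()`), which is near 1 when a depletion
scales transcription as a whole (an attenuation/flux effect, as under
Integrator loss) rather than moving signal into the flank; and positional
concordance between call sets (`end_position_concordance()`), reported
directionally and as the symmetric mean, either within a ±tolerance window
(default ±0, exact base) or in binned mode — both modes ship because the
choice is not uniquely determined by the quantity's informal definition.

## The simulator

`sim_config()` + `build_synthetic_genome()` + `simulate_polymerases()` +
`render_end_profile()` generate all inputs. The generative model encodes
the mechanistic picture quantitatively:

* Each polymerase starts at its TU's TSS. With probability
  `attenuation_p` (default 0.3) it is attenuated by Integrator and
  releases its RNA within the promoter-proximal pausing zone (geometric,
  mean 150 bases, truncated at 250 — Integrator acts on
  promoter-proximally paused polymerases, so release points do not reach
  into the gene body). Under `dINT` attenuation is off, which raises the
  downstream flux by $1/(1-p)$ without touching any termination mechanism.
* At every maximal coding-strand T-run of length $L$ at sense distance $d$
  from the TSS — planted or arising by chance in the background sequence —
  the polymerase terminates with probability
  $1 - (1 - p_T \cdot 2^{-d/h})^L$, a per-T hazard ($p_T$ = 0.15 at the
  promoter) that halves every $h$ = `maturation_halfdist` bases (default
  1 kb) as the elongation complex matures. Within a run, the stop position
  follows the truncated geometric law implied by the per-T hazard.
  Released products are nonadenylated exosome substrates.
* At the TES of PAS-bearing TUs the RNA is cleaved with probability
  `pas_strength`, releasing an adenylated mRNA 3' end; the polymerase
  continues and is caught by the XRN2 torpedo after a geometric chase
  (mean 300 bases), snapping to a planted G-rich pause element within
  100 bases if one is near. Under `dXRN2` the torpedo is disabled;
  cleaved polymerases remain subject to downstream T-run hazards and
  otherwise run off at TES + 5 kb. snRNA-like TUs are instead cleaved
  (without terminating) at a 3' box 12 bases past the TES (off under
  `dINT`); the upstream product is a stable matured RNA.
* Rendering applies the assay's detection model. 3'-seq: adenylated ends
  are seen with or without EPAP; nonadenylated ends only with EPAP;
  released exosome substrates survive detection with probability
  `exosome_survival` (default 0.2) while the exosome is active and always
  once it is depleted. POINT5-analog: capped TSS 5' ends plus 3'-box and
  PAS cleavage-product 5' ends (the latter eroded by active XRN2).
  mNET-analog: an occupancy snapshot of *engaged* polymerases — one
  uniformly drawn trajectory position per polymerase plus dwell-weighted
  counts at crossed pause sites (8-fold dwell for PAS-cleaved "sitting
  ducks" when XRN2 is absent). Polymerases already released by
  termination have left the template and leave no active-site footprint;
  this is why T-tracts, despite carrying termination flux, do not
  accumulate active-site signal.

Every stochastic step runs on a stream derived from the configuration
seed, one stream per (condition) and per (sample, flavor), so adding a
sample never perturbs existing ones and identical seeds give byte-identical
bundles. Coordinates are 0-based half-open throughout, on minus-strand TUs
offsets are measured 5'→3' along the TU and mapped through the reverse
complement, and planted T-tracts therefore appear as A-runs in the
reference.

### What the simulator does and does not emulate

It reproduces the statistical structure the analysis relies on: point
pileups of 3' ends at termination positions, EPAP-gated visibility of
nonadenylated ends, condition-dependent stabilisation, distance-decaying
DNA-directed termination, and G-rich pausing downstream of cleaved PASs.
It does not model read-level artefacts (sequencing error, mappability,
internal priming), chromatin, replicate dispersion, or spike-in
normalisation. Tests passing on synthetic data therefore demonstrate the
correctness and calibration of the *pipeline*, not the biological accuracy
of any particular real-data analysis.

### Default study conditions

The reference panel (`tu_panel_default()`, 24 TUs) mixes snRNA-like,
monoexonic noncoding, short protein-coding, long multiexonic and
replication-dependent-histone-like TUs on both strands, with T6
terminators at realistic sense distances, G-rich pause elements downstream
of PAS-bearing TES, and 300 polymerases per TU per condition (≥ 50
termination events per proximal terminator). The distance panel
(`tu_panel_distance()`, 42 long TUs × 120 polymerases ≥ 5000) plants one
T6 tract in each kilobase bin out to 4 kb. Base composition is uniform;
incidental T4+ runs in the random background are deliberately kept as
hazard-bearing (the sequence, not the registry, is the source of truth),
which adds realistic "unplanted" termination signal. These sizes keep the
full test suite under a minute of simulation while leaving wide
statistical margins; they are stated here as the package's reference
conditions.

## Numerical and design choices

* Pseudocount 1 CPM on both ratio arms; recorded in every output.
* Bin edges for scaled metaprofiles: equal base partition with the
  remainder spread left-to-right; mean within bin (not max), so uniform
  tracks stay exactly flat.
* Ties in k-mer ranking break lexicographically; ties in heat-map row
  sorting keep input order (stable sort).
* The "last detectable transcription position" downstream of a TES is
  operationalised as the most 3' position within 10 kb whose 21-base
  running-mean CPM exceeds a 0.1-CPM floor (`detect_transcription_end()`);
  width and floor are arguments.
* Degenerate inputs error loudly rather than being repaired: overlapping
  bedGraph intervals, negative or fractional counts, strand values outside
  {+,−}, empty call/region sets for the T-fraction statistic, flavor- or
  EPAP-mismatched sample pairs, overlapping planted elements, and
  overlapping distance bins are all rejected.
* Figures are drawn from result tibbles only (`plot_kmer_table()`,
  `plot_metaprofile()`, `plot_motif_meta()`, `autoplot()` methods); no
  analysis quantity is computed inside a plotting function.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(tu_panel_default(), seed = 1)
genome <- build_synthetic_genome(cfg)
truth_ctrl <- simulate_polymerases(genome, "CTRL")
truth_exo  <- simulate_polymerases(genome, "dEXOSC3", seed = 2001)
ctrl <- render_end_profile(truth_ctrl, "three_prime", epap = TRUE)
exo  <- render_end_profile(truth_exo,  "three_prime", epap = TRUE)

calls <- call_stabilized_ends(exo, ctrl)         # log2fc >= 1, count >= 1
count_terminal_kmers(calls, genome)              # TTTTTT ranks first
t_fraction_statistic(calls, genome, genome$tus)  # end T% >> genomic T%
```

The same path is scripted end-to-end by `run_simulate()` →
`run_analyze()` → `run_compare()`, or from a shell via
`inst/scripts/ttract-cli.R`.

## Known limitations

* Replicates are not modelled; the calling is per-pair with no dispersion
  estimation or shrinkage — by design, matching the hard-threshold
  analysis the package operationalises.
* "T-rich" is defined only through exact runs and terminal k-mers;
  degenerate elements (e.g. AT-tracts, which retain termination activity
  in reporter assays) are not given a separate detector.
* The per-base concordance statistic is sensitive to sampling noise at
  ±0 tolerance on sparse call sets; use a small tolerance or binned mode
  when comparing low-depth conditions.
* The torpedo/pause interplay is deliberately coarse (geometric chase,
  fixed dwell factor); the active-site channel is meant for qualitative
  contrasts, not kinetic inference.
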