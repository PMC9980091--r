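---
title: "Modeling and correcting ligation biases in ribosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and correcting ligation biases in ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboshift)
library(data.table)
```

## The problem

Ribosome profiling sequences the ~25-31 nt mRNA fragments protected by
translating ribosomes. At codon resolution, footprint counts are shaped by
two very different processes:

* **biology** — a ribosome dwells longer on some codons than others, mostly
  as a function of the codon being decoded in its A site (and, more weakly,
  the P and E sites), on top of transcript-level differences in mRNA
  abundance and initiation rate;
* **technique** — nuclease digestion stops at variable distances from the
  decoded codon, exposing different "bias sequences" at the fragment ends,
  and the ligases used in library construction strongly prefer some end
  sequences over others. A footprint's chance of making it into the library
  therefore depends on the transcript sequence around the ribosome, not just
  on where ribosomes sit.

Because the same codon always has the same sequence neighborhood, these
recovery artifacts masquerade as reproducible "pauses". riboshift separates
the two contributions with an explicit regression model and inverts the
technical part.

## The model

Footprint counts are aggregated by transcript $i$, A-site codon index $j$,
and digestion lengths $(d_5, d_3)$, where $d_5$ is the distance from the
read 5' end to the first nucleotide of the A-site codon and
$d_3 = \mathrm{length} - d_5 - 3$. Counts are modeled as negative binomial,

$$Y_{i,j,d_5,d_3} \sim \mathrm{NB}(\mu_{i,j,d_5,d_3}, \phi),
\qquad \mathrm{var}(Y) = \mu + \mu^2/\phi,$$

with log-mean

$$\log \mu = \beta_0
 + \beta^{t}_{i}
 + \beta^{A}_{A_{ij}} + \beta^{P}_{P_{ij}} + \beta^{E}_{E_{ij}}
 + \beta^{d_5}_{d_5} + \beta^{d_3}_{d_3}
 + \beta^{f_5}_{f_5} + \beta^{f_3}_{f_3}
 + \beta^{d_5:f_5}_{d_5,f_5} + \beta^{d_3:f_3}_{d_3,f_3}
 + \beta^{g}\, g_{i,j,d_5,d_3}.$$

Here $f_5$ is the first $k$ (default 3, configurable to 2) transcript
nucleotides under the footprint, $f_3$ the last three, and $g$ the GC
fraction of the footprint excluding the nine E/P/A-site nucleotides (a crude
proxy for structure-dependent recovery). The transcript factor absorbs
abundance and initiation; the A/P/E blocks absorb decoding speed; everything
else is technical. Interactions between digestion length and bias sequence
capture nuclease sequence preference and untemplated-addition effects.

All categorical terms use treatment coding with the lexicographically first
observed level as the reference, so every reported coefficient is a log
ratio against that reference level.

Bias sequences are always taken from the *transcript*, never from the read,
which makes featurization immune to sequencing errors, and all coordinates
are 0-based half-open with codon index 0 at the start AUG. With the
canonical yeast monosome rule — a 28-nt, frame-0 read has offset
$d_5 = 15$ — a read whose 5' end sits exactly on the start codon is
decoding codon index 5, the "sixth codon".

### Fitting

`fit_nb_glm()` maximizes the NB likelihood by alternating IRLS updates of
the coefficients (sparse Cholesky on the weighted normal equations) with a
one-dimensional golden-section maximization of $\phi$ at fixed mean, to a
relative log-likelihood tolerance of `1e-8` (at most 50 outer rounds). The
likelihood is evaluated through the gamma-function extension, so fractional
counts — sums of multi-mapping posterior weights — are legitimate responses.
Wald standard errors come from the expected information at the optimum,
conditional on $\hat\phi$, exactly as `MASS::glm.nb` reports them (the two
agree to ~1e-4 on integer data; `glm.nb` is used as a cross-check in the
test suite, never as the fitting engine).

Zero cells matter: without unobserved combinations the model cannot tell "a
disfavored end sequence" from "no ribosomes". The full covariate
cross-product is intractable, so `materialize_zero_cells()` fills in zeros
only over (selected transcript) x (codon inside the training range) x
(dataset-wide observed $(d_5, d_3)$ pair). Rare interaction cells can still
be collinear (e.g. a 3-mer observed under a single $d_3$); `build_design()`
drops such aliased columns with a warning, the same resolution `lm` applies
to inestimable levels.

### Training set

Technical biases are global, so the model is fit on a high-coverage subset:
transcripts with at least 5 mean footprints per codon and at least 100
covered codon positions are ranked by mean footprints per codon; 250 of the
top 500 are sampled uniformly (seeded), and the first and last 20 codons of
each are excluded to avoid initiation and termination effects. All of these
are arguments of `select_training_set()`.

## Correction factors

The technical blocks are inverted into a per-record multiplier:

$$\mathrm{factor}(r) = \exp\!\big(-[\,\beta^{f_5}(f_5) + \beta^{f_3}(f_3)
 + \beta^{d_5:f_5}(d_5,f_5) + \beta^{d_3:f_3}(d_3,f_3)
 + \beta^{g}(g - \bar g)\,]\big),$$

with $\bar g$ the count-weighted mean GC of the observed records, and the
corrected counts rescaled by a single constant so the total library size is
preserved exactly. The sign convention deserves a note: multiplying counts
by the *positive* exponent of the technical terms would amplify
over-represented sequences rather than shrink them, so riboshift uses the
multiplicative inverse, with GC mean-centered so that an average-GC record
at reference end sequences is left untouched — the form that demonstrably
lowers footprint-boundary signal on simulated data. Bias levels unseen in
training contribute neutrally (exponent 0) rather than erroring, since
held-out footprints legitimately contain k-mers the training subset lacks.
Correction is multiplicative and cannot restore counts to positions where
none were observed; no pseudocounts are added.

Disome (collided-ribosome) footprints are too sparse to model directly, but
share the library chemistry of the matched monosome library.
`aggregate_disome_counts()` featurizes each disome read with the lagging
ribosome's 5' end ($d_5$, $f_5$; offsets from start-codon metagenes) and the
leading ribosome's 3' end ($d_3$, $f_3$; offsets from stop-codon metagenes,
3'-anchored), with GC excluding both ribosomes' E/P/A codons, and
`correct_disome()` applies the monosome-learned factors.

## The simulator

`simulate_library()` draws footprints from the same generative story the
regression assumes: transcript ~ multinomial with user probabilities; A-site
position within the CDS proportional to the dwell weight of the codon at
that position; $(d_5, d_3)$ from user distributions; then a Bernoulli
retention with probability $r_5(f_5)\cdot r_3(f_3)$ — the two ends are
assumed independent. Draws repeat until exactly `library_size` footprints
are retained; footprints that would overrun the transcript are resampled so
interior sampling stays unbiased. The output is a reads table (optionally
FASTQ with truth-encoded read names) plus an exact truth table of
pre-retention and retained counts per cell.

`make_default_config()` encodes the study conditions used throughout the
tests:

* transcript probabilities: $\propto$ a log-linear decreasing function of
  transcript length with Poisson sampling noise (a parametric stand-in for
  abundance-vs-length fits to real data, so nothing needs downloading);
* codon dwell weights: log-normal, rescaled to an exact 8-fold range
  (within the 5-10x spread seen in codon-level dwell estimates);
* digestion: $d_5 \in 13..17$ with probabilities (0.1, 0.2, 0.4, 0.2, 0.1)
  and $d_3 \in 9..11$ with (0.2, 0.6, 0.2). The 5' end is raggeder than the
  3' end on purpose: a symmetric ±2 spread at both ends makes $(\mathrm{length},
  \mathrm{frame})$ ambiguous in $d_5$ (13+11 and 16+8 both give a 27-nt
  frame-2 read), which would poison every offset rule table; the asymmetric
  choice keeps rules exact while still pushing the 5' bias trimer across
  codons −4..−6 and the 3' trimer across +3/+4, where boundary artifacts
  appear in real data;
* recovery: per-k-mer probabilities uniform on [0.2, 1] on whichever ends
  the `bias_mode` (none / bias5 / bias3 / both) activates, 1.0 elsewhere.

What the simulator does *not* emulate: sequencing error, adapters and UMIs,
rRNA contamination, multi-mapping ambiguity, nuclease sequence preference
(digestion is independent of sequence), position-dependent dwell (initiation
ramps), or secondary-structure effects (recovery ignores GC). Passing tests
therefore demonstrate correctness of the estimator under its own generative
assumptions — parameter identifiability, debiasing power, null safety — not
robustness to every artifact of real libraries.

### Offset rules, truth vs. inference

`infer_offset_rules()` picks, per (length, frame) class, the candidate
offset in 12..18 (frame-compatible, ties toward 15) maximizing the
start-codon metagene signal — the count of reads whose implied A site lands
on the first two codons. In real data the initiation peak makes this
unambiguous. The default simulator has *no* initiation peak, so offsets o
and o−3 tie in expectation; simulation-driven analyses therefore assign A
sites with `true_offset_rules()` (exact by construction from the digestion
support), and offset inference is validated on simulations with an elevated
AUG dwell weight, which plays the role of the initiation peak. The same
logic, 3'-anchored at the stop codon (candidates 7..13, ties toward 10),
yields the leading-ribosome rules for disomes.

## Diagnostics

* **Position importance** (`position_importance()`): per-codon counts are
  summed over digestion lengths, scaled by the transcript mean
  (`scale_counts()`), and regressed on one-hot sequence features of the 13
  codons (or 39 nucleotides) centered on the A site. Importance of a
  position is the drop in in-sample Pearson correlation between fitted and
  observed values when that position's features are removed. Ligation bias
  shows up at the footprint boundaries (−6/−5 and +3/+4 under the default
  digestion); decoding shows up at 0. Because the fit is in-sample, pure
  noise yields a floor of roughly $p_{\mathrm{block}} / (2 r n)$ rather
  than exactly zero — with ~5e4 windows this is well below 0.01, but
  importance values at positions without genuine signal should be read
  against that floor, which is why the boundary debiasing check aggregates
  the four boundary positions rather than ratioing the noise-scale −6 value
  alone.
* **Start-codon metagene** (`metagene_5prime()`): 5'-end counts by offset
  from the start codon; corrected counts are redistributed to the 5'
  position implied by (codon index, $d_5$). Elevated 5' recovery of ATG
  produces a spurious peak at offset 0 — footprints starting exactly at the
  start codon, decoding the sixth codon — which correction removes.
  `metagene_peak_ratio()` compares the peak to in-frame downstream
  background, since the $d_5$ distribution imprints 3-nt periodicity.
* **Pause scores** (`codon_pause_scores()`): mean scaled count over all
  A-site occurrences of each codon. Aggregation over many sequence contexts
  averages ligation bias out, so raw and corrected scores agree closely —
  the correction matters for per-position distributions, not codon-level
  aggregates.
* **Mean-variance** (`mean_variance_diagnostic()`): per-position mean and
  variance across replicate libraries, with least-squares fits of
  $v = \mu$, $v = \theta\mu$ and $v = \mu + \mu^2/\phi$; overdispersed
  profiling data favor the quadratic law.

## Numerical and design choices

* Dispersion is parameterized as the NB "size" ($\mathrm{var} = \mu +
  \mu^2/\phi$) and reported as $\phi$, matching the mean-variance
  diagnostic.
* Reference levels are the lexicographically first observed level of each
  factor; exposed via the coefficient table (`coefficient_table()` includes
  reference rows at estimate 0).
* Differential occupancy (`fit_differential()`) adds a condition indicator
  (absorbing library size; no additional depth normalization) and per-codon
  A-site:condition interactions to a single joint fit, then Wald tests with
  Benjamini-Hochberg correction across the estimable codons.
* Records whose k-mers or codons contain N, and alignments that are
  reverse-strand, gapped, or shorter than offset+3, are dropped with
  logged counts; drops are data, not errors.
* Analysis scales used in the bundled checks, chosen once as realistic
  desk-scale study conditions: 100 transcripts (150-400 codons) at 5e5
  retained footprints for the biased scenarios — deep enough that
  coefficient noise sits well below the simulated 5-fold biases. The
  null-safety check ("correction must not touch unbiased data") instead
  uses a 4e6-read library: a Fisher-information estimate puts the 95th
  percentile of correction-factor noise at ~6-12% for 5e5 reads once the
  digestion-by-sequence interaction cells are included (rare cells hold only
  $N p_{d_5} / 64$ reads), which would measure estimator noise rather than
  improper adjustment; at 4e6 reads — an ordinary published depth — the
  floor drops to ~3-4%, below the 5% band the check asserts.
* The differential check uses 60 transcripts at 2e5 reads per condition
  with a 40-fold dwell change on one codon, comfortably detectable at that
  depth.

## Limitations

Correction quality is bounded by coefficient noise, so sparse libraries
gain little and can even become noisier per-record; like the underlying
method, riboshift is most appropriate for abundant transcripts in
high-coverage datasets. The GC term is a blunt instrument for structure
effects. Offset inference assumes a visible initiation peak, and disome
correction inherits whatever the monosome fit got wrong. None of the
bundled analyses touch real sequencing data; they establish correctness of
the machinery, not biological conclusions.
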