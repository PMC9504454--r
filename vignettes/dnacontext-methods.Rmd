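---
title: "Models and methods in dnacontext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dnacontext}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dnacontext` models the conditional distribution of a DNA base given its
flanking context and analyses what such models learn. This vignette explains
the models, the choices behind the defaults, and what the synthetic test
world does and does not establish.

## The prediction problem

For a position i with left and right flanks of F bases each (the focus base
itself excluded), a context model supplies p(base_i = x | context_i) over
x ∈ {A, C, G, T}. Prediction is the argmax, accuracy the fraction of
positions where the argmax equals the reference base. Positions are
**disqualified** when the context contains an N, the focus base is N, or the
position lies within F bases of a sequence end; they are excluded from
training and scoring. The focus-is-N rule is our addition: such a position
cannot be scored at all.

## The three model families

**Central model (flank k).** For every 2k-mer context the counts of the four
focus bases are accumulated over all qualified positions of the forward
strand; probabilities are the per-context frequencies. The dense table has
3·4^(2k) free parameters, but only observed contexts are stored, so large-k
fits on small genomes stay cheap. Contexts never seen in training predict
the uniform distribution (0.25 each) at apply time — the uniform fallback keeps
seen-context estimates exactly equal to frequencies, with no smoothing
assumed by default. An optional additive
pseudocount α (default 0) is available for users who prefer smoothing.

**Markov model (order k).** Identical machinery on the left k-mer only
(3·4^k dense parameters). Context codes are stored as doubles; tables are
refused once 4^(context size) exceeds 2^53, where integer arithmetic in
doubles would silently lose exactness.

**Neural model.** A one-hot encoding of the 2F context bases feeds one or
two valid convolutions with kernel length 3 or 4 (the "word encoding" of
tri-/quadro-nucleotides, ReLU activations), then one or more bidirectional
LSTM layers; the final forward and backward hidden states are concatenated,
optionally passed through a ReLU dense layer, and a 4-unit softmax emits the
distribution. Training minimizes categorical cross-entropy with mini-batch
Adam on a seeded random sample of qualified positions (single strand),
organized in rounds that each end with a validation pass on held-out,
disjoint positions. Because no deep-learning framework is available in the
target environment, the forward pass, backpropagation-through-time and Adam
are written directly in base R matrix code. This caps practical model sizes
far below GPU-scale architectures, which is deliberate: the package
demonstrates the method at desk scale, and matching any particular
large-model parameter count is not a goal.

**Bidirectional averaging.** Any model can be applied on both strands:
q(x) = ½[p_fwd(x | ctx) + p_rev(comp(x) | revcomp ctx)]. Since
complementation is a bijection of the outcomes, q is again a distribution.

### Neural defaults, and why

* `flankSize` — no default; tests use 3–5. For a synthetic order-k chain,
  F ≥ k already carries all information; real genomes motivate much larger
  flanks (50–200), far beyond CPU-R training budgets.
* `convFilters = 16`, `kernelSizes = 3`, `lstmUnits = 16` — the smallest
  shapes that reliably reach the entropy floor of low-order chains in
  minutes on one CPU.
* `learningRate = 0.005` with optional `learningRateDecay` — Adam at 0.01
  with decay 0.8/round converges to the two-sided entropy floor on 2 Mb
  order-2 genomes in ~12 rounds; a constant rate plateaus noticeably above
  it. Decay is the standard cure and is exposed as a config knob.
* The two flanks are processed jointly as one 2F sequence (left then right):
  joint processing is simpler than two towers, and the recurrent layers can
  learn the location of the focus gap between timesteps F and F+1.
* Reproducibility: all sampling flows through R's RNG from the config seed,
  so identical seeds with single-threaded BLAS reproduce training logs
  bit-for-bit; under multi-threaded BLAS only statistical reproducibility is
  promised.

## Evaluation

**Accuracy reports** count argmax hits over qualified positions, overall,
per chromosome (the overall value is their position-weighted mean) and per
annotation stratum; empty strata are reported as absent rather than zero.
Annotations come from BED via `rtracklayer` into `GRanges`; the soft-mask
(lower case in the FASTA) defines the repeat stratum.

**Reference-base probability arrays** hold, per position, the probability
the model assigned to the base actually present. Disqualified positions are
flagged and imputed with a constant (default 0.25) so downstream spectral
arrays are gap-free; the randomization controls treat those positions like
any others, which presumes they carry values.

**Density grids** are 2-D histograms of paired reference-base probabilities
on 50 equal bins per axis over [0,1]; bin edges are i/50 with the last bin
right-closed so probability 1.0 is counted.

**Vuong test.** For per-position log-likelihood differences d_i (numerator
minus denominator model), z = √n·mean(d)/sd(d) with a two-sided normal
p-value; sd(d) = 0 is a degenerate-test error. Genome-level values pool the
per-chromosome sufficient statistics (Σd, Σd², n), which is identical to
running the test on the union sample. The basic non-nested z statistic is
implemented (no variance correction for overlapping models). Log-likelihoods use natural log
with probabilities floored at 1e-12, and no multiple-testing correction is
applied. The standard protocol samples 10% of qualified positions per
chromosome with a seed.

## Spectral analysis

Each chromosome is segmented into adjacent 1 Mb pieces starting at position
0; the trailing remainder is dropped, and a segment is excluded when
strictly more than 10% of its positions are disqualified (exactly 10% stays
in). Each included segment's per-base array is discrete-Fourier transformed
(raw, unnormalized magnitudes — the simplest convention, and documented as
such). The
running-window statistic is the Euclidean norm of the magnitudes in a
window of `window` consecutive frequencies (default 1,000) advanced by
`step` (default 100) — the square root of the windowed power, i.e. a
cumulative power spectrum in a running window; plain summed power
is available via `power = TRUE`. Frequency 0 is always excluded: the
segment mean carries no periodicity and would dominate GC arrays. A
frequency window [f, f+w] on a segment of length L maps to periods
L/(f+w) … L/f with mid-frequency period L/(f+w/2), each rounded to the
nearest integer bp. Peak calling is deliberately minimal (`peakWindow()` is
an argmax helper); peak interpretation is left to visual inspection and no
significance machinery is promised.

**Controls.** `shuffleControl()` permutes the array (destroying phase
coherence while preserving the value multiset); `randomizeControl()`
replaces a chosen position subset with independent uniform draws. For a
planted unit cosine the post-shuffle noise floor of the windowed norm
scales as √(2·window/L) of the peak: at the standard scale (1 Mb, window
1,000) that is ≈4.5%, which is why the "peak abolished" checks in the tests
tie their array length to the window size.

## The synthetic world

`generateGenome()` samples from an order-0–3 Markov chain (uniform start,
burn-in negligible at Mb scale). Optional planted GC modulation reweights
each emission row so P(G or C at i) = baseline + amplitude·cos(2πi/period),
keeping within-class proportions — a single generative process rather than
an overlay, so oracle quantities remain computable away from the modulation
limit. Repeat copies are inserted afterwards at seeded non-overlapping
positions in lower case, and N blocks are overwritten last so masks are
unambiguous. The default test world is 2 Mb, order 2, 200 bp GC period
(amplitude 0.1, baseline 0.4), 50 copies of a 300-base motif — sized so the
full pipeline runs in minutes on one CPU.

Oracles are exact enumerations: `bayesAccuracy()` computes
Σ_ctx π(ctx)·max_x p(x|ctx) over all (2k+1)-mers with the chain's
stationary distribution (refused when k is below the generating order,
where the value would not be the Bayes bound), and `conditionalEntropy()`
gives the entropy rate over left k-mers or, with `context = "central"`, the
two-sided conditional entropy — the cross-entropy floor for a bidirectional
predictor. Note the ordering H(central) < H(left): a network that sees both
flanks should beat the Markov floor, and the tests check convergence
against the central floor.

What a green synthetic test does **not** establish: real genomes are not
low-order Markov chains — isochores, CpG depletion, interspersed repeat
families and centromeric structure are all absent here — so desk-scale
results say nothing about genome-wide accuracy on real reference genomes,
which is out of scope here.

## Numerical choices and degenerate inputs

* Coordinates are 0-based with half-open intervals, matching BED.
* IUPAC ambiguity codes other than A/C/G/T become N at parse time; the
  pipeline only distinguishes the four bases and N.
* Argmax ties break in fixed order A < C < G < T for determinism.
* Count-model context codes are exact doubles; fits are refused beyond 2^53
  possible contexts.
* A window wider than the available frequencies yields a single truncated
  window with a warning; an empty genome yields an empty mask; training
  aborts with a diagnostic on non-finite loss.
* Model files use R's native serialization (no HDF5 library is assumed),
  with TSV exports for human inspection.

## Limitations

* Neural training is CPU-bound R; flanks beyond ~10 and hidden sizes beyond
  ~100 are impractical. No pretrained weights ship.
* No Transformer, no back-off smoothing hierarchy, no variable-order
  models, no statistical significance testing of spectral peaks.
* The Vuong implementation is the basic non-nested z-test.
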