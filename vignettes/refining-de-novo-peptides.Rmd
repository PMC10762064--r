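---
title: "Refining de novo peptide sequences: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining de novo peptide sequences: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqmend)
```

## The problem

De novo peptide sequencing reads a peptide's sequence directly from a
tandem mass spectrum, without a protein database. Modern tools get most
residues right, but a single wrong residue makes the whole peptide wrong,
and the tools' own confidence scores separate correct from incorrect
peptides poorly. `seqmend` post-processes candidate peptides from any
such tool with three cooperating components:

1. **Bin reclassification.** A convolutional network predicts, for every
   1-Da m/z bin of the spectrum, the probability that it holds a singly
   charged b- or y-ion of the *correct* peptide, taking the candidate's
   own (possibly wrong) ion annotations as part of its input and learning
   to mend them.
2. **A PSM confidence score.** A random forest regresses
   `log2(d + 1)`, where `d` is the Levenshtein distance between the
   candidate and the correct peptide, from 114 features comparing
   predicted and observed fragment intensities and summarizing the bin
   reclassifier's suggested changes. Smaller predicted distance = higher
   confidence, so ranking PSMs by this score concentrates correct
   peptides at the top.
3. **Guided mutation and evolutionary search.** High-probability y-ion
   bins form a spectrum graph whose source (bin 19, water + proton) to
   target (precursor mass + proton) paths spell peptides; weighted random
   walks on this graph propose corrected candidates, and an elitist
   evolutionary algorithm with the score as fitness searches among them.

## Key modelling choices

### Masses, tokens, binning

Sequences are token vectors over the 20 canonical residues plus oxidized
methionine `"M(ox)"`; cysteine is treated as carbamidomethylated
throughout (fixed +57.02146 Da). Monoisotopic masses are tabulated to
five decimals (proton 1.00728 Da, water 18.01056 Da) because isobaric
arithmetic at 20 ppm needs sub-millidalton precision. Spectra are binned
at 1 Da up to 2000 Da with the floor convention — bin `b` covers
`[b, b + 1)` — which puts the y-ladder's origin (water + proton,
19.018 Da) in bin 19 and makes tryptophan, the heaviest residue, span
186 bins. The rounding convention for binning was genuinely open; floor
was chosen because it keeps those two integers exact.

### The AA-gapped convolution

Consecutive singly charged ions of one series are separated by exactly
one residue mass, i.e. by 57 to 186 bins — far beyond an ordinary local
convolution kernel. Each layer therefore aggregates, at bin `i` and for
every dilation `m` in the set of 18 distinct integer residue masses
(K/Q collide at 128, F/M(ox) at 147), weighted inputs from bins
`i - m`, `i`, `i + m`, zero-padded so the length dimension is constant.
Layers use batch normalization, ReLU and per-layer residual skips (the
skip topology was unstated in the design space; per-layer residuals are
the simplest choice satisfying it), with one shared trunk and two
sigmoid heads (b and y). Training minimizes binary focal loss
(`gamma = 2` by default, configurable; an optional `alpha` class weight
is off by default so that `gamma = 0` reduces exactly to cross-entropy)
with Adam, learning-rate reduction on validation plateau, and early
stopping.

Two presets are shipped. The full-scale configuration (16 layers x 20
filters, batch 512, learning rate 4e-5, dropout 0.3) reflects the
regime the architecture was designed for; the default `"desk"` preset
(4 layers x 8 filters, batch 64, learning rate 3e-3, up to 5 epochs)
trains in minutes on one CPU on a ~2,000-spectrum simulated study,
which is the problem size this package's own tests use. The forward and
backward passes are hand-written (shifted BLAS matrix products on a
sample-fastest memory layout; see `src/gapped_conv.cpp`) and verified
against finite differences in the test suite.

### Change probabilities

For downstream use the per-bin probability `p` is re-expressed as the
probability that the *final* label differs from the candidate's initial
label: `p` where the initial label is 0, `1 - p` where it is 1. The
alternative orientation (scoring agreement rather than change) reads
contradictorily with the notion of a "change" probability; the
implemented orientation makes a flipped initial bit flip its change
probability, which the suite tests as an invariant.

### The spectrum graph

b-ion probabilities are folded onto the y-ladder through the
complementarity identity `b_k + y_(n-k) = M + 2 * proton`, discretized
as `complement(b) = floor(M + 2 * proton) - b_bin`; a bin's node weight
is the larger of its y probability and its complemented b probability.
Bins above 0.35 become nodes (the operating point of the method), the
candidate's own y-bins are kept alive at weight 0.01, and edges connect
bins whose difference is an integer residue mass, labeled with every
matching residue. After pruning to the source-target path subgraph,
walks sample edges with probability proportional to the sum of the two
endpoint weights, normalized over the node's out-edges. Because edge
lengths telescope, every walk's residue-bin sum equals
`target - 19` exactly — the mass-closure invariant the acceptance suite
checks over a thousand walks.

One consequence of 1-Da discretization is worth stating: fractional
residue masses accumulate along a ladder, so for heavy peptides the true
ladder occasionally steps `floor(m) + 1` bins rather than `floor(m)`,
and no single-residue edge spans that step. This limits which peptides
the walks can reproduce exactly and is inherent to the 1-Da resolution,
not to this implementation.

### The 114 scoring features

For each ion group (all, b-only, y-only): normalized spectral angle,
Pearson correlation and cosine similarity between predicted and matched
experimental intensities; mean, standard deviation, minimum and maximum
of the absolute intensity differences plus their 5%–95% quantiles in 5%
steps (26 features); and the counts, absolute and relative to the
group's predicted peak count, of the four zero/nonzero predicted x
matched cells (8 features). Twelve further features count predicted bin
changes at thresholds 0.25–0.50 (strictly greater), for b and y
separately. The exact quantile grid and the per-ion-type split of the
change counts were open details; the grid above is the completion that
matches the stated feature families and the total of 114. Matching uses
the closest experimental peak within 20 ppm; both spectra are base-peak
normalized with intensities below 0.02 zeroed. Degenerate statistics
(constant vectors, empty groups) are imputed as 0 to keep the vector
finite.

The regressor is a `ranger` random forest on `log2(d + 1)`. The
full-scale optimum (86 trees, depth 175, 36 split candidates, minimum
node size 112) ships as the `"paper"` preset; the desk default (200
trees, minimum node size 5) suits a few thousand training PSMs, where a
minimum leaf of 112 would underfit badly.

### The evolutionary algorithm

Selection weights are `exp((f_i - f*) / T)` with fitness `f = -score`;
the score estimates a distance, so the sign convention is fixed by
requiring the fittest member to have weight 1 and all weights at most 1.
The temperature is not dictated by anything in the model; `T = 1` on the
`log2(d + 1)` scale is the neutral default and is configurable. Elites
(`n_e` best) pass unchanged; the remaining `n - n_e` slots are filled by
weighted draws with replacement (standard fitness-proportional practice;
drawing without replacement would couple the draws for no benefit), each
mutated by a single guided walk on its own spectrum-graph. Candidates
whose initial estimated distance lies outside `[1, 7]` are returned
unmodified: below 1 the candidate is probably already correct and search
only risks replacing it; above 7 the walks cannot bridge that much
corruption. Full-scale population parameters (n = 1024, elite 103, 5
generations) ship as the `"paper"` preset; the desk preset (64/7/5)
keeps a per-spectrum run in seconds. Ineligible inputs (length > 30,
charge > 6) are returned with the sentinel worst score `Inf` — the score
axis is a distance, so "worst" is maximal.

## What the simulator does and does not emulate

`simulate_dataset()` generates tryptic peptides (uniform length 7–30,
C-terminal K or R, 20% of methionines oxidized), charges from a
tryptic-like distribution dominated by 2+/3+, and spectra built from the
deterministic surrogate predictor: y-series stronger than b-series
(base 1.0 vs 0.5), a triangular positional intensity profile peaking
mid-sequence, charge-2 ions attenuated to 0.3. Noise comprises per-peak
dropout (default 0.10), Gaussian m/z jitter (5 ppm), Poisson
contamination peaks (mean 10 per spectrum) with exponential intensities
(mean 0.05 of base peak) uniform in m/z, and a random absolute scale.
Candidate corruption mixes a single isobaric window rewrite (50%), an
adjacent-residue swap (30%) and a composite of two operators (20%),
spanning true distances of roughly 1–6 — the band the evolutionary
algorithm's gate targets. Defaults were fixed once as plausible
desk-scale conditions and are not tuned per experiment.

The surrogate is deliberately *not* a learned intensity model: it has no
sequence-specific fragmentation effects (proline cleavage enhancement,
mobile-proton chemistry), no neutral losses, no isotope envelopes, no
precursor-mass error, and no chimeric spectra. Passing tests on
simulated data therefore demonstrate that the machinery — labeling,
training, graph search, scoring, selection — is correct and recovers
planted signal under realistic noise; they do not certify performance
on instrument data, which depends on plugging a real intensity
predictor into the registry (`register_predictor()`) and retraining.

## Numerical choices and degenerate inputs

* Peak matching: closest peak within `delta * M_theo`, `delta = 20` ppm;
  ties broken toward the smaller absolute difference.
* All-zero spectra are rejected at normalization; empty ion groups and
  constant vectors impute 0 into similarity features.
* Walks are capped at 35 edges (the maximum residue count reachable
  under 2000 Da is ~34 glycines) and resampled if the cap is hit.
* Spectra whose precursor-derived target bin falls outside the modeled
  range, and population members whose pruned graph has no source-target
  path, pass through the evolutionary step unmutated.
* Training splits are by unique peptide, so no peptide (hence no
  spectrum) is shared between train, validation and test.
* Candidates whose mass misses the precursor-derived mass by more than
  20 ppm are excluded from reclassifier training; at inference the
  initial candidate is only taken when its mass is within 1 Da,
  otherwise the next tool's candidate is used.

## Problem sizes used by the package's own checks

The test suite trains the desk preset on a seeded simulated study of
2,000 spectra (80/10/10 split by peptide) and checks: the trained
reclassifier's held-out y-ion ranking beats the corrupted initial labels
and a label-permuted null; the scorer's predicted distances correlate
with the true ones (Spearman > 0.6) and rank the correct peptide below
its corrupted sibling in over 80% of held-out pairs; and the
evolutionary search never regresses below the initial score while
improving a strictly positive fraction of corrupted candidates. These
desk-scale bars are internal regression bars, intentionally below what
the full-scale configuration reaches on real data.

## Known limitations

* One post-translational modification only (methionine oxidation);
  cysteine carbamidomethylation is fixed.
* One peptide per spectrum is assumed; chimeric spectra are out of
  scope.
* The graph operates at 1-Da resolution (see the carry caveat above).
* The shipped predictor is a surrogate; accuracy on instrument data
  requires an external learned predictor behind the registry interface.
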