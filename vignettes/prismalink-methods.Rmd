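---
title: "Models and methods behind prismalink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prismalink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prismalink)
```

## The two screens and what the package computes

A peptide-array interaction screen (PRISMA) decomposes an intrinsically
disordered bait protein into fixed-length overlapping peptides, with and
without post-translational modifications (PTMs), immobilized as spots on
a membrane. Incubation with cell extract followed by label-free MS of
each spot yields, per spot, an LFQ intensity for every detected protein.
Because short linear motifs fit inside a 15-mer, the per-spot enrichment
pattern localizes each interaction along the bait sequence. BioID
complements this *in vitro* map with in-cell evidence: a promiscuous
biotin ligase fused to the bait biotinylates proximal proteins, and
enrichment is assessed against two negative controls — cells expressing
the ligase alone, and uninduced cells.

`prismalink` covers array design, LFQ preprocessing, the differential
test engine, the two callers, and their integration. Every stage is
exercised against a synthetic data generator with known ground truth.

## Array design

Tiles are fixed-length windows (default 15 residues) starting every
`step` residues (default 8, i.e. a 7-residue overlap between neighbours).
If the final regular window would overrun the C-terminus, a last window
anchored at the C-terminus is used instead of a short peptide — spot
synthesis uses fixed-length peptides, and full coverage of the sequence
matters more than uniform spacing at the tail. The anchored tile may
therefore overlap its neighbour by more than 7 residues.

PTM variants never mutate the sequence; they annotate positions in a
spot that shares its window with the unmodified parent. Multi-PTM spots
are created only when explicitly listed, since the combinatorial space
is not what an array measures.

**Overlap is positional, not substring-based.** The exclusion rule for
control groups ("overlap at or above 50%") is computed as shared protein
coordinates divided by the tile length. Two consequences drove this
choice: a PTM sibling must score 100% overlap with its parent (it is the
same window), and tiles of equal length make the denominator unambiguous.
With the default 15/8 design, all regular neighbours overlap 7/15 < 0.5,
so every non-sibling spot is an eligible control; an anchored C-terminal
tile can overlap its neighbour by 8/15 or more, in which case that
neighbour is excluded too. At a threshold of 0 the control group
degenerates to strictly disjoint windows (zero-overlap spots are always
eligible).

## Preprocessing

The protein-groups dialect is the MaxQuant-style TSV: contaminant,
reverse-hit and identified-by-site rows are removed, as are groups
supported by fewer than 2 peptides; an LFQ intensity of 0 means "not
detected" and becomes an explicit missing value.

The min-valid filter keeps a protein if *some* sample group contains at
least `min_valid` observations. The default is 3 for quadruplicate
BioID designs; for duplicate peptide-array screens a requirement of 3
cannot be met within a group of 2, so PRISMA-style runs use
`min_valid = 2`. The parameter is exposed rather than hard-coded because
the appropriate value follows from the replication depth of the design.

**Imputation.** LFQ missingness is missing-not-at-random: values vanish
because they fall below the detection limit. Missing entries are drawn
per sample column from `Normal(m − 1.8·s, 0.3·s)` with `m`, `s` the
column's observed mean and standard deviation (denominator `n − 1`).
Imputation runs after filtering and log2 transform, per column, and
never alters an observed value; an `imputed_mask` records provenance.
The per-column convention reflects that the detection limit is a
property of a run, not of a protein.

## The moderated test engine

With only 2–4 replicates per condition, per-protein variance estimates
are unstable. The engine shrinks each contrast's pooled two-sample
variance `s²_g` (residual df `d_g = n₁ + n₂ − 2`) toward a prior
variance `s₀²` with prior df `d₀`:

\[
\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
t_g = \frac{\bar x_{case} - \bar x_{ctrl}}
           {\tilde s_g \sqrt{1/n_1 + 1/n_2}},
\]

with `t_g ~ t(d_g + d₀)` under the null, two-sided. The hyperparameters
are estimated by moment-matching on `log s²_g`: the digamma equation
gives `s₀²`, the trigamma equation gives `d₀` (Newton inversion of the
trigamma function, tolerance 1e−8). If the empirical dispersion of the
log variances does not exceed the pure sampling term, the prior is
degenerate (`d₀ = ∞`) and every posterior variance equals `s₀²`;
estimates of `d₀` above 1e6 are treated as infinite. `d₀ = 0` recovers
the classical pooled t-test exactly, which the test suite verifies
against an independent textbook implementation to 1e−10, and the whole
fit is cross-checked against `limma::squeezeVar`.

Benjamini–Hochberg q-values are computed by the step-up rule with stable
tie handling; the suite compares them against brute-force enumeration
over all orderings of six p-values and against `p.adjust`.

Two-sided p-values are used throughout. Enrichment-only calls (PRISMA
binders, BioID interactors) additionally require a positive fold change;
the PTM-differential and pairwise isoform contrasts report both
directions, since loss of binding on modification is as informative as
gain.

## PRISMA inference

Per spot: case = the spot's replicate columns; control = the pooled
replicate columns of all eligible spots (pooling, rather than averaging
per spot first, retains the within-spot replicate variability in the
null group). Each contrast gets its own empirical-Bayes fit — control
group composition differs per spot, so a global fit would mix residual
structures — and its own BH family at FDR 0.1.

A protein enriched equally on all spots is *not* callable: its control
group mean rises with it. This is a feature of the peptide-specific
control-group design, and the suite asserts it directly.

Binding profiles are per-spot replicate means min–max normalized to
[0, 1] per significant protein, with spots ordered N- to C-terminal
(unmodified before modified siblings). A constant row maps to all zeros,
not ones: a flat profile carries no positional information. Column sums
of the profile matrix locate interaction hotspots.

PTM-differential binding is the direct sibling-vs-sibling contrast
(modified minus unmodified at the same window) rather than a
control-group contrast: the question is whether the modification changes
binding, not whether the window binds at all.

## BioID inference

An interactor must be significantly enriched (q < 0.05, positive fold
change) over *both* negative controls — two separate contrasts with
separate BH families, implemented as a conjunction rather than a pooled
control group because the two controls capture different artifacts
(endogenous biotinylation vs leaky expression). Isoform/mutant
specificity adds the direct case-vs-case contrast at q < 0.1 in its own
BH family, with the direction deciding which case the protein is
specific to; the two specific sets are disjoint by construction and
always nested inside the corresponding interactor sets.

## Integration

The high-confidence core is: found by both screens, or by one screen and
the literature. Isoform preference splits the unmodified spots at the
first residue of the short isoform; a window straddling the boundary
counts as present in both isoforms (part of it exists in the short
form). Sums are taken on the linear intensity scale — summing log
intensities would weight spots multiplicatively — and each protein's
two sums are divided by its grand total, so the two fractions add to 1.
Network filtering keeps edges with score strictly above 0.5 and then
removes unconnected nodes.

## The synthetic data generator

The generator emulates the statistical structure the analysis assumes:

- per-protein baseline log2 intensities `Normal(25, 2)` — the typical
  location and spread of LFQ protein intensities in a deep nuclear
  extract;
- replicate noise SD 0.5 on the log2 scale, the magnitude consistent
  with full-workflow screen replicates (implying replicate correlations
  around 0.85–0.95 at this baseline spread);
- planted binders: by default 10% of proteins, each enriched by 2 log2
  units on one window (and its PTM siblings, unless a PTM-specific delta
  is planted on top) — a moderate, realistic effect;
- PRISMA duplicates and BioID quadruplicates, matching the two designs;
- missing-not-at-random censoring: a value `x` drops out with
  probability `logistic((T − x)·steepness)` where `T` is the 10th
  percentile of the baseline distribution and steepness is 1 — overall
  ~15% missingness concentrated in low-abundance proteins.

All randomness flows from one seed through per-(column, purpose)
substreams, so adding proteins appends draws without perturbing existing
columns, and the same seed reproduces a bit-identical table.

**What the generator does not emulate:** peptide-level quantification,
inter-membrane batch effects beyond replicate noise, correlated binding
across neighbouring windows (a real motif spanning a tile junction
lights up two spots), ragged protein-specific variances, and the
long-tailed contaminant structure of real extracts. Passing recovery
tests on this generator therefore demonstrates the pipeline's
correctness and calibration, not field performance on any particular
real dataset.

## Calibration results the package computes

`scripts/acceptance.R` (and the corresponding test blocks) recompute,
from scratch at fixed seeds:

- the imputation downshift and width, measured over 1e5 imputed cells in
  a single synthetic column (recovered to within Monte-Carlo error of
  the nominal 1.8 and 0.3);
- the empirical false-discovery proportion of the full per-spot pipeline
  over 200 simulated screens (500 proteins, 10-spot design, duplicate
  spots, 10% binders at 2 log2 units) — comfortably below the nominal
  0.1, reflecting the conservatism of imputation-inflated variances.

These problem sizes (500 proteins, 10 spots, 200 replicates of the
simulation) are chosen to make the Monte-Carlo error small relative to
the tolerances while keeping a full run in the order of seconds to
minutes on one core.

## Power at duplicate depth, and other limitations

With n = 2 replicates per spot, an effect of 2 log2 units, and per-spot
BH families of ~500 proteins, the per-(protein, spot) recall of the full
pipeline is about 0.6–0.7 under the generator's default noise and
censoring. This is intrinsic: the expected moderated t at these settings
sits near the BH rejection boundary, and single censored-and-imputed
replicates inflate individual variances; an independent moderated-t
implementation (limma) yields the same calls on identical data. Recall
rises quickly with effect size (the suite asserts monotonicity) and
exceeds 0.9 by 3–4 log2 units or with milder noise. Screens at duplicate
depth should therefore be read as high-confidence-positive rather than
exhaustive — consistent with the conservative empirical FDR above.

Other limitations: the equal-variance pooling assumes comparable spread
in case and control groups; the empirical-Bayes fit has no
intensity-trend or robust variants; control groups assume the array is
large enough that most spots are null for any given protein; and protein
id harmonization keeps only the first accession of a group.
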