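# prismalink

Mapping the linear, PTM-regulated interactome of an intrinsically
disordered protein from two complementary screens:

- **PRISMA** (protein interaction screen on a peptide matrix): the protein
  of interest is synthesized as overlapping fixed-length peptides spotted
  on a membrane, with and without post-translational modifications
  (PTMs); each spot is incubated with cell extract and its bound proteins
  are quantified by label-free MS (LFQ).
- **BioID**: a promiscuous biotin ligase fused to the bait biotinylates
  neighboring proteins in living cells; enriched proteins are compared
  against two negative controls (ligase-only and uninduced cells).

`prismalink` implements the full downstream analysis for both screens and
their integration, plus a ground-truth synthetic data generator so every
stage can be validated without access to raw MS data.

## The statistics at the core

**Peptide-specific null groups.** Each spot *k* is tested against a
control group pooling the replicate columns of every spot whose
positional overlap with *k* is below 50% of the tile length — so the
target's own window and all its PTM siblings are excluded, and a protein
bound promiscuously across the array cancels out of its own contrast.

**Moderated t.** Per protein *g* and contrast, the pooled two-sample
variance s²_g (d_g = n₁ + n₂ − 2 residual df) is shrunk toward a prior by
empirical Bayes:

    s̃²_g = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g)
    t_g  = (mean(case) − mean(control)) / sqrt(s̃²_g·(1/n₁ + 1/n₂))

with t_g referred to a t distribution on d_g + d₀ df. The hyperparameters
(d₀, s₀²) are estimated by matching the mean and variance of log s²_g to
the log-F prior moments (digamma/trigamma equations, trigamma inverted by
Newton iteration). With d₀ = 0 the statistic reduces exactly to the
classical pooled t-test.

**Detection-limit imputation.** Missing LFQ values are drawn per sample
column from Normal(m − 1.8·s, 0.3·s), where m and s are the column's
observed mean and SD — a downshifted normal at the detection limit,
reflecting that LFQ missingness is missing-not-at-random.

**Calling rules.** PRISMA: Benjamini–Hochberg within each spot's contrast,
significant at q < 0.1 with positive fold change. BioID: a protein is an
interactor only if enriched over *both* controls at q < 0.05; isoform- or
mutant-specific interactors additionally require q < 0.1 in the direct
pairwise contrast. Binding profiles are per-spot means min–max normalized
to [0, 1] per protein; their column sums locate interaction hotspots.

## Worked example

```r
library(prismalink)

# 1. design a tiling array over an 87-residue bait
seqs   <- paste(rep(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 5)[1:87], collapse = "")
design <- tile_protein(seqs, tile_length = 15, step = 8, protein_id = "BAIT")
design
#> ArrayDesign for BAIT (87 aa): 10 spots (0 modified), tile 15, step 8

# 2. simulate a duplicate PRISMA screen with 10% planted binders
cfg <- generator_config(n_proteins = 500, fraction_binders = 0.1,
                        effect_log2 = 2, seed = 42)
sim <- generate_prisma_dataset(design, cfg)
sim$table
#> IntensityTable: 500 proteins x 20 samples (10 groups), linear scale, 17.2% missing, 0.0% imputed

# 3. preprocess: min-valid filter, log2, downshifted-normal imputation
tb <- filter_min_valid(sim$table, min_valid = 2)
tb <- impute_downshift(log2_transform(tb), seed = 42)

# 4. per-spot differential enrichment vs peptide-specific controls
res <- run_prisma(tb, design, fdr = 0.1)
sum(res$significant)                      # (protein, spot) calls at q < 0.1
#> [1] 31
length(unique(res$protein_id[res$significant]))  # distinct proteins called
#> [1] 31

# 5. binding profiles and the per-spot hotspot totals
prof <- binding_profiles(tb, res, design)
round(spot_signal_sum(prof), 1)
#> BAIT_001 BAIT_002 BAIT_003 BAIT_004 BAIT_005 BAIT_006 BAIT_007 BAIT_008
#>      9.4      9.1     10.1     10.7      8.8      7.5      8.8      9.4
#> BAIT_009 BAIT_010
#>      9.6     11.6
```

Each significant (protein, spot) pair is a candidate interaction with
that peptide's window; the spot totals sum the 0–1 normalized profiles of
all called proteins, so peaks mark interaction hotspots along the bait.

For BioID, `run_bioid()` returns per-protein dual-control calls and
`pairwise_specific()` adds isoform/mutant specificity; `overlap_sets()`,
`isoform_preference()` and `network_filter()` integrate the two screens.

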