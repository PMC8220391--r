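# Shared fixtures, built in code at test time.

# deterministic pseudo-protein sequence of length n
toy_sequence <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  paste(rep(aa, length.out = n), collapse = "")
}

# the 10-spot reference design used throughout: 87 aa, 15-mers, step 8
toy_design <- function(protein_id = "CEBPA") {
  tile_protein(toy_sequence(87), tile_length = 15, step = 8,
               protein_id = protein_id)
}

# small hand-built log2 IntensityTable: values matrix + group map
toy_table <- function(values, groups, scale = "log2") {
  intensity_table(values, groups, scale = scale)
}

# full PRISMA pipeline on generator output: filter (duplicate screens ->
# min_valid 2), log2, impute, test
prisma_pipeline <- function(sim, impute_seed, fdr = 0.1, design) {
  tb <- filter_min_valid(sim$table, min_valid = 2L)
  tb <- log2_transform(tb)
  tb <- impute_downshift(tb, seed = impute_seed)
  run_prisma(tb, design, fdr = fdr)
}

# (protein, spot) keys of planted truth and of significant calls
truth_keys <- function(truth) paste(truth$binders$protein_id, truth$binders$spot_id)
sig_keys <- function(res) paste(res$protein_id, res$contrast_id)[res$significant]

# classical pooled two-sample t-test oracle (textbook formulas, no package
# code path shared with moderated_t)
classical_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# brute-force BH step-up oracle: find largest k with p_(k) <= k*q/m by
# direct enumeration, and compute q-values as the minimal level at which
# each p-value would be rejected
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q
}
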