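test_that("planted binders are recovered in their planted spots", {
  d <- toy_design()
  cfg <- generator_config(n_proteins = 300, fraction_binders = 0.05,
                          effect_log2 = 3, noise_sd = 0.3,
                          detection_limit_quantile = 0.05, seed = 41)
  sim <- generate_prisma_dataset(d, cfg)
  res <- prisma_pipeline(sim, impute_seed = 41, design = d)

  tk <- truth_keys(sim$truth)
  sk <- sig_keys(res)
  expect_gt(sum(sk %in% tk) / length(tk), 0.8)     # strong effects found
  expect_lt(sum(!sk %in% tk) / max(1, length(sk)), 0.2)
})

test_that("a globally sticky protein is never called in any spot", {
  d <- toy_design()
  cfg <- generator_config(n_proteins = 150, fraction_binders = 0,
                          noise_sd = 0.3, detection_limit_quantile = 0,
                          seed = 8)
  sim <- generate_prisma_dataset(d, cfg)
  tb <- log2_transform(sim$table)
  tb$values["P0007", ] <- tb$values["P0007", ] + 5  # enriched everywhere
  res <- run_prisma(tb, d)
  expect_false(any(res$significant[res$protein_id == "P0007"]))
})

test_that("global-null data yields at most FDR-level significance", {
  d <- toy_design()
  cfg <- generator_config(n_proteins = 400, fraction_binders = 0, seed = 55)
  sim <- generate_prisma_dataset(d, cfg)
  res <- prisma_pipeline(sim, impute_seed = 55, design = d)
  expect_lt(mean(res$significant), 0.1)
})

test_that("results are invariant to protein row permutation", {
  d <- toy_design()
  cfg <- generator_config(n_proteins = 80, seed = 4)
  sim <- generate_prisma_dataset(d, cfg)
  tb <- impute_downshift(log2_transform(sim$table), seed = 1)
  res <- run_prisma(tb, d)

  perm <- sample(nrow(tb$values))
  tbp <- tb
  tbp$values <- tb$values[perm, ]
  tbp$imputed_mask <- tb$imputed_mask[perm, ]
  tbp$proteins <- tb$proteins[perm, ]
  resp <- run_prisma(tbp, d)

  key <- function(r) r[order(r$protein_id, r$contrast_id),
                       c("protein_id", "contrast_id", "log2_fc", "p_value",
                         "q_value", "significant")]
  a <- key(res); b <- key(resp)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("sensitivity increases with planted effect size", {
  d <- toy_design()
  recall_at <- function(effect) {
    hits <- 0; total <- 0
    for (s in 1:5) {
      cfg <- generator_config(n_proteins = 200, fraction_binders = 0.1,
                              effect_log2 = effect, seed = 600 + s)
      sim <- generate_prisma_dataset(d, cfg)
      res <- prisma_pipeline(sim, impute_seed = s, design = d)
      tk <- truth_keys(sim$truth)
      hits <- hits + sum(sig_keys(res) %in% tk)
      total <- total + length(tk)
    }
    hits / total
  }
  r <- vapply(c(1, 2.5, 4), recall_at, numeric(1))
  expect_true(all(diff(r) >= 0))
  expect_gt(r[3], r[1])
})

test_that("binding profiles are 0-1 normalized in design order", {
  # hand-built: 3 proteins x 3 spots, 1 replicate column each
  d <- tile_protein(toy_sequence(31), 15, 8)
  vals <- rbind(A = c(2, 4, 6), B = c(5, 5, 5), C = c(1, 0, 1))
  colnames(vals) <- paste0(d$spots$spot_id, "_rep1")
  tb <- toy_table(vals, setNames(d$spots$spot_id, colnames(vals)))
  results <- data.frame(protein_id = c("A", "B", "C"),
                        contrast_id = d$spots$spot_id[1],
                        significant = TRUE)
  prof <- binding_profiles(tb, results, d)
  expect_equal(unname(prof["A", ]), c(0, 0.5, 1))
  expect_equal(unname(prof["B", ]), c(0, 0, 0))   # constant row -> no signal
  expect_equal(unname(prof["C", ]), c(1, 0, 1))
  expect_identical(colnames(prof), d$spots$spot_id)
  expect_true(all(prof >= 0 & prof <= 1))

  expect_equal(unname(spot_signal_sum(prof)), c(1, 0.5, 2))
  expect_error(binding_profiles(tb, results[0, ], d), "no significant")
})

test_that("hotspot spots carry the maximal summed signal", {
  d <- toy_design()
  cfg <- generator_config(n_proteins = 250, fraction_binders = 0, seed = 90)
  sim <- generate_prisma_dataset(d, cfg)
  tb <- impute_downshift(log2_transform(sim$table), seed = 2)
  # plant a hotspot: 25 proteins bound at spot 7
  hot <- d$spots$spot_id[7]
  grp <- tb$sample_groups[colnames(tb$values)]
  planted <- sprintf("P%04d", 1:25)
  tb$values[planted, grp == hot] <- tb$values[planted, grp == hot] + 3
  res <- run_prisma(tb, d)
  prof <- binding_profiles(tb, res, d)
  totals <- spot_signal_sum(prof)
  expect_identical(names(which.max(totals)), hot)
})

test_that("PTM-differential calls detect planted sibling deltas", {
  base <- tile_protein(toy_sequence(87), 15, 8, "CEBPA")
  res42 <- substr(toy_sequence(87), 42, 42)
  d <- add_ptm_variants(base, data.frame(position = 42, residue = res42,
                                         modification = "me2"))
  mod_spot <- d$spots$spot_id[d$spots$is_modified & d$spots$start == 41]
  par_spot <- d$spots$spot_id[!d$spots$is_modified & d$spots$start == 41]

  cfg <- generator_config(n_proteins = 200, fraction_binders = 0,
                          replicates_per_spot = 3, noise_sd = 0.3,
                          detection_limit_quantile = 0, seed = 66)
  ptm <- data.frame(protein_id = c("P0010", "P0020"),
                    spot_id = mod_spot, delta_log2 = c(2, -2))
  sim <- generate_prisma_dataset(d, cfg, ptm_effects = ptm)
  tb <- log2_transform(sim$table)
  res <- ptm_differential(tb, d, mod_spot, par_spot)

  r10 <- res[res$protein_id == "P0010", ]
  r20 <- res[res$protein_id == "P0020", ]
  expect_true(r10$significant); expect_gt(r10$log2_fc, 0)
  expect_true(r20$significant); expect_lt(r20$log2_fc, 0)  # both directions
  expect_lt(sum(res$significant), 10)  # null background stays quiet

  other_mod <- d$spots$spot_id[d$spots$is_modified & d$spots$start == 33]
  expect_error(ptm_differential(tb, d, other_mod, par_spot), "share a window")
  expect_error(ptm_differential(tb, d, par_spot, mod_spot), "modified spot")
})
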