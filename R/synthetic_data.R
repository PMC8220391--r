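# Seed of the (column, purpose) substream: each sample column draws its
# noise and its censoring uniforms from their own streams, so adding
# proteins appends draws and never perturbs existing columns or the other
# purpose's draws.
.column_seed <- function(seed, j, purpose = 0L) {
  as.integer((as.numeric(seed) * 7919 + j * 104729 + purpose * 7457) %%
               2147483647)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration of the synthetic LFQ data generator
#'
#' Collects and validates every distributional parameter of the generator.
#' Defaults describe a realistic nuclear-extract LFQ experiment: per-protein
#' baseline abundances of log2 mean 25 and SD 2, replicate noise of 0.5 on
#' the log2 scale, planted binder effects of 2 log2 units for 10% of
#' proteins, and detection-limit censoring at the 10th percentile of the
#' baseline distribution with logistic steepness 1. Replicate counts default
#' to the two study designs: duplicate peptide-array screens and
#' quadruplicate BioID conditions.
#'
#' @param n_proteins Number of background proteins.
#' @param replicates_per_spot PRISMA replicates per peptide spot.
#' @param replicates_per_condition BioID replicates per condition.
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-protein
#'   baseline log2 intensity.
#' @param effect_log2 Planted binder / interactor effect size (log2 units).
#' @param fraction_binders Fraction of proteins planted as binders.
#' @param ptm_delta_log2 Default extra log2 effect on a modified sibling
#'   spot relative to its unmodified counterpart.
#' @param detection_limit_quantile Quantile of the baseline distribution at
#'   which the stochastic detection threshold sits (0 disables missingness).
#' @param missingness_steepness Steepness of the logistic censoring curve.
#' @param noise_sd Replicate noise SD (log2 scale).
#' @param seed Integer seed; all randomness flows from it through
#'   per-column substreams.
#' @return A validated list of class `GeneratorConfig`.
#' @export
generator_config <- function(n_proteins = 500L,
                             replicates_per_spot = 2L,
                             replicates_per_condition = 4L,
                             baseline_log2_mean = 25,
                             baseline_log2_sd = 2,
                             effect_log2 = 2,
                             fraction_binders = 0.1,
                             ptm_delta_log2 = 2,
                             detection_limit_quantile = 0.1,
                             missingness_steepness = 1,
                             noise_sd = 0.5,
                             seed = 1L) {
  stopifnot(n_proteins >= 1, replicates_per_spot >= 1,
            replicates_per_condition >= 1,
            fraction_binders >= 0, fraction_binders <= 1,
            detection_limit_quantile >= 0, detection_limit_quantile < 1,
            missingness_steepness >= 0, noise_sd >= 0,
            baseline_log2_sd > 0)
  structure(as.list(environment()), class = "GeneratorConfig")
}

# expected log2 matrix -> observed linear IntensityTable with MNAR censoring
.emit_table <- function(expected, groups, config) {
  n <- nrow(expected)
  vals <- expected
  threshold <- if (config$detection_limit_quantile > 0) {
    stats::qnorm(config$detection_limit_quantile,
                 config$baseline_log2_mean, config$baseline_log2_sd)
  } else -Inf
  for (j in seq_len(ncol(expected))) {
    x <- expected[, j] + .with_seed(.column_seed(config$seed, j, 1L),
                                    stats::rnorm(n, 0, config$noise_sd))
    if (is.finite(threshold)) {
      p_miss <- stats::plogis((threshold - x) * config$missingness_steepness)
      u <- .with_seed(.column_seed(config$seed, j, 2L), stats::runif(n))
      x[u < p_miss] <- NA_real_
    }
    vals[, j] <- x
  }
  intensity_table(2^vals, groups, scale = "linear")
}

#' Generate a synthetic PRISMA dataset with known ground truth
#'
#' Emulates the data structure of a peptide-array interaction screen: one
#' LFQ sample per (spot, replicate); each protein's log2 intensity is its
#' baseline plus a planted spot-restricted binding effect (for binder
#' proteins, on their target window and all PTM siblings of that window,
#' plus any PTM-specific delta) plus replicate noise; intensities below a
#' stochastic detection threshold are censored (missing not at random).
#'
#' @param design An `ArrayDesign` defining the spots.
#' @param config A `GeneratorConfig`.
#' @param ptm_effects Optional data.frame (`protein_id`, `spot_id`,
#'   `delta_log2`) planting differential binding on modified sibling spots;
#'   `protein_id` may name background proteins (`"P0001"`, ...).
#' @return List with `table` (linear-scale `IntensityTable`; missing as
#'   `NA`) and `truth` (class `SyntheticTruth`): `binders` data.frame
#'   (`protein_id`, `spot_id`, `log2_effect`), `ptm_effects`,
#'   `generator_params`.
#' @export
generate_prisma_dataset <- function(design, config = generator_config(),
                                    ptm_effects = NULL) {
  stopifnot(inherits(design, "ArrayDesign"), inherits(config, "GeneratorConfig"))
  spots <- design$spots
  n <- config$n_proteins
  ids <- sprintf("P%04d", seq_len(n))

  reps <- seq_len(config$replicates_per_spot)
  sample_ids <- as.vector(t(outer(spots$spot_id, reps, function(s, r) {
    paste0(s, "_rep", r)
  })))
  groups <- stats::setNames(rep(spots$spot_id, each = length(reps)), sample_ids)

  planted <- .with_seed(config$seed, {
    baseline <- stats::rnorm(n, config$baseline_log2_mean,
                             config$baseline_log2_sd)
    n_bind <- round(config$fraction_binders * n)
    binder_idx <- if (n_bind > 0) sample.int(n, n_bind) else integer(0)
    unmod_ids <- spots$spot_id[!spots$is_modified]
    target <- if (n_bind > 0) {
      unmod_ids[sample.int(length(unmod_ids), n_bind, replace = TRUE)]
    } else character(0)
    list(baseline = baseline, binder_idx = binder_idx, target = target)
  })

  # effect applies to the target window and every spot sharing that window
  # (PTM siblings bind the same sequence unless a delta says otherwise)
  expected <- matrix(planted$baseline, n, length(sample_ids),
                     dimnames = list(ids, sample_ids))
  binders <- data.frame(protein_id = character(0), spot_id = character(0),
                        log2_effect = numeric(0), stringsAsFactors = FALSE)
  for (k in seq_along(planted$binder_idx)) {
    i <- planted$binder_idx[k]
    tgt <- spots[spots$spot_id == planted$target[k], ]
    window_spots <- spots$spot_id[spots$start == tgt$start & spots$end == tgt$end]
    cols <- which(groups[sample_ids] %in% window_spots)
    expected[i, cols] <- expected[i, cols] + config$effect_log2
    binders <- rbind(binders, data.frame(
      protein_id = ids[i], spot_id = window_spots,
      log2_effect = config$effect_log2, stringsAsFactors = FALSE))
  }
  if (!is.null(ptm_effects) && nrow(ptm_effects)) {
    for (k in seq_len(nrow(ptm_effects))) {
      i <- match(ptm_effects$protein_id[k], ids)
      if (is.na(i)) stop("unknown protein in ptm_effects: ",
                         ptm_effects$protein_id[k])
      sp <- .get_spot(design, ptm_effects$spot_id[k])
      if (!sp$is_modified) stop("ptm_effects spot '", sp$spot_id,
                                "' is not a modified spot")
      cols <- which(groups[sample_ids] == sp$spot_id)
      expected[i, cols] <- expected[i, cols] + ptm_effects$delta_log2[k]
    }
  } else {
    ptm_effects <- data.frame(protein_id = character(0), spot_id = character(0),
                              delta_log2 = numeric(0), stringsAsFactors = FALSE)
  }

  table <- .emit_table(expected, groups, config)
  truth <- structure(list(binders = binders, ptm_effects = ptm_effects,
                          bioid_effects = NULL, generator_params = config),
                     class = "SyntheticTruth")
  list(table = table, truth = truth)
}

#' Generate a synthetic BioID dataset with known ground truth
#'
#' Emulates a proximity-labeling design with one or more bait conditions
#' and exactly two negative controls (ligase-only and uninduced). Planted
#' interactors are enriched in case conditions over both controls by their
#' stated log2 enrichment; condition-specific interactors (e.g. enriched
#' with one bait isoform only) are supported through explicit `effects`.
#'
#' @param cases Character vector of case condition labels (>= 1).
#' @param controls Character vector of exactly 2 control condition labels.
#' @param config A `GeneratorConfig`.
#' @param effects Optional data.frame (`protein_id`, `condition`,
#'   `log2_enrichment`) planting explicit per-condition enrichments; by
#'   default `fraction_binders` of proteins are enriched by `effect_log2`
#'   in every case condition.
#' @return List with `table` (linear `IntensityTable`) and `truth`
#'   (`SyntheticTruth` with `bioid_effects` data.frame).
#' @export
generate_bioid_dataset <- function(cases, controls,
                                   config = generator_config(),
                                   effects = NULL) {
  stopifnot(inherits(config, "GeneratorConfig"))
  if (length(cases) < 1L) stop("need at least one case condition")
  if (length(controls) != 2L) stop("exactly 2 control conditions required")
  conditions <- c(cases, controls)
  n <- config$n_proteins
  ids <- sprintf("P%04d", seq_len(n))

  reps <- seq_len(config$replicates_per_condition)
  sample_ids <- as.vector(t(outer(conditions, reps, function(c, r) {
    paste0(c, "_rep", r)
  })))
  groups <- stats::setNames(rep(conditions, each = length(reps)), sample_ids)

  planted <- .with_seed(config$seed, {
    baseline <- stats::rnorm(n, config$baseline_log2_mean,
                             config$baseline_log2_sd)
    if (is.null(effects)) {
      n_bind <- round(config$fraction_binders * n)
      idx <- if (n_bind > 0) sample.int(n, n_bind) else integer(0)
      effects <- if (length(idx)) {
        expand <- expand.grid(protein_id = ids[idx], condition = cases,
                              stringsAsFactors = FALSE)
        expand$log2_enrichment <- config$effect_log2
        expand
      } else {
        data.frame(protein_id = character(0), condition = character(0),
                   log2_enrichment = numeric(0), stringsAsFactors = FALSE)
      }
    }
    list(baseline = baseline, effects = effects)
  })
  effects <- planted$effects
  if (any(effects$condition %in% controls)) {
    stop("effects may only target case conditions")
  }
  if (!all(effects$condition %in% cases)) stop("unknown condition in effects")
  if (!all(effects$protein_id %in% ids)) stop("unknown protein in effects")

  expected <- matrix(planted$baseline, n, length(sample_ids),
                     dimnames = list(ids, sample_ids))
  for (k in seq_len(nrow(effects))) {
    i <- match(effects$protein_id[k], ids)
    cols <- which(groups[sample_ids] == effects$condition[k])
    expected[i, cols] <- expected[i, cols] + effects$log2_enrichment[k]
  }

  table <- .emit_table(expected, groups, config)
  truth <- structure(list(binders = NULL, ptm_effects = NULL,
                          bioid_effects = effects, generator_params = config),
                     class = "SyntheticTruth")
  list(table = table, truth = truth)
}

#' Write generator ground truth as TSV
#'
#' @param truth A `SyntheticTruth`.
#' @param path Output TSV path (binders for PRISMA truth, enrichments for
#'   BioID truth).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  df <- if (!is.null(truth$binders)) truth$binders else truth$bioid_effects
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
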