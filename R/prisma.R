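#' Per-spot differential enrichment against peptide-specific control groups
#'
#' The core peptide-array inference. For every spot on the array, the
#' "case" samples are that spot's replicate columns and the "control" group
#' pools all replicate columns of every spot whose positional overlap with
#' the target is below `overlap_threshold` (which always excludes the
#' target's PTM siblings). Each contrast gets its own empirical-Bayes
#' moderated t-test across proteins and its own Benjamini-Hochberg family;
#' a protein is called significant for a spot iff `q < fdr` with positive
#' log2 fold change (enrichment only). A protein bound equally everywhere
#' raises its own control group and is therefore not called - the design
#' cancels promiscuous stickiness.
#'
#' @param table A complete (imputed) log2-scale `IntensityTable` whose
#'   sample groups are spot ids.
#' @param design The `ArrayDesign` covering those spots.
#' @param fdr FDR cutoff within each spot's BH family (default 0.1).
#' @param overlap_threshold Overlap fraction excluding a spot from another
#'   spot's control group (default 0.5).
#' @return data.frame of per-(protein, spot) results: `protein_id`,
#'   `contrast_id` (the spot), `log2_fc`, `t`, `df_total`, `p_value`,
#'   `q_value`, `direction`, `significant`. Spots without eligible control
#'   spots are skipped with a warning.
#' @export
run_prisma <- function(table, design, fdr = 0.1, overlap_threshold = 0.5) {
  stopifnot(inherits(table, "IntensityTable"), inherits(design, "ArrayDesign"))
  if (table$scale != "log2") stop("run_prisma expects a log2-scale table")
  if (anyNA(table$values)) stop("missing values present; impute first")
  grp <- table$sample_groups[colnames(table$values)]
  spot_ids <- design$spots$spot_id
  if (!all(unique(grp) %in% spot_ids)) {
    stop("sample groups not covered by the design: ",
         paste(setdiff(unique(grp), spot_ids), collapse = ", "))
  }

  out <- vector("list", length(spot_ids))
  for (k in seq_along(spot_ids)) {
    spot <- spot_ids[k]
    case_cols <- which(grp == spot)
    if (length(case_cols) < 2L) next
    ctrl_spots <- control_spots(design, spot, overlap_threshold)
    ctrl_cols <- which(grp %in% ctrl_spots)
    if (length(ctrl_cols) < 2L) {
      warning("spot '", spot, "' has no eligible control columns; skipped")
      next
    }
    out[[k]] <- .run_contrast(table$values, case_cols, ctrl_cols,
                              contrast_id = spot, fdr = fdr,
                              require_up = TRUE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    stop("no spot had both case and control columns")
  }
  rownames(res) <- NULL
  res
}

# design-order of spots: N- to C-terminal, unmodified before modified
.ordered_spots <- function(design) {
  sp <- design$spots
  sp$spot_id[order(sp$start, sp$is_modified, sp$spot_id)]
}

#' Binding profiles of significant proteins
#'
#' For every protein significant in at least one spot, averages its
#' intensity over each spot's replicate columns and min-max normalizes the
#' resulting per-spot vector to `[0, 1]` across all peptides. A constant
#' row (no positional information) maps to all zeros. Spots are ordered
#' N- to C-terminal, unmodified before modified siblings.
#'
#' @param table The (imputed, log2) `IntensityTable` used for testing.
#' @param results Result data.frame from [run_prisma()] (or any data.frame
#'   with `protein_id` and `significant` columns).
#' @param design The `ArrayDesign` (fixes spot order).
#' @return A proteins x spots matrix of values in `[0, 1]`, with attribute
#'   `"significant_in"`: a named list of the spots each protein was
#'   significant in.
#' @export
binding_profiles <- function(table, results, design) {
  stopifnot(inherits(table, "IntensityTable"))
  sig <- unique(results$protein_id[results$significant])
  if (length(sig) == 0L) stop("no significant proteins to profile")
  spots <- .ordered_spots(design)
  grp <- table$sample_groups[colnames(table$values)]
  spot_means <- sapply(spots, function(s) {
    rowMeans(table$values[sig, grp == s, drop = FALSE])
  })
  m <- matrix(spot_means, nrow = length(sig),
              dimnames = list(sig, spots))
  rng <- apply(m, 1L, range)
  span <- rng[2L, ] - rng[1L, ]
  prof <- (m - rng[1L, ]) / ifelse(span > 0, span, 1)
  prof[span == 0, ] <- 0
  attr(prof, "significant_in") <- split(
    results$contrast_id[results$significant],
    results$protein_id[results$significant])[sig]
  prof
}

#' Summed normalized signal per peptide spot
#'
#' Column sums of the 0-1 normalized binding-profile matrix: one total per
#' spot, the quantity used to locate interaction hotspots along the
#' protein.
#'
#' @param profiles Matrix from [binding_profiles()].
#' @return Named numeric vector of per-spot totals.
#' @export
spot_signal_sum <- function(profiles) {
  colSums(profiles)
}

#' Differential binding between a PTM-modified spot and its unmodified sibling
#'
#' Direct two-group moderated t contrast between the replicate columns of a
#' modified peptide and its unmodified counterpart (same window, different
#' PTM state), reported in both directions: `log2_fc` is modified minus
#' unmodified, and negative calls (binding lost on modification) count as
#' significant too.
#'
#' @param table A complete log2-scale `IntensityTable`.
#' @param design The `ArrayDesign`.
#' @param modified_spot,unmodified_spot Spot ids sharing a window and
#'   differing only in PTM state.
#' @param fdr BH FDR cutoff (default 0.1).
#' @return Contrast-result data.frame as in [run_prisma()].
#' @export
ptm_differential <- function(table, design, modified_spot, unmodified_spot,
                             fdr = 0.1) {
  stopifnot(inherits(table, "IntensityTable"), inherits(design, "ArrayDesign"))
  if (table$scale != "log2") stop("ptm_differential expects log2 scale")
  a <- .get_spot(design, modified_spot)
  b <- .get_spot(design, unmodified_spot)
  if (a$start != b$start || a$end != b$end) {
    stop("spots do not share a window: (", a$start, ",", a$end, ") vs (",
         b$start, ",", b$end, ")")
  }
  if (!a$is_modified || b$is_modified) {
    stop("expected a modified spot and its unmodified sibling")
  }
  grp <- table$sample_groups[colnames(table$values)]
  case_cols <- which(grp == modified_spot)
  ctrl_cols <- which(grp == unmodified_spot)
  .run_contrast(table$values, case_cols, ctrl_cols,
                contrast_id = paste0(modified_spot, "_vs_", unmodified_spot),
                fdr = fdr, require_up = FALSE)
}
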