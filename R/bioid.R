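#' BioID interactor calling with the dual-control rule
#'
#' Tests each protein's enrichment in the case condition against each of the
#' two negative controls (typically ligase-only cells and uninduced cells)
#' with separate moderated-t contrasts and separate Benjamini-Hochberg
#' families. A protein is an interactor iff it is significantly enriched
#' (q below `fdr_ctrl`, positive log2 fold change) over *both* controls.
#'
#' @param table A complete (imputed) log2-scale `IntensityTable` whose
#'   sample groups are condition labels.
#' @param case Case condition label.
#' @param controls Character vector of exactly 2 control condition labels.
#' @param fdr_ctrl FDR cutoff for each case-vs-control family (default 0.05).
#' @return data.frame with one row per protein: `protein_id`,
#'   `case_condition`, `log2_fc_vs_control1`, `log2_fc_vs_control2`,
#'   `q_vs_control1`, `q_vs_control2`, `interactor` (logical) and
#'   `category` (`"interactor"` / `"not_significant"`).
#' @export
run_bioid <- function(table, case, controls, fdr_ctrl = 0.05) {
  stopifnot(inherits(table, "IntensityTable"))
  if (length(controls) != 2L) stop("exactly 2 control conditions required")
  if (table$scale != "log2") stop("run_bioid expects a log2-scale table")
  if (anyNA(table$values)) stop("missing values present; impute first")
  grp <- table$sample_groups[colnames(table$values)]
  for (cond in c(case, controls)) {
    if (sum(grp == cond) < 2L) {
      stop("condition '", cond, "' has fewer than 2 replicate columns")
    }
  }
  case_cols <- which(grp == case)
  r1 <- .run_contrast(table$values, case_cols, which(grp == controls[1L]),
                      contrast_id = paste0(case, "_vs_", controls[1L]),
                      fdr = fdr_ctrl, require_up = TRUE)
  r2 <- .run_contrast(table$values, case_cols, which(grp == controls[2L]),
                      contrast_id = paste0(case, "_vs_", controls[2L]),
                      fdr = fdr_ctrl, require_up = TRUE)
  stopifnot(identical(r1$protein_id, r2$protein_id))
  calls <- data.frame(
    protein_id = r1$protein_id,
    case_condition = case,
    log2_fc_vs_control1 = r1$log2_fc, log2_fc_vs_control2 = r2$log2_fc,
    q_vs_control1 = r1$q_value, q_vs_control2 = r2$q_value,
    interactor = r1$significant & r2$significant,
    stringsAsFactors = FALSE
  )
  calls$category <- ifelse(calls$interactor, "interactor", "not_significant")
  attr(calls, "contrasts") <- list(r1, r2)
  calls
}

#' Isoform / mutant specific interactors by pairwise comparison
#'
#' Extends [run_bioid()] to two case conditions (e.g. the long and short
#' bait isoforms, or wild type and a methylation-site mutant): a protein is
#' caseA-specific iff it is a dual-control interactor for caseA *and* the
#' direct caseA-vs-caseB moderated-t contrast is significant toward caseA
#' (q below `fdr_pair`). The pairwise p-values form their own BH family.
#' The two specific sets are disjoint by construction.
#'
#' @param table,controls,fdr_ctrl As in [run_bioid()].
#' @param caseA,caseB The two case condition labels.
#' @param fdr_pair FDR cutoff of the pairwise family (default 0.1).
#' @return data.frame with two rows per protein (one per case):
#'   dual-control columns as in [run_bioid()] plus `pairwise_log2_fc`
#'   (toward that case), `pairwise_q` and `category`
#'   (`"case_specific"`, `"interactor"` or `"not_significant"`).
#' @export
pairwise_specific <- function(table, caseA, caseB, controls,
                              fdr_ctrl = 0.05, fdr_pair = 0.1) {
  callsA <- run_bioid(table, caseA, controls, fdr_ctrl)
  callsB <- run_bioid(table, caseB, controls, fdr_ctrl)

  grp <- table$sample_groups[colnames(table$values)]
  pw <- .run_contrast(table$values, which(grp == caseA), which(grp == caseB),
                      contrast_id = paste0(caseA, "_vs_", caseB),
                      fdr = fdr_pair, require_up = FALSE)
  stopifnot(identical(pw$protein_id, callsA$protein_id))

  specificA <- callsA$interactor & pw$q_value < fdr_pair & pw$log2_fc > 0
  specificB <- callsB$interactor & pw$q_value < fdr_pair & pw$log2_fc < 0

  callsA$pairwise_log2_fc <- pw$log2_fc
  callsA$pairwise_q <- pw$q_value
  callsA$category <- ifelse(specificA, "case_specific", callsA$category)
  callsB$pairwise_log2_fc <- -pw$log2_fc
  callsB$pairwise_q <- pw$q_value
  callsB$category <- ifelse(specificB, "case_specific", callsB$category)

  out <- rbind(callsA, callsB)
  rownames(out) <- NULL
  attr(out, "pairwise") <- pw
  out
}
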