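#' Construct an LFQ intensity table
#'
#' The central container of the pipeline: a proteins x samples matrix of
#' label-free quantification intensities with an explicit missing-value
#' mask, a sample-to-group map and a scale flag. On the linear scale all
#' non-missing values are positive (a raw intensity of 0 means "not
#' detected" and is stored as `NA`); after [log2_transform()] values are
#' finite log2 intensities.
#'
#' @param values Numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids). `NA` marks missing.
#' @param sample_groups Named character vector mapping every sample id to a
#'   group label (a peptide spot for PRISMA, a condition for BioID).
#' @param proteins Optional data.frame of per-protein annotation
#'   (`protein_id`, `peptides`, flag columns); defaults are filled in.
#' @param scale `"linear"` or `"log2"`.
#' @param imputed_mask Optional logical matrix, `TRUE` where a value was
#'   imputed; defaults to all-`FALSE`.
#' @return An object of class `IntensityTable`.
#' @export
intensity_table <- function(values, sample_groups, proteins = NULL,
                            scale = c("linear", "log2"),
                            imputed_mask = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have protein rownames")
  if (is.null(colnames(values))) stop("values must have sample colnames")
  if (!all(colnames(values) %in% names(sample_groups))) {
    stop("every sample column needs an entry in sample_groups")
  }
  sample_groups <- sample_groups[colnames(values)]
  if (scale == "linear" && any(values <= 0, na.rm = TRUE)) {
    stop("linear-scale intensities must be positive (0 encodes missing)")
  }
  if (is.null(proteins)) {
    proteins <- data.frame(protein_id = rownames(values), peptides = 2L,
                           contaminant = FALSE, reverse = FALSE,
                           site_only = FALSE, stringsAsFactors = FALSE)
  }
  if (is.null(imputed_mask)) {
    imputed_mask <- matrix(FALSE, nrow(values), ncol(values),
                           dimnames = dimnames(values))
  }
  stopifnot(identical(dim(values), dim(imputed_mask)))
  structure(
    list(values = values, sample_groups = sample_groups,
         proteins = proteins, scale = scale, imputed_mask = imputed_mask),
    class = "IntensityTable"
  )
}

#' @export
print.IntensityTable <- function(x, ...) {
  cat(sprintf(
    "IntensityTable: %d proteins x %d samples (%d groups), %s scale, %.1f%% missing, %.1f%% imputed\n",
    nrow(x$values), ncol(x$values), length(unique(x$sample_groups)), x$scale,
    100 * mean(is.na(x$values)), 100 * mean(x$imputed_mask)))
  invisible(x)
}

# column indices of samples belonging to the given group labels
.group_columns <- function(table, groups) {
  which(table$sample_groups[colnames(table$values)] %in% groups)
}

#' Read a MaxQuant-style protein-groups table
#'
#' Parses the proteinGroups TSV dialect: an id column
#' `Majority protein IDs`, a `Peptides` count, flag columns
#' `Potential contaminant`, `Reverse` and `Only identified by site` (marker
#' `"+"`), and one `LFQ intensity <sample>` column per sample. Rows flagged
#' as contaminant, reverse or identified-by-site only are removed, as are
#' protein groups supported by fewer than `min_peptides` peptides. Zero
#' intensities are converted to missing.
#'
#' @param path Protein-groups TSV.
#' @param annotation_path Sample-annotation TSV with columns `sample_id`,
#'   `group` (and optionally `replicate`); every annotated sample must have
#'   an `LFQ intensity` column.
#' @param min_peptides Minimum peptide count per protein group (default 2).
#' @return An `IntensityTable` on the linear scale.
#' @export
read_protein_groups <- function(path, annotation_path, min_peptides = 2L) {
  pg <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(ann))) {
    stop("annotation needs columns sample_id and group")
  }
  idcol <- "Majority protein IDs"
  if (!idcol %in% names(pg)) stop("missing column '", idcol, "'")
  lfq_cols <- paste("LFQ intensity", ann$sample_id)
  missing_cols <- setdiff(lfq_cols, names(pg))
  if (length(missing_cols)) {
    stop("annotated samples without LFQ columns: ",
         paste(sub("^LFQ intensity ", "", missing_cols), collapse = ", "))
  }

  flag <- function(col) {
    if (col %in% names(pg)) pg[[col]] %in% "+" else rep(FALSE, nrow(pg))
  }
  contaminant <- flag("Potential contaminant")
  reverse <- flag("Reverse")
  site_only <- flag("Only identified by site")
  peptides <- if ("Peptides" %in% names(pg)) pg$Peptides else rep(min_peptides, nrow(pg))
  keep <- !contaminant & !reverse & !site_only & peptides >= min_peptides

  vals <- as.matrix(pg[keep, lfq_cols, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric intensity values in ", path)
  vals[vals == 0] <- NA_real_
  rownames(vals) <- pg[[idcol]][keep]
  colnames(vals) <- ann$sample_id

  proteins <- data.frame(protein_id = pg[[idcol]][keep],
                         peptides = peptides[keep],
                         contaminant = FALSE, reverse = FALSE,
                         site_only = FALSE, stringsAsFactors = FALSE)
  groups <- stats::setNames(as.character(ann$group), ann$sample_id)
  intensity_table(vals, groups, proteins = proteins, scale = "linear")
}

#' Write an IntensityTable in the protein-groups TSV dialect
#'
#' Inverse of [read_protein_groups()]: missing values are written as 0 and
#' the flag columns as empty strings. Only valid for linear-scale tables.
#'
#' @param table An `IntensityTable` (linear scale).
#' @param path Output TSV path.
#' @export
write_protein_groups <- function(table, path) {
  stopifnot(inherits(table, "IntensityTable"))
  if (table$scale != "linear") stop("write_protein_groups expects linear scale")
  vals <- table$values
  vals[is.na(vals)] <- 0
  out <- data.frame(
    `Majority protein IDs` = rownames(table$values),
    Peptides = table$proteins$peptides,
    `Potential contaminant` = "", Reverse = "",
    `Only identified by site` = "",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  # 17 significant digits so the value matrix round-trips bit-exactly
  lfq <- as.data.frame(lapply(as.data.frame(vals), sprintf, fmt = "%.17g"))
  names(lfq) <- paste("LFQ intensity", colnames(table$values))
  utils::write.table(cbind(out, lfq), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_protein_groups
#' @param replicate Optional replicate labels; defaults to the sample's
#'   index within its group.
#' @export
write_sample_annotation <- function(table, path, replicate = NULL) {
  stopifnot(inherits(table, "IntensityTable"))
  grp <- table$sample_groups[colnames(table$values)]
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(grp), grp, FUN = seq_along)
  }
  ann <- data.frame(sample_id = colnames(table$values), group = unname(grp),
                    replicate = replicate, stringsAsFactors = FALSE)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter proteins by minimum detection within a group
#'
#' Keeps a protein iff at least one sample group contains `min_valid` or
#' more non-missing values for it, mirroring the "detected in at least n
#' replicates of the same sample" rule. Use `min_valid = 3` for BioID-style
#' quadruplicate designs and `min_valid = 2` for duplicate peptide-array
#' screens.
#'
#' @param table An `IntensityTable`.
#' @param min_valid Required number of non-missing values in some group.
#' @return The filtered `IntensityTable` (row order preserved).
#' @export
filter_min_valid <- function(table, min_valid = 3L) {
  stopifnot(inherits(table, "IntensityTable"))
  if (min_valid <= 0L) return(table)
  grp <- table$sample_groups[colnames(table$values)]
  if (min_valid > max(table(grp))) {
    warning("min_valid exceeds the largest group size; all proteins dropped")
  }
  obs <- !is.na(table$values)
  # per-protein max over groups of the within-group detection count
  counts <- sapply(unique(grp), function(g) {
    rowSums(obs[, grp == g, drop = FALSE])
  })
  counts <- matrix(counts, nrow = nrow(table$values))
  keep <- apply(counts, 1L, max) >= min_valid
  table$values <- table$values[keep, , drop = FALSE]
  table$imputed_mask <- table$imputed_mask[keep, , drop = FALSE]
  table$proteins <- table$proteins[keep, , drop = FALSE]
  table
}

#' Log2-transform a linear-scale intensity table
#'
#' @param table An `IntensityTable` on the linear scale.
#' @return The table with non-missing values replaced by their log2 and the
#'   scale flag updated; missing values stay missing.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "IntensityTable"))
  if (table$scale != "linear") stop("table is already on the log2 scale")
  table$values <- log2(table$values)
  table$scale <- "log2"
  table
}

#' Impute missing values from a downshifted normal distribution
#'
#' Detection-limit imputation for missing-not-at-random LFQ data: for each
#' sample column with observed mean `m` and standard deviation `s`
#' (denominator `n - 1`), missing entries are drawn i.i.d. from
#' `Normal(m - shift * s, width * s)`. The defaults (shift 1.8 SD, width
#' 0.3 SD) place imputed values near the instrument's detection limit, below
#' the bulk of observed intensities. Observed values are never altered.
#'
#' @param table An `IntensityTable` on the log2 scale.
#' @param shift Downshift of the imputation mean, in column-SD units.
#' @param width Ratio of the imputation SD to the column SD.
#' @param seed Optional integer seed for reproducible draws.
#' @return The table with missing entries filled in and `imputed_mask` set.
#' @export
impute_downshift <- function(table, shift = 1.8, width = 0.3, seed = NULL) {
  stopifnot(inherits(table, "IntensityTable"))
  if (table$scale != "log2") stop("impute_downshift expects log2 scale")
  miss <- is.na(table$values)
  if (!any(miss)) return(table)
  if (!is.null(seed)) set.seed(seed)
  for (j in seq_len(ncol(table$values))) {
    mj <- miss[, j]
    if (!any(mj)) next
    obs <- table$values[!mj, j]
    if (length(obs) < 2L) {
      stop("column '", colnames(table$values)[j],
           "' has fewer than 2 observed values; cannot impute")
    }
    m <- mean(obs)
    s <- stats::sd(obs)
    table$values[mj, j] <- stats::rnorm(sum(mj), m - shift * s, width * s)
    table$imputed_mask[mj, j] <- TRUE
  }
  table
}

#' Write / read the processed intensity matrix
#'
#' Plain TSV with protein ids in the first column; used to hand the
#' filtered, transformed, imputed matrix between pipeline stages.
#'
#' @param table An `IntensityTable`.
#' @param path TSV path.
#' @param annotation_path Sample annotation TSV (as written by
#'   [write_sample_annotation()]) used to restore the group map.
#' @export
write_matrix <- function(table, path) {
  stopifnot(inherits(table, "IntensityTable"))
  vals <- as.data.frame(lapply(as.data.frame(table$values), sprintf,
                               fmt = "%.17g"))
  names(vals) <- colnames(table$values)
  df <- data.frame(protein_id = rownames(table$values), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @param scale Scale flag of the stored matrix.
#' @export
read_matrix <- function(path, annotation_path, scale = "log2") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  groups <- stats::setNames(as.character(ann$group), ann$sample_id)
  intensity_table(vals, groups, scale = scale)
}
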