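# single-accession harmonization: first accession of a group, uppercased
.harmonize_ids <- function(ids) {
  toupper(vapply(strsplit(as.character(ids), ";"), `[[`, character(1), 1L))
}

#' Cross-validate peptide-array and proximity-labeling interactomes
#'
#' Combines the significant protein sets of the two screens with an
#' optional literature set. A protein belongs to the high-confidence core
#' iff it was found by both screens, or by one screen and the literature.
#'
#' @param prisma_ids,bioid_ids,literature_ids Character vectors of protein
#'   ids (duplicates are an error; multi-accession groups are reduced to
#'   their first accession, uppercased).
#' @return List with `records` (one row per protein: `protein_id`,
#'   `in_prisma`, `in_bioid`, `in_literature`, `core`) and `counts`
#'   (`prisma`, `bioid`, `overlap` = |P n B|, `prisma_literature_only` =
#'   |P n L \ B|, `bioid_literature_only` = |B n L \ P|, `core`).
#' @export
overlap_sets <- function(prisma_ids, bioid_ids, literature_ids = character(0)) {
  P <- .harmonize_ids(prisma_ids)
  B <- .harmonize_ids(bioid_ids)
  L <- .harmonize_ids(literature_ids)
  for (s in list(P = P, B = B, L = L)) {
    if (anyDuplicated(s)) stop("duplicate protein ids in an input set")
  }
  all_ids <- sort(unique(c(P, B, L)))
  rec <- data.frame(
    protein_id = all_ids,
    in_prisma = all_ids %in% P,
    in_bioid = all_ids %in% B,
    in_literature = all_ids %in% L,
    stringsAsFactors = FALSE
  )
  rec$core <- (rec$in_prisma & rec$in_bioid) |
    ((rec$in_prisma | rec$in_bioid) & rec$in_literature)
  counts <- list(
    prisma = length(P), bioid = length(B),
    overlap = sum(rec$in_prisma & rec$in_bioid),
    prisma_literature_only = sum(rec$in_prisma & rec$in_literature & !rec$in_bioid),
    bioid_literature_only = sum(rec$in_bioid & rec$in_literature & !rec$in_prisma),
    core = sum(rec$core)
  )
  list(records = rec, counts = counts)
}

#' Isoform-preference score from peptide-array profiles
#'
#' Splits the unmodified peptides of the array at the first residue of the
#' short isoform: windows ending before `region_boundary` exist only in the
#' long isoform ("exclusive"), all other windows (including those straddling
#' the boundary) are present in both isoforms. Per protein, the mean spot
#' intensities (linear scale) are summed within each class and divided by
#' the grand total over all unmodified spots, yielding two fractions that
#' sum to 1. PTM-modified peptides are omitted.
#'
#' @param table An `IntensityTable`; log2 tables are converted back to the
#'   linear scale, since intensity sums are a linear-scale notion.
#' @param design The `ArrayDesign`.
#' @param region_boundary 1-based position of the short isoform's first
#'   residue in the long isoform's coordinates.
#' @param proteins Protein ids to score (default: all rows).
#' @return data.frame with `protein_id`, `sum_exclusive`, `sum_shared`,
#'   `total`, `frac_exclusive`, `frac_shared`.
#' @export
isoform_preference <- function(table, design, region_boundary,
                               proteins = rownames(table$values)) {
  stopifnot(inherits(table, "IntensityTable"), inherits(design, "ArrayDesign"))
  L <- nchar(design$protein_sequence)
  if (region_boundary < 1 || region_boundary > L) {
    stop("region_boundary outside the protein (1..", L, ")")
  }
  vals <- table$values
  if (table$scale == "log2") vals <- 2^vals
  vals[is.na(vals)] <- 0
  grp <- table$sample_groups[colnames(vals)]

  unmod <- design$spots[!design$spots$is_modified, , drop = FALSE]
  exclusive <- unmod$spot_id[unmod$end < region_boundary]
  shared <- setdiff(unmod$spot_id, exclusive)

  spot_mean <- function(spot_ids) {
    if (length(spot_ids) == 0L) {
      return(stats::setNames(rep(0, length(proteins)), proteins))
    }
    per_spot <- sapply(spot_ids, function(s) {
      rowMeans(vals[proteins, grp == s, drop = FALSE])
    })
    rowSums(matrix(per_spot, nrow = length(proteins)))
  }
  sum_ex <- spot_mean(exclusive)
  sum_sh <- spot_mean(shared)
  total <- sum_ex + sum_sh
  data.frame(
    protein_id = proteins,
    sum_exclusive = unname(sum_ex), sum_shared = unname(sum_sh),
    total = unname(total),
    frac_exclusive = unname(ifelse(total > 0, sum_ex / total, NA_real_)),
    frac_shared = unname(ifelse(total > 0, sum_sh / total, NA_real_)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Score-threshold and prune an interaction network
#'
#' Keeps edges with score strictly above `min_score` whose endpoints are
#' both in the node set, then removes nodes left without any edge.
#'
#' @param nodes Character vector of node ids.
#' @param edges data.frame with columns `a`, `b`, `score`; edges touching
#'   ids outside `nodes` are ignored.
#' @param min_score Score threshold (default 0.5, strict).
#' @return List with `nodes` (kept), `edges` (kept rows) and
#'   `dropped_nodes` (removed as unconnected).
#' @export
network_filter <- function(nodes, edges, min_score = 0.5) {
  nodes <- as.character(nodes)
  if (is.null(edges) || nrow(edges) == 0L) {
    return(list(nodes = character(0), edges = edges[0, , drop = FALSE],
                dropped_nodes = nodes))
  }
  stopifnot(all(c("a", "b", "score") %in% names(edges)))
  keep <- edges$score > min_score &
    edges$a %in% nodes & edges$b %in% nodes & edges$a != edges$b
  kept_edges <- edges[keep, , drop = FALSE]
  connected <- unique(c(kept_edges$a, kept_edges$b))
  list(nodes = intersect(nodes, connected),
       edges = kept_edges,
       dropped_nodes = setdiff(nodes, connected))
}
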