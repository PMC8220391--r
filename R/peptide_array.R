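#' Tile a protein sequence into fixed-length overlapping peptide spots
#'
#' Generates the unmodified spots of a peptide-array design: fixed-length
#' windows starting at 1, 1+step, 1+2*step, ... along the protein. If the
#' last regular window would overrun the C-terminus, a final window anchored
#' at the C-terminus (positions `L - tile_length + 1` to `L`) is appended so
#' that every residue is covered by at least one fixed-length peptide, unless
#' that window duplicates the last regular one.
#'
#' @param sequence Character scalar, the protein sequence (one-letter amino
#'   acid codes). Must be at least `tile_length` residues long.
#' @param tile_length Integer, peptide length per spot (default 15).
#' @param step Integer, offset between consecutive window starts (default 8,
#'   giving a 7-residue overlap between neighbouring 15-mers).
#' @param protein_id Identifier used as prefix of spot ids.
#' @return An object of class `ArrayDesign`: a list with elements
#'   `protein_id`, `protein_sequence`, `tile_length`, `step` and `spots`, a
#'   data.frame with columns `spot_id`, `protein_id`, `start`, `end`
#'   (1-based, inclusive protein coordinates), `sequence`, `ptms`
#'   (semicolon-joined `pos:res:mod`, empty for unmodified spots) and
#'   `is_modified`.
#' @seealso [add_ptm_variants()], [control_spots()]
#' @export
tile_protein <- function(sequence, tile_length = 15L, step = 8L,
                         protein_id = "protein") {
  sequence <- toupper(as.character(sequence)[1L])
  if (!grepl("^[ARNDCQEGHILKMFPSTWYVUO]+$", sequence)) {
    stop("sequence contains non-amino-acid characters")
  }
  tile_length <- as.integer(tile_length)
  step <- as.integer(step)
  L <- nchar(sequence)
  if (L < tile_length) {
    stop("sequence (", L, " aa) is shorter than tile_length (", tile_length, ")")
  }
  if (step < 1L) stop("step must be >= 1")

  starts <- seq.int(1L, L - tile_length + 1L, by = step)
  anchor <- L - tile_length + 1L
  if (starts[length(starts)] != anchor) starts <- c(starts, anchor)
  ends <- starts + tile_length - 1L

  spots <- data.frame(
    spot_id     = sprintf("%s_%03d", protein_id, seq_along(starts)),
    protein_id  = protein_id,
    start       = starts,
    end         = ends,
    sequence    = substring(sequence, starts, ends),
    ptms        = "",
    is_modified = FALSE,
    stringsAsFactors = FALSE
  )
  structure(
    list(protein_id = protein_id, protein_sequence = sequence,
         tile_length = tile_length, step = step, spots = spots),
    class = "ArrayDesign"
  )
}

#' @export
print.ArrayDesign <- function(x, ...) {
  cat("ArrayDesign for", x$protein_id,
      sprintf("(%d aa): %d spots (%d modified), tile %d, step %d\n",
              nchar(x$protein_sequence), nrow(x$spots),
              sum(x$spots$is_modified), x$tile_length, x$step))
  invisible(x)
}

# one-row spot accessor with validation
.get_spot <- function(design, spot_id) {
  i <- match(spot_id, design$spots$spot_id)
  if (is.na(i)) stop("spot '", spot_id, "' not found in design")
  design$spots[i, , drop = FALSE]
}

#' Add PTM variant spots to an array design
#'
#' For every unmodified spot whose window contains all positions of a PTM
#' variant, a modified sibling spot with the identical window is appended.
#' Residues are never mutated: modifications annotate positions. A variant
#' with several rows sharing the same `variant` label yields a single
#' multi-PTM sibling (only for spots containing all of its positions);
#' combinatorial variants are therefore created only when explicitly listed.
#'
#' @param design An `ArrayDesign`.
#' @param ptm_spec data.frame with columns `position` (1-based protein
#'   coordinate), `residue` (expected residue at that position) and
#'   `modification` (label such as `"me2"`, `"ph"`, `"ac"`); optional column
#'   `variant` groups rows applied jointly (default: one variant per row).
#' @return The design with modified sibling spots appended. Sibling spot ids
#'   are `parent_id` + `_` + `modification` + `position` (joined by `.` for
#'   multi-PTM variants), giving deterministic, join-stable identifiers.
#' @export
add_ptm_variants <- function(design, ptm_spec) {
  stopifnot(inherits(design, "ArrayDesign"))
  if (is.null(ptm_spec) || nrow(ptm_spec) == 0L) return(design)
  needed <- c("position", "residue", "modification")
  if (!all(needed %in% names(ptm_spec))) {
    stop("ptm_spec must have columns position, residue, modification")
  }
  ptm_spec$position <- as.integer(ptm_spec$position)
  seq_res <- substring(design$protein_sequence, ptm_spec$position, ptm_spec$position)
  bad <- seq_res != toupper(ptm_spec$residue)
  if (any(bad)) {
    stop("PTM residue mismatch at position(s) ",
         paste(ptm_spec$position[bad], collapse = ", "),
         ": protein has ", paste(seq_res[bad], collapse = ", "))
  }
  if (is.null(ptm_spec$variant)) ptm_spec$variant <- seq_len(nrow(ptm_spec))

  parents <- design$spots[!design$spots$is_modified, , drop = FALSE]
  new_rows <- list()
  for (v in unique(ptm_spec$variant)) {
    rows <- ptm_spec[ptm_spec$variant == v, , drop = FALSE]
    rows <- rows[order(rows$position), , drop = FALSE]
    label <- paste0(rows$modification, rows$position, collapse = ".")
    ptm_str <- paste(sprintf("%d:%s:%s", rows$position, rows$residue,
                             rows$modification), collapse = ";")
    hit <- vapply(seq_len(nrow(parents)), function(i) {
      all(rows$position >= parents$start[i] & rows$position <= parents$end[i])
    }, logical(1))
    if (!any(hit)) next
    sib <- parents[hit, , drop = FALSE]
    sib$spot_id <- paste(sib$spot_id, label, sep = "_")
    sib$ptms <- ptm_str
    sib$is_modified <- TRUE
    new_rows[[length(new_rows) + 1L]] <- sib
  }
  if (length(new_rows)) {
    design$spots <- rbind(design$spots, do.call(rbind, new_rows))
    if (anyDuplicated(design$spots$spot_id)) {
      stop("duplicate spot ids after adding PTM variants")
    }
    rownames(design$spots) <- NULL
  }
  design
}

#' Positional overlap between two peptide spots
#'
#' Fraction of the tile covered by the intersection of the two spots'
#' protein windows: `|[a.start, a.end] n [b.start, b.end]| / tile_length`.
#' PTM state is ignored, so a spot and its PTM sibling score 1. Both spots
#' must derive from the same protein and have equal tile length.
#'
#' @param a,b One-row data.frames (rows of `design$spots`) or lists with
#'   fields `protein_id`, `start`, `end`.
#' @return A fraction in `[0, 1]`, symmetric in its arguments.
#' @export
positional_overlap <- function(a, b) {
  if (a$protein_id[1L] != b$protein_id[1L]) {
    stop("spots belong to different proteins")
  }
  la <- a$end[1L] - a$start[1L] + 1L
  lb <- b$end[1L] - b$start[1L] + 1L
  if (la != lb) stop("spots have different tile lengths")
  shared <- min(a$end[1L], b$end[1L]) - max(a$start[1L], b$start[1L]) + 1L
  max(0L, shared) / la
}

#' Peptide-specific control group for a target spot
#'
#' Returns the spot ids forming the null group for a target peptide: every
#' other spot on the array whose positional overlap with the target is below
#' `threshold`. At the default threshold of 0.5 this excludes the target's
#' immediate window (and all its PTM siblings, which overlap fully) while
#' retaining adjacent tiles (7/15 overlap with the default design). Spots
#' with zero overlap are always eligible, so a threshold of 0 reduces the
#' group to disjoint spots only.
#'
#' @param design An `ArrayDesign`.
#' @param target A spot id present in the design.
#' @param threshold Overlap fraction at or above which a spot is excluded
#'   from the control group (default 0.5).
#' @return Character vector of control spot ids (possibly empty).
#' @export
control_spots <- function(design, target, threshold = 0.5) {
  stopifnot(inherits(design, "ArrayDesign"))
  tgt <- .get_spot(design, target)
  others <- design$spots[design$spots$spot_id != target, , drop = FALSE]
  if (nrow(others) == 0L) return(character(0))
  ov <- vapply(seq_len(nrow(others)), function(i) {
    positional_overlap(tgt, others[i, , drop = FALSE])
  }, numeric(1))
  others$spot_id[ov < threshold | ov == 0]
}

#' Read a single protein sequence from a FASTA file
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return List with `protein_id` (first word of the header) and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) != 1L) {
    stop("expected a single-record FASTA, found ", length(aa), " records")
  }
  id <- strsplit(names(aa)[1L], "\\s+")[[1L]][1L]
  list(protein_id = id, sequence = as.character(aa[[1L]]))
}

#' Write / read an array design as TSV
#'
#' The on-disk format is one row per spot with columns `spot_id`,
#' `protein_id`, `start`, `end`, `sequence`, `ptms`, `is_modified`.
#' `read_design()` reconstructs the parent protein sequence from the
#' unmodified tiles (which by construction cover every residue).
#'
#' @param design An `ArrayDesign`.
#' @param path Output / input TSV path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "ArrayDesign"))
  utils::write.table(design$spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  spots <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(ptms = "character"))
  spots$ptms[is.na(spots$ptms)] <- ""
  unmod <- spots[!spots$is_modified, , drop = FALSE]
  L <- max(unmod$end)
  chars <- character(L)
  for (i in seq_len(nrow(unmod))) {
    chars[unmod$start[i]:unmod$end[i]] <-
      strsplit(unmod$sequence[i], "")[[1L]]
  }
  tl <- unique(unmod$end - unmod$start + 1L)
  if (length(tl) != 1L) stop("tiles in design file have unequal lengths")
  step <- if (nrow(unmod) > 1L) min(diff(sort(unique(unmod$start)))) else tl
  structure(
    list(protein_id = unmod$protein_id[1L],
         protein_sequence = paste(chars, collapse = ""),
         tile_length = tl, step = as.integer(step), spots = spots),
    class = "ArrayDesign"
  )
}
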