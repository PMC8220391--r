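test_that("tiling enumerates fixed-length windows with a C-terminal anchor", {
  d <- tile_protein(toy_sequence(30), tile_length = 15, step = 8)
  expect_equal(d$spots$start, c(1, 9, 16))
  expect_equal(d$spots$end, c(15, 23, 30))
  expect_equal(unique(nchar(d$spots$sequence)), 15)

  # exact fit: single window
  d1 <- tile_protein(toy_sequence(15))
  expect_equal(nrow(d1$spots), 1L)
  expect_equal(c(d1$spots$start, d1$spots$end), c(1, 30 - 15))

  # no duplicated anchor when the last regular window already ends at L
  d2 <- tile_protein(toy_sequence(31), tile_length = 15, step = 8)
  expect_equal(d2$spots$start, c(1, 9, 17))
  expect_false(anyDuplicated(d2$spots$spot_id) > 0)

  expect_error(tile_protein(toy_sequence(10)), "shorter")
  expect_error(tile_protein("ACDEFGHIKLMNPQ1"), "non-amino-acid")
})

test_that("tiles reconstruct the parent sequence and cover every residue", {
  for (L in c(15, 40, 87, 101)) {
    seq <- toy_sequence(L)
    d <- tile_protein(seq, 15, 8)
    chars <- character(L)
    for (i in seq_len(nrow(d$spots))) {
      win <- d$spots$start[i]:d$spots$end[i]
      tile <- strsplit(d$spots$sequence[i], "")[[1L]]
      # tiles never disagree with previously placed residues
      placed <- chars[win] != ""
      expect_identical(chars[win][placed], tile[placed])
      chars[win] <- tile
    }
    expect_identical(paste(chars, collapse = ""), seq)
  }
})

test_that("PTM variants are appended for every window containing the site", {
  d <- tile_protein(toy_sequence(30), 15, 8)
  res10 <- substr(toy_sequence(30), 10, 10)
  d2 <- add_ptm_variants(d, data.frame(position = 10, residue = res10,
                                       modification = "me"))
  added <- d2$spots[d2$spots$is_modified, ]
  expect_equal(nrow(added), 2L)  # position 10 lies in (1,15) and (9,23)
  expect_setequal(paste(added$start, added$end), c("1 15", "9 23"))
  expect_identical(added$sequence,
                   d$spots$sequence[match(added$start, d$spots$start)])

  # empty spec: unchanged
  expect_identical(add_ptm_variants(d, NULL), d)

  # site in the last window only
  res30 <- substr(toy_sequence(30), 30, 30)
  d3 <- add_ptm_variants(d, data.frame(position = 30, residue = res30,
                                       modification = "ph"))
  expect_equal(sum(d3$spots$is_modified), 1L)
  expect_equal(d3$spots$start[d3$spots$is_modified], 16)

  # residue mismatch rejected
  wrong <- setdiff(c("A", "C"), res10)[1L]
  expect_error(add_ptm_variants(d, data.frame(position = 10, residue = wrong,
                                              modification = "me")),
               "mismatch")
})

test_that("multi-PTM variants require an explicit joint listing", {
  d <- tile_protein(toy_sequence(30), 15, 8)
  s <- toy_sequence(30)
  spec <- data.frame(position = c(10, 12), residue = substring(s, c(10, 12), c(10, 12)),
                     modification = c("me", "ac"), variant = "double")
  d2 <- add_ptm_variants(d, spec)
  added <- d2$spots[d2$spots$is_modified, ]
  expect_equal(nrow(added), 2L)  # one joint sibling per containing window
  expect_true(all(grepl("10:.*:me;12:.*:ac", added$ptms)))
})

test_that("positional overlap is the shared-coordinate fraction of the tile", {
  d <- tile_protein(toy_sequence(30), 15, 8)
  sp <- function(i) d$spots[i, ]
  expect_equal(positional_overlap(sp(1), sp(2)), 7 / 15)
  expect_equal(positional_overlap(sp(2), sp(1)), 7 / 15)  # symmetric
  expect_equal(positional_overlap(sp(1), sp(3)), 0)
  expect_equal(positional_overlap(sp(1), sp(1)), 1)

  # PTM sibling: same window, overlap 1 regardless of modification state
  res10 <- substr(toy_sequence(30), 10, 10)
  d2 <- add_ptm_variants(d, data.frame(position = 10, residue = res10,
                                       modification = "me"))
  sib <- d2$spots[d2$spots$is_modified & d2$spots$start == 1, ]
  expect_equal(positional_overlap(d2$spots[1, ], sib), 1)

  other <- sp(1); other$protein_id <- "OTHER"
  expect_error(positional_overlap(other, sp(2)), "different proteins")
})

test_that("control groups exclude the window and its PTM siblings", {
  d <- tile_protein(toy_sequence(30), 15, 8)
  res10 <- substr(toy_sequence(30), 10, 10)
  d <- add_ptm_variants(d, data.frame(position = 10, residue = res10,
                                      modification = "me"))
  sib_id <- d$spots$spot_id[d$spots$is_modified & d$spots$start == 1]
  target <- d$spots$spot_id[1]  # window (1,15)

  ctrl <- control_spots(d, target, 0.5)
  # eligible: window (9,23) and its own PTM sibling (7/15 < 0.5) and the
  # disjoint window (16,30); never the target or its sibling
  expect_setequal(ctrl, d$spots$spot_id[d$spots$start %in% c(9, 16)])
  expect_false(target %in% ctrl)
  expect_false(sib_id %in% ctrl)

  # threshold 0: only disjoint windows remain
  ctrl0 <- control_spots(d, target, 0)
  expect_setequal(ctrl0, d$spots$spot_id[d$spots$start == 16])

  # the anchored C-terminal tile (16,30) shares 8 residues with (9,23):
  # 8/15 >= 0.5, so that neighbour is excluded from its control group
  ctrl3 <- control_spots(d, d$spots$spot_id[3], 0.5)
  expect_setequal(ctrl3, d$spots$spot_id[d$spots$start == 1])

  expect_error(control_spots(d, "nope"), "not found")
})

test_that("with the default 15/8 design every non-sibling spot is a control", {
  d <- toy_design()
  for (target in d$spots$spot_id) {
    ctrl <- control_spots(d, target, 0.5)
    expect_setequal(ctrl, setdiff(d$spots$spot_id, target))
  }
})

test_that("design TSV and FASTA round-trips preserve the array", {
  d <- toy_design()
  res42 <- substr(toy_sequence(87), 42, 42)
  d <- add_ptm_variants(d, data.frame(position = 42, residue = res42,
                                      modification = "me2"))
  tsv <- tempfile(fileext = ".tsv")
  write_design(d, tsv)
  d2 <- read_design(tsv)
  expect_identical(d2$spots$spot_id, d$spots$spot_id)
  expect_identical(d2$protein_sequence, d$protein_sequence)
  expect_equal(d2$tile_length, d$tile_length)
  expect_equal(d2$step, d$step)

  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">CEBPA test protein", toy_sequence(87)), fa)
  rec <- read_protein_fasta(fa)
  expect_identical(rec$protein_id, "CEBPA")
  expect_identical(rec$sequence, toy_sequence(87))

  writeLines(c(">a", "ACDEF", ">b", "GHIKL"), fa)
  expect_error(read_protein_fasta(fa), "single-record")
})
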