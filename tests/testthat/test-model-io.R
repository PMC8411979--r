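test_that("mmCIF round trip preserves coordinates to format precision", {
  dup <- build_duplex(2, pair_spec(category = "RNA-RNA",
                                   pair_type = "A-U", buckle = 5),
                      resolution = 2.45)
  f <- tempfile(fileext = ".cif")
  write_structure_cif(dup, f)
  st <- read_structure(f)
  expect_s3_class(st, "nucval_structure")
  expect_length(st$residues, 4)
  expect_equal(st$resolution, 2.45)
  for (k in names(dup$residues)) {
    a0 <- dup$residues[[k]]$atoms
    a1 <- st$residues[[k]]$atoms
    expect_setequal(a1$name, a0$name)
    m <- match(a0$name, a1$name)
    expect_lt(max(abs(as.matrix(a1[m, c("x", "y", "z")]) -
                        as.matrix(a0[, c("x", "y", "z")]))), 1e-3 + 1e-9)
  }
  ## Re-reading the same file reproduces measured geometry.
  p0 <- validate_model(dup)$model$rmsz_bpg
  p1 <- validate_model(st)$model$rmsz_bpg
  expect_equal(p1, p0, tolerance = 0.05)
})

test_that("PDB fixed-column input parses with resolution", {
  pdb <- tempfile(fileext = ".pdb")
  gc <- build_pair(pair_spec(category = "DNA-DNA", pair_type = "G-C"))
  lines <- c("REMARK   2 RESOLUTION.    3.71 ANGSTROMS.")
  n <- 0
  for (res in gc$residues) {
    for (i in seq_len(nrow(res$atoms))) {
      n <- n + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        n, res$atoms$name[i], " ", res$comp_id, res$chain_id,
        res$seq_num, " ", res$atoms$x[i], res$atoms$y[i], res$atoms$z[i],
        1.0, 10.0, res$atoms$element[i]))
    }
  }
  writeLines(c(lines, "END"), pdb)
  st <- read_structure(pdb, format = "pdb")
  expect_equal(st$resolution, 3.71)
  expect_length(st$residues, 2)
  det <- find_wc_pairs(st)
  expect_length(det$pairs, 1)
  expect_equal(det$pairs[[1]]$pair_type, "G-C")
})

test_that("residue classification is total and idempotent", {
  mk <- function(comp, atoms = character(0)) {
    nucval:::classify_residue(list(
      chain_id = "A", seq_num = 1, insertion_code = "", comp_id = comp,
      atoms = data.frame(name = atoms, element = substr(atoms, 1, 1),
                         x = seq_along(atoms), y = 0, z = 0,
                         altloc = "", occupancy = 1,
                         stringsAsFactors = FALSE),
      had_altloc = FALSE))
  }
  dg <- mk("DG", standard_base("G")$atoms)
  expect_equal(dg$parent_base, "G")
  expect_equal(dg$nucleic_class, "DNA")
  expect_false(dg$is_modified)

  u <- mk("U", standard_base("U")$atoms)
  expect_equal(u$parent_base, "U")
  expect_equal(u$nucleic_class, "RNA")

  ## Listed modification maps to its parent and is flagged.
  m5c <- mk("5MC", standard_base("C")$atoms)
  expect_equal(m5c$parent_base, "C")
  expect_true(m5c$is_modified)

  ## Unlisted component falls back to ring-atom matching.
  weird <- mk("XXG", c(standard_base("G")$atoms, "O2'"))
  expect_equal(weird$parent_base, "G")
  expect_equal(weird$nucleic_class, "RNA")
  expect_true(weird$is_modified)

  ## Unmatched -> other, with parent none.
  his <- mk("HIS", c("N", "CA", "CB", "CG"))
  expect_equal(his$parent_base, "none")
  expect_equal(his$nucleic_class, "other")

  ## Idempotence.
  again <- classify_residue(dg)
  expect_identical(again$parent_base, dg$parent_base)
  expect_identical(again$nucleic_class, dg$nucleic_class)
})

test_that("alternate conformations collapse to one conformer", {
  st <- build_pair(pair_spec(category = "DNA-DNA", pair_type = "G-C"))
  ## No altlocs: untouched.
  st1 <- select_conformation(st)
  expect_identical(st1$residues[[1]]$atoms, st$residues[[1]]$atoms)
  expect_false(st1$residues[[1]]$had_altloc)

  ## Duplicate the guanine as conformers A (0.6) and B (0.4).
  g <- st$residues[[1]]
  a <- g$atoms; a$altloc <- "A"; a$occupancy <- 0.6
  b <- g$atoms; b$altloc <- "B"; b$occupancy <- 0.4
  b$x <- b$x + 0.5
  g$atoms <- rbind(a, b)
  st$residues[[1]] <- g
  st2 <- select_conformation(st)
  r <- st2$residues[[1]]
  expect_true(r$had_altloc)
  expect_true(all(r$atoms$altloc == "A"))
  expect_equal(nrow(r$atoms), nrow(a))

  ## Requested missing altloc falls back to highest occupancy.
  expect_message(
    st3 <- select_conformation(st, policy = "altloc_id", altloc_id = "C"),
    "falling back")
  expect_true(all(st3$residues[[1]]$atoms$altloc == "A"))

  ## Flagged residues produce no restraints.
  det <- find_wc_pairs(st2)
  expect_length(det$pairs, 1)
  hb <- hbond_restraints(det$pairs, st2)
  expect_equal(nrow(hb), 0)
  expect_match(attr(hb, "skipped"), "altloc")
})

test_that("RSCC sidecar parsing validates rows and keys", {
  f <- tempfile()
  writeLines(character(0), f)
  expect_length(read_rscc_table(f), 0)

  writeLines(c("chain seqnum ins rscc", "B 44 . 0.97", "X 57 A 0.88"), f)
  m <- read_rscc_table(f)
  expect_equal(unname(m["B/44"]), 0.97)
  expect_equal(unname(m["X/57A"]), 0.88)

  writeLines(c("B 44 . 0.97", "B 44 . 0.95"), f)
  expect_error(read_rscc_table(f), "duplicate")
  writeLines("B 44 . 1.97", f)
  expect_error(read_rscc_table(f), "out of range")
  writeLines("B 44 0.97", f)
  expect_error(read_rscc_table(f), "malformed")
})
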