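test_that("reading keeps protein ATOM records and drops waters and nucleic chains", {
  s <- readStructure(fixture_pdb_text())
  expect_s4_class(s, "ProteinStructure")
  expect_equal(nAtoms(s), 38L)            # GLY 4 + ALA 5 + SER 6 + LYS 9 + TRP 14
  expect_false(any(atoms(s)$residue_name %in% c("HOH", "DA", "DC", "DG", "DT")))
  expect_equal(length(residueKeys(s)), 5L)
})

test_that("a file whose only chain is nucleic yields an empty-structure error", {
  lines <- vapply(1:4, function(i) sprintf(
    "ATOM  %5d  P    D%s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           P",
    i, c("A", "C", "G", "T")[i], i, 1 + i, 0, 0, 1, 0), character(1))
  expect_error(readStructure(c(lines, "END")), "empty structure")
})

test_that("no ATOM records and malformed coordinates are distinct failures", {
  expect_error(readStructure("HEADER    NOTHING\nEND"), "empty structure")
  bad <- fixture_pdb_text()
  substr(bad[3], 31, 38) <- "  xx.yyy"
  err <- tryCatch(readStructure(bad), error = conditionMessage)
  expect_match(err, "malformed record")
  expect_match(err, "line 3")
})

test_that("both chains of a two-chain file stay in one structure, in file order", {
  s1 <- line_structure(c("ALA", "GLY"), chain = "A")
  s2 <- line_structure(c("SER", "LYS"), chain = "B")
  a2 <- atoms(s2); a2$y <- a2$y + 20
  both <- methods::new("ProteinStructure",
                       atoms = rbind(atoms(s1), a2), sourceId = "AB",
                       ecLabel = NA_character_, depositionDate = as.Date(NA))
  s <- readStructure(writeStructure(both))
  expect_equal(unique(atoms(s)$chain_id), c("A", "B"))
  expect_equal(atoms(s)$atom_name, atoms(both)$atom_name)
})

test_that("alternate locations resolve to highest occupancy, ties to first", {
  base <- writeStructure(line_structure(c("ALA")))
  alt1 <- "ATOM      1  CA AALA A   9      50.000   0.000   0.000  0.40  0.00           C"
  alt2 <- "ATOM      2  CA BALA A   9      60.000   0.000   0.000  0.60  0.00           C"
  s <- readStructure(c(setdiff(base, "END"), alt1, alt2, "END"))
  ca9 <- atoms(s)[atoms(s)$residue_seq == 9, ]
  expect_equal(nrow(ca9), 1L)
  expect_equal(ca9$x, 60)                 # higher occupancy wins
  # tie: equal occupancy keeps the first record
  alt2b <- sub("0.60", "0.40", alt2)
  s2 <- readStructure(c(setdiff(base, "END"), alt1, alt2b, "END"))
  expect_equal(atoms(s2)[atoms(s2)$residue_seq == 9, "x"], 50)
})

test_that("multi-model files keep model 1 only; hydrogens drop unless kept", {
  body <- setdiff(writeStructure(line_structure(c("GLY"))), "END")
  shifted <- sub("   0.000   0.000   0.000", "  99.000   0.000   0.000",
                 body, fixed = TRUE)
  txt <- c("MODEL        1", body, "ENDMDL", "MODEL        2", shifted,
           "ENDMDL", "END")
  s <- readStructure(txt)
  expect_equal(nAtoms(s), 4L)
  expect_false(any(atoms(s)$x > 90))
  h <- "ATOM      9  H   GLY A   1       0.500   0.500   0.500  1.00  0.00           H"
  txt2 <- c(body, h, "END")
  expect_equal(nAtoms(readStructure(txt2)), 4L)
  expect_equal(nAtoms(readStructure(txt2, keepHydrogens = TRUE)), 5L)
})

test_that("write/read round trip preserves atoms and coordinates", {
  s <- makeToyStructure(15, defaultClassSpecs()[[2]], seed = 9)$structure
  s2 <- readStructure(writeStructure(s))
  expect_equal(nAtoms(s2), nAtoms(s))
  expect_equal(atoms(s2)$atom_name, atoms(s)$atom_name)
  expect_equal(atoms(s2)$residue_name, atoms(s)$residue_name)
  expect_equal(atoms(s2)$x, atoms(s)$x, tolerance = 1e-3)
  expect_equal(atoms(s2)$z, atoms(s)$z, tolerance = 1e-3)
})

test_that("alanine mutation truncates at CB and leaves the backbone untouched", {
  s <- line_structure(c("GLY", "LYS", "TRP"))
  lys_atoms <- sum(atoms(s)$residue_seq == 2)
  expect_equal(lys_atoms, 9L)
  m <- mutateToAlanine(s, "A|2")
  ma <- atoms(m)[atoms(m)$residue_seq == 2, ]
  expect_equal(nrow(ma), 5L)
  expect_setequal(ma$atom_name, c("N", "CA", "C", "O", "CB"))
  expect_equal(unique(ma$residue_name), "ALA")
  # untouched residues and backbone coordinates are bit-identical
  bb <- c("N", "CA", "C", "O")
  before <- atoms(s)[atoms(s)$atom_name %in% bb, c("x", "y", "z")]
  after <- atoms(m)[atoms(m)$atom_name %in% bb, c("x", "y", "z")]
  expect_identical(unname(as.matrix(before)), unname(as.matrix(after)))
  # glycine gains no atoms
  g <- mutateToAlanine(s, "A|1")
  expect_equal(sum(atoms(g)$residue_seq == 1), 4L)
  expect_equal(atoms(g)$residue_name[1], "ALA")
})

test_that("alanine mutation is a fixed point on poly-alanine and on empty selections", {
  s <- line_structure(rep("ALA", 4))
  expect_equal(atoms(mutateToAlanine(s, NULL)), atoms(s))
  s2 <- line_structure(c("LYS", "TRP"))
  expect_identical(atoms(mutateToAlanine(s2, character(0))), atoms(s2))
  # predicate selector form
  m <- mutateToAlanine(s2, function(res, chain, seq) res == "LYS")
  expect_equal(sum(atoms(m)$residue_seq == 1), 5L)
  expect_equal(sum(atoms(m)$residue_seq == 2), 14L)
})

test_that("coordinate perturbation is bounded, seeded and order-preserving", {
  s <- line_structure(c("SER", "LYS", "TRP"))
  expect_identical(atoms(perturbCoordinates(s, 0, seed = 5)), atoms(s))
  p1 <- perturbCoordinates(s, 2.5, seed = 7)
  p2 <- perturbCoordinates(s, 2.5, seed = 7)
  expect_identical(atoms(p1), atoms(p2))
  expect_equal(atoms(p1)$atom_name, atoms(s)$atom_name)
  disp <- sqrt((atoms(p1)$x - atoms(s)$x)^2 + (atoms(p1)$y - atoms(s)$y)^2 +
               (atoms(p1)$z - atoms(s)$z)^2)
  expect_true(all(disp <= 2.5 + 1e-12))
  expect_true(any(disp > 0))
  expect_error(perturbCoordinates(s, -1), "invalid amplitude")
})
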