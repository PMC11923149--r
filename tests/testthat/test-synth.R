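test_that("generated chains have ideal spacing, no clashes, and a centered motif", {
  toy <- makeToyStructure(40, defaultClassSpecs()[[1]], seed = 2)
  ca <- pocketec:::calpha_table(toy$structure)
  pos <- cbind(ca$x, ca$y, ca$z)
  consec <- sqrt(rowSums((pos[-1, ] - pos[-nrow(pos), ])^2))
  expect_true(all(abs(consec - 3.8) < 0.01))
  expect_gt(min(stats::dist(pos)), 2.5)
  # motif residues sit within the placement radius of the site center
  motif_rows <- which(ca$residue_name %in% c("SER", "HIS", "ASP"))
  spec <- defaultClassSpecs()[[1]]
  d <- sqrt(colSums((t(pos) - toy$site@center)^2))
  expect_gte(sum(d[motif_rows] <= spec$placementRadius), 6L)
  expect_equal(toy$label, 1L)
})

test_that("generation is bit-identical under the same seed", {
  a <- makeToyStructure(25, defaultClassSpecs()[[3]], seed = 99)
  b <- makeToyStructure(25, defaultClassSpecs()[[3]], seed = 99)
  expect_identical(atoms(a$structure), atoms(b$structure))
  expect_identical(a$site@center, b$site@center)
  c2 <- makeToyStructure(25, defaultClassSpecs()[[3]], seed = 100)
  expect_false(identical(atoms(a$structure), atoms(c2$structure)))
})

test_that("custom motif geometries are validated for 3D realizability", {
  # consecutive 3.8 with a compatible skip distance: realizable
  ok <- matrix(c(0, 3.8, 5.4,
                 3.8, 0, 3.8,
                 5.4, 3.8, 0), 3, 3)
  sp <- motifSpec(1L, c("SER", "HIS", "ASP"), geometry = ok)
  toy <- makeToyStructure(20, sp, seed = 4)
  ca <- pocketec:::calpha_table(toy$structure)
  pos <- cbind(ca$x, ca$y, ca$z)
  consec <- sqrt(rowSums((pos[-1, ] - pos[-nrow(pos), ])^2))
  expect_true(all(abs(consec - 3.8) < 0.011))
  # violating the triangle inequality is rejected
  bad <- matrix(c(0, 3.8, 50,
                  3.8, 0, 3.8,
                  50, 3.8, 0), 3, 3)
  expect_error(motifSpec(1L, c("SER", "HIS", "ASP"), geometry = bad),
               "infeasible motif")
  # breaking chain continuity is rejected
  bad2 <- matrix(c(0, 10, 12,
                   10, 0, 10,
                   12, 10, 0), 3, 3)
  expect_error(motifSpec(1L, c("SER", "HIS", "ASP"), geometry = bad2),
               "3.8")
  expect_error(makeToyStructure(5, defaultClassSpecs()[[1]]), "nResidues")
})

test_that("class descriptors differ in node-type multiset; decoys stay out of the local cut", {
  scheme <- defaultAnnotationScheme()
  specs <- defaultClassSpecs()
  t1 <- makeToyStructure(60, specs[[1]], seed = 7)
  t2 <- makeToyStructure(60, specs[[2]], seed = 7)
  g1 <- datasetGraphs(list(t1), scheme, parameter = 20)[[1]]
  g2 <- datasetGraphs(list(t2), scheme, parameter = 20)[[1]]
  expect_false(identical(sort(g1@types), sort(g2@types)))
  # decoy: wrong-class motif far from the center never enters the cut
  td <- makeToyStructure(60, specs[[1]], seed = 8, decoyMotif = specs[[2]])
  gd <- datasetGraphs(list(td), scheme, parameter = 20)[[1]]
  decoy_keys <- paste0("A|", 55:60)
  expect_false(any(decoy_keys %in% gd@provenance$keys))
  # the decoy types are present in the full structure though
  ca <- pocketec:::calpha_table(td$structure)
  expect_true(all(c("CYS", "MET", "TRP") %in% ca$residue_name[55:60]))
})

test_that("the emitted lineage clustering fold-splits cleanly and files are consumable", {
  dir <- file.path(tempdir(), "synthds")
  ds <- makeDataset(6L, decoyRate = 0.2, seed = 3L, nResidues = 40L,
                    nLineages = 3L, dir = dir)
  expect_length(ds$entries, 24L)
  sp <- foldSplit(ds$clustering, ds$labels, seed = 1)
  expect_equal(nrow(verifySplit(sp, ds$clustering, ds$labels)), 0L)
  # written artifacts load back through the standard readers
  sites <- readSiteTable(file.path(dir, "sites.csv"))
  expect_length(sites, 24L)
  cl <- readClusterTSV(file.path(dir, "clusters.tsv"))
  expect_identical(unname(cl[names(ds$clustering)]), unname(ds$clustering))
  s <- readStructure(file.path(dir, paste0(ds$entries[[1]]$id, ".pdb")))
  expect_equal(length(residueKeys(s)), 40L)
  expect_equal(sites[[ds$entries[[1]]$id]][[1]]@center,
               ds$entries[[1]]$site@center, tolerance = 1e-4)
  unlink(dir, recursive = TRUE)
})

test_that("a nearest-centroid baseline separates the default fixture but fails random centers", {
  scheme <- defaultAnnotationScheme()
  ds <- makeDataset(12L, seed = 21L, nResidues = 50L)
  histos <- function(graphs) t(vapply(graphs, function(g)
    tabulate(g@types, 21L), numeric(21)))
  graphs <- datasetGraphs(ds$entries, scheme, parameter = 25)
  y <- vapply(ds$entries, `[[`, integer(1), "label")
  H <- histos(graphs)
  # leave-one-out nearest centroid
  noc <- function(H, y) {
    mean(vapply(seq_len(nrow(H)), function(i) {
      cent <- t(vapply(sort(unique(y)), function(c)
        colMeans(H[y == c & seq_len(nrow(H)) != i, , drop = FALSE]),
        numeric(ncol(H))))
      dd <- rowSums((cent - matrix(H[i, ], nrow(cent), ncol(H),
                                   byrow = TRUE))^2)
      which.min(dd) == y[i]
    }, logical(1)))
  }
  expect_gte(noc(H, y), 0.9)
  # random site centers destroy the signal: accuracy drops toward chance
  rnd <- lapply(seq_along(ds$entries), function(i) {
    e <- ds$entries[[i]]
    list(structure = e$structure,
         site = randomCenter(e$structure, seed = 5000 + i),
         label = e$label)
  })
  Hr <- histos(datasetGraphs(rnd, scheme, parameter = 25))
  expect_lt(noc(Hr, y), noc(H, y) - 0.2)
})
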