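mk_items <- function(spec) {
  # spec: list(ec = list(cluster_sizes))
  clustering <- character(0); labels <- character(0)
  for (ec in names(spec)) {
    for (ci in seq_along(spec[[ec]])) {
      n <- spec[[ec]][ci]
      ids <- sprintf("%s_c%d_%02d", ec, ci, seq_len(n))
      clustering[ids] <- sprintf("%s_cl%d", ec, ci)
      labels[ids] <- ec
    }
  }
  list(clustering = clustering, labels = labels)
}

test_that("an EC with three equal clusters puts one whole cluster per partition", {
  f <- mk_items(list(`1.1.1.1` = c(4, 4, 4)))
  sp <- foldSplit(f$clustering, f$labels, seed = 2)
  per_cluster <- split(unname(sp), f$clustering[names(sp)])
  expect_true(all(vapply(per_cluster, function(p) length(unique(p)) == 1L,
                         logical(1))))
  expect_setequal(vapply(per_cluster, `[`, character(1), 1),
                  c("train", "val", "test"))
})

test_that("an EC with two clusters sends the smaller to test and divides the larger", {
  f <- mk_items(list(`2.7.1.1` = c(8, 2)))
  sp <- foldSplit(f$clustering, f$labels, seed = 3)
  small <- names(f$clustering)[f$clustering == "2.7.1.1_cl2"]
  big <- names(f$clustering)[f$clustering == "2.7.1.1_cl1"]
  expect_true(all(sp[small] == "test"))
  expect_setequal(unique(sp[big]), c("train", "val"))
  expect_false(any(sp[big] == "test"))
})

test_that("a single-cluster EC is divided by ratio; a singleton EC goes to train", {
  f <- mk_items(list(`3.1.1.1` = c(10)))
  sp <- foldSplit(f$clustering, f$labels, seed = 4)
  expect_equal(sum(sp == "train"), 8L)
  expect_equal(sum(sp == "val"), 1L)
  expect_equal(sum(sp == "test"), 1L)
  f2 <- mk_items(list(`4.1.1.1` = c(1)))
  expect_warning(sp2 <- foldSplit(f2$clustering, f2$labels), "single item")
  expect_equal(as.character(sp2), "train")
})

test_that("fold splits verify clean; corrupted splits are reported; 1-cluster ECs exempt", {
  f <- mk_items(list(A = c(5, 5, 5, 5), B = c(8, 2), C = c(10)))
  sp <- foldSplit(f$clustering, f$labels, seed = 5)
  expect_equal(nrow(verifySplit(sp, f$clustering, f$labels)), 0L)
  # corrupt: move one test item of a multi-cluster EC into train
  bad <- sp
  victim <- names(bad)[f$labels[names(bad)] == "A" & bad == "test"][1]
  bad[victim] <- "train"
  rep <- verifySplit(bad, f$clustering, f$labels)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$ec, "A")
  # single-cluster EC C spans partitions by design and is never reported
  expect_false("C" %in% rep$ec)
})

test_that("the Jaccard similarity over co-clustered pairs matches hand enumeration", {
  a <- c(x1 = "c1", x2 = "c1", x3 = "c1")
  expect_equal(clusteringJaccard(a, a), 1.0)
  singles <- c(x1 = "s1", x2 = "s2", x3 = "s3")
  mega <- c(x1 = "m", x2 = "m", x3 = "m")
  expect_equal(clusteringJaccard(singles, mega), 0.0)
  # {{1,2,3}} vs {{1,2},{3}}: pairs {12,13,23} vs {12} -> 1/3
  b <- c(x1 = "c1", x2 = "c1", x3 = "c2")
  expect_equal(clusteringJaccard(a, b), 1 / 3)
  expect_equal(clusteringJaccard(b, a), 1 / 3)
  expect_error(clusteringJaccard(a, c(y1 = "c")), "universe mismatch")
})

test_that("temporal splits order by date with id tie-breaks and honor ratios", {
  dates <- stats::setNames(as.Date("2010-01-01") + 1:10,
                           sprintf("s%02d", 1:10))
  sp <- temporalSplit(dates)
  expect_equal(sum(sp == "train"), 8L)
  expect_equal(unname(sp["s10"]), "test")       # newest in test
  expect_equal(unname(sp["s09"]), "val")
  expect_true(all(sp[sprintf("s%02d", 1:8)] == "train"))
  # all-equal dates: deterministic id order
  same <- stats::setNames(rep(as.Date("2010-01-01"), 10),
                          sprintf("s%02d", 1:10))
  sp2 <- temporalSplit(same)
  expect_identical(sp2, temporalSplit(same))
  expect_equal(unname(sp2["s10"]), "test")
  # undated items are excluded with a warning
  d3 <- dates; d3[2] <- NA
  expect_warning(sp3 <- temporalSplit(d3), "undated")
  expect_false("s02" %in% names(sp3))
})

test_that("split and cluster files round-trip losslessly", {
  f <- mk_items(list(A = c(3, 3), B = c(4)))
  sp <- foldSplit(f$clustering, f$labels, seed = 1)
  tfs <- tempfile(fileext = ".csv")
  writeSplitCSV(sp, tfs)
  back <- readSplitCSV(tfs)
  expect_identical(as.character(back[names(sp)]), as.character(sp))
  expect_equal(attr(back, "provenance"), "fold")
  tfc <- tempfile(fileext = ".tsv")
  writeClusterTSV(f$clustering, tfc)
  cb <- readClusterTSV(tfc)
  expect_identical(unname(cb[names(f$clustering)]), unname(f$clustering))
})

test_that("the greedy identity clusterer groups near-identical sequences only", {
  seqs <- c(a1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            a2 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVA",   # 1 mutation from a1
            b1 = "GGGGSSSSPPPPLLLLVVVVTTTTHHHHNNNN",
            c1 = "WWWWCCCCFFFFYYYYDDDDEEEERRRRKKKK")
  cl <- greedyIdentityCluster(seqs, minIdentity = 0.3)
  expect_equal(cl[["a1"]], cl[["a2"]])
  expect_length(unique(cl), 3L)
})
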