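# memoized study fixture: the planted-motif dataset under the default
# study conditions, fold-split, and classifiers trained from several
# seeds; shared across the experiment-level tests

.study_cache <- new.env(parent = emptyenv())

study_conditions <- function() {
  list(nPerClass = 40L, nResidues = 60L, dataSeed = 11L,
       descriptorCount = 30, neighborRadius = 10, maxNeighbors = 16L,
       embeddingDim = 64L, nInteractions = 3L, nGaussians = 32L,
       batchSize = 32L, maxEpochs = 200L)
}

study_dataset <- function() {
  if (!is.null(.study_cache$ds)) return(.study_cache$ds)
  sc <- study_conditions()
  ds <- makeDataset(sc$nPerClass, seed = sc$dataSeed,
                    nResidues = sc$nResidues)
  split <- foldSplit(ds$clustering, ds$labels, seed = 1L)
  ids <- vapply(ds$entries, `[[`, character(1), "id")
  scheme <- defaultAnnotationScheme()
  part <- function(p) ds$entries[split[ids] == p]
  graphs <- lapply(c(train = "train", val = "val", test = "test"),
                   function(p) datasetGraphs(part(p), scheme,
                     parameter = sc$descriptorCount,
                     neighborRadius = sc$neighborRadius,
                     maxNeighbors = sc$maxNeighbors))
  .study_cache$ds <- list(ds = ds, split = split, ids = ids,
                          scheme = scheme, graphs = graphs,
                          entries = list(train = part("train"),
                                         val = part("val"),
                                         test = part("test")))
  .study_cache$ds
}

# train one classifier per seed (memoized); returns list(model, history,
# trainAcc, testAcc)
study_model <- function(seed = 1L) {
  key <- paste0("m", seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  sc <- study_conditions()
  sd <- study_dataset()
  m <- graphClassifier("distances", sd$ds$vocab, sd$scheme,
                       embeddingDim = sc$embeddingDim,
                       nInteractions = sc$nInteractions,
                       nGaussians = sc$nGaussians,
                       cutoff = sd$graphs$train[[1]]@neighborRadius,
                       seed = seed)
  tr <- trainClassifier(m, sd$graphs$train, sd$graphs$val,
                        trainConfig(batchSize = sc$batchSize,
                                    maxEpochs = sc$maxEpochs, seed = seed))
  trEv <- evaluateClassifier(tr$model, sd$graphs$train)
  teEv <- evaluateClassifier(tr$model, sd$graphs$test)
  .study_cache[[key]] <- list(model = tr$model, history = tr$history,
                              trainAcc = trEv$accuracy,
                              testAcc = teEv$accuracy)
  .study_cache[[key]]
}
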