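# Loss, sampling, augmentation and the training loop.

#' Inverse-frequency class weights
#'
#' Rare classes get higher weight: \code{w_c} is proportional to
#' \code{1 / count_c}, normalized to mean 1 so the loss scale is
#' comparable to unweighted cross-entropy.
#'
#' @param labelCounts named numeric vector (or table) of per-class
#'   training counts, all >= 1.
#' @return named weight vector, mean 1, strictly decreasing in count.
#' @examples
#' classWeights(c(a = 1, b = 9))   # 1.8, 0.2
#' @export
classWeights <- function(labelCounts) {
  cnt <- as.numeric(labelCounts)
  if (any(is.na(cnt) | cnt < 1)) stop("unseen class: all counts must be >= 1")
  w <- 1 / cnt
  w <- w / mean(w)
  names(w) <- names(labelCounts)
  w
}

# softmax cross-entropy with per-class weights; returns loss and dlogits
.wce_grad <- function(logits, targets, weights, reduction = "mean") {
  G <- nrow(logits)
  mx <- apply(logits, 1L, max)
  z <- exp(logits - mx)
  p <- z / rowSums(z)
  wt <- weights[targets]
  ln <- -wt * (log(p[cbind(seq_len(G), targets)]))
  y <- matrix(0, G, ncol(logits))
  y[cbind(seq_len(G), targets)] <- 1
  dl <- wt * (p - y)
  if (reduction == "mean") {
    loss <- mean(ln); dl <- dl / G
  } else loss <- sum(ln)
  list(loss = loss, dlogits = dl, perSample = ln)
}

#' Weighted cross-entropy loss
#'
#' Per sample n with true class t:
#' \code{l_n = -w_t log( exp(x_{n,t}) / sum_i exp(x_{n,i}) )},
#' reduced over the minibatch by mean or sum. Linear in the weight
#' vector; uniform weights recover standard cross-entropy.
#'
#' @param logits N x C matrix.
#' @param targets integer class indices (length N) or N x C one-hot
#'   matrix.
#' @param weights per-class weights (length C), default uniform.
#' @param reduction \code{"mean"} or \code{"sum"}.
#' @return scalar loss.
#' @export
weightedCrossEntropy <- function(logits, targets,
                                 weights = rep(1, ncol(logits)),
                                 reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!all(is.finite(logits))) stop("numeric error: non-finite logits")
  if (is.matrix(targets)) targets <- apply(targets, 1L, which.max)
  if (any(weights <= 0)) stop("class weights must be > 0")
  .wce_grad(logits, as.integer(targets), weights, reduction)$loss
}

#' Class-balanced oversampling indices
#'
#' Draws training indices with replacement so that every class has equal
#' expected frequency, countering class imbalance; seeded-deterministic.
#'
#' @param labels vector of class labels.
#' @param size number of indices to draw (default one epoch's worth).
#' @param seed integer seed.
#' @return integer index vector.
#' @export
oversampleIndices <- function(labels, size = length(labels), seed = 1L) {
  if (!length(labels)) stop("need at least one label")
  cnt <- table(labels)
  prob <- 1 / as.numeric(cnt[as.character(labels)])
  with_seed(seed, sample.int(length(labels), size, replace = TRUE,
                             prob = prob))
}

#' Coordinate jitter augmentation for one graph
#'
#' Displaces every node independently by a random vector of norm at most
#' \code{amplitude} (default 0.05 Angstrom, the training-time
#' augmentation scale). Edges are kept; only positions move, so the
#' distance expansions seen by the network change slightly. Applied to
#' training graphs only.
#'
#' @param g a \linkS4class{ProteinGraph}.
#' @param amplitude maximum displacement (Angstrom, >= 0).
#' @param seed integer seed.
#' @return the jittered \linkS4class{ProteinGraph}.
#' @export
augmentTranslate <- function(g, amplitude = 0.05, seed = 1L) {
  if (amplitude < 0) stop("invalid amplitude")
  if (amplitude == 0) return(g)
  d <- with_seed(seed, random_displacements(nrow(g@positions), amplitude))
  methods::initialize(g, positions = g@positions + d,
                      neighborRadius = g@neighborRadius + 2 * amplitude)
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 0.001).
#' @param beta1,beta2 Adam moment decays (0.9, 0.999).
#' @param batchSize minibatch size (a power of two; the largest that
#'   fits is the usual choice).
#' @param maxEpochs epoch cap.
#' @param patience early stopping: stop when validation accuracy has not
#'   increased for this many epochs (default 10).
#' @param augmentAmplitude training-time coordinate jitter (0.05 A).
#' @param oversample class-balanced sampling with replacement per epoch.
#' @param seed master seed for sampling, jitter and dropout.
#' @return config list for \code{\link{trainClassifier}}.
#' @export
trainConfig <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                        batchSize = 32L, maxEpochs = 200L, patience = 10L,
                        augmentAmplitude = 0.05, oversample = FALSE,
                        seed = 1L) {
  stopifnot(lr > 0, patience >= 1L)
  list(lr = lr, beta1 = beta1, beta2 = beta2, batchSize = as.integer(batchSize),
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       augmentAmplitude = augmentAmplitude, oversample = oversample,
       seed = as.integer(seed))
}

.adam_step <- function(params, grads, state, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gmat
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

.graph_labels <- function(graphs) vapply(graphs, function(g) g@label, integer(1))

#' Train a classifier on labeled graphs
#'
#' Minimizes the weighted cross-entropy (inverse-frequency class
#' weights) with Adam, class-balanced oversampling if requested,
#' coordinate-jitter augmentation on training graphs, and early stopping
#' on validation accuracy. The checkpoint with the best validation
#' accuracy is returned. Fully seeded: the same seed, data and config
#' reproduce the same history.
#'
#' @param model an untrained \linkS4class{GraphClassifier}
#'   (\code{"distances"} architecture; the directional network has no
#'   analytic backward pass and is supported for inference and
#'   explanation).
#' @param trainGraphs,valGraphs lists of labeled
#'   \linkS4class{ProteinGraph}s with disjoint provenance.
#' @param tcfg a \code{\link{trainConfig}}.
#' @param weights optional per-class loss weights; default computed from
#'   the training label counts.
#' @param verbose print per-epoch progress.
#' @return list with \code{model} (best checkpoint), \code{history}
#'   (data.frame epoch/train_loss/train_acc/val_acc) and
#'   \code{bestEpoch}.
#' @export
trainClassifier <- function(model, trainGraphs, valGraphs,
                            tcfg = trainConfig(), weights = NULL,
                            verbose = FALSE) {
  if (!length(trainGraphs) || !length(valGraphs)) stop("empty dataset")
  if (model@architecture != "distances")
    stop("training is implemented for the 'distances' architecture")
  yl <- .graph_labels(trainGraphs)
  C <- model@config$nClasses
  if (anyNA(yl) || max(yl) > C)
    stop("vocabulary mismatch: graph labels outside the class vocabulary")
  if (is.null(weights)) {
    cnt <- tabulate(yl, C)
    if (any(cnt == 0)) {
      w <- rep(1, C)
      w[cnt > 0] <- classWeights(cnt[cnt > 0])
    } else w <- classWeights(cnt)
  } else w <- weights

  params <- model@params
  state <- list(t = 0L,
                m = lapply(params, function(x) array(0, dim(x) %||% length(x))),
                v = lapply(params, function(x) array(0, dim(x) %||% length(x))))
  for (nm in names(params)) {        # keep vectors as vectors
    if (is.null(dim(params[[nm]]))) {
      state$m[[nm]] <- numeric(length(params[[nm]]))
      state$v[[nm]] <- numeric(length(params[[nm]]))
    }
  }
  valBatch <- batchGraphs(valGraphs)
  yval <- .graph_labels(valGraphs)
  cfg <- model@config
  best <- list(acc = -Inf, params = params, epoch = 0L)
  hist <- list()
  noImprove <- 0L

  with_seed(tcfg$seed, {
    for (epoch in seq_len(tcfg$maxEpochs)) {
      idx <- if (tcfg$oversample) {
        cnt <- table(yl)
        sample.int(length(yl), length(yl), replace = TRUE,
                   prob = 1 / as.numeric(cnt[as.character(yl)]))
      } else sample.int(length(yl))
      eloss <- 0; ncorr <- 0L; nseen <- 0L
      starts <- seq(1L, length(idx), by = tcfg$batchSize)
      for (st in starts) {
        take <- idx[st:min(st + tcfg$batchSize - 1L, length(idx))]
        gb <- batchGraphs(trainGraphs[take])
        if (tcfg$augmentAmplitude > 0)
          gb@positions <- gb@positions +
            random_displacements(nrow(gb@positions), tcfg$augmentAmplitude)
        fw <- forward_distances(params, cfg, gb, training = TRUE,
                                keepCache = TRUE)
        lg <- .wce_grad(fw$logits, yl[take], w)
        bw <- backward_distances(params, cfg, gb, fw$cache, lg$dlogits)
        upd <- .adam_step(params, bw$grads, state, tcfg$lr, tcfg$beta1,
                          tcfg$beta2)
        params <- upd$params; state <- upd$state
        eloss <- eloss + lg$loss * length(take)
        ncorr <- ncorr + sum(apply(fw$logits, 1L, which.max) == yl[take])
        nseen <- nseen + length(take)
      }
      vlog <- forward_distances(params, cfg, valBatch)$logits
      vacc <- mean(apply(vlog, 1L, which.max) == yval)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = eloss / nseen,
                                  train_acc = ncorr / nseen, val_acc = vacc)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  train %.3f  val %.3f",
                        epoch, eloss / nseen, ncorr / nseen, vacc))
      if (vacc >= best$acc) {
        # checkpoint the latest among equally good validation epochs;
        # patience counts only epochs without a strict increase
        improved <- vacc > best$acc
        best <- list(acc = vacc, params = params, epoch = epoch)
        if (improved) noImprove <- 0L else noImprove <- noImprove + 1L
        if (noImprove >= tcfg$patience) break
      } else {
        noImprove <- noImprove + 1L
        if (noImprove >= tcfg$patience) break
      }
    }
  })
  out <- model
  out@params <- best$params
  list(model = out, history = do.call(rbind, hist), bestEpoch = best$epoch)
}

#' Evaluate a classifier on labeled graphs
#'
#' @param model a trained \linkS4class{GraphClassifier}.
#' @param graphs list of labeled \linkS4class{ProteinGraph}s.
#' @return list with \code{predictions} (truth, predicted label,
#'   confidence), \code{accuracy}, \code{f1} (protein-centric, plain and
#'   F-max), \code{aupr} (per class + macro), \code{perLevel} accuracy
#'   by EC truncation level when the vocabulary is dotted, and the raw
#'   \code{scores} matrix.
#' @export
evaluateClassifier <- function(model, graphs) {
  gb <- batchGraphs(graphs)
  y <- .graph_labels(graphs)
  logits <- forwardLogits(model, gb)
  pr <- predictEC(logits, model@classVocab)
  sm <- exp(logits - apply(logits, 1L, max)); sm <- sm / rowSums(sm)
  truthLab <- model@classVocab[y]
  acc <- mean(pr$label == truthLab)
  f1 <- proteinCentricF1(pr$label, pr$confidence, truthLab)
  aupr <- perClassAUPR(sm, y, classNames = model@classVocab)
  perLevel <- NULL
  if (all(grepl(".", model@classVocab, fixed = TRUE))) {
    perLevel <- vapply(c("main", "sub", "subsub", "designation"),
                       function(lv) mean(ecTruncate(pr$label, lv) ==
                                         ecTruncate(truthLab, lv)),
                       numeric(1))
  }
  list(predictions = data.frame(truth = truthLab, pred = pr$label,
                                confidence = pr$confidence,
                                correct = pr$label == truthLab,
                                stringsAsFactors = FALSE),
       accuracy = acc, f1 = f1, aupr = aupr, perLevel = perLevel,
       scores = sm)
}
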