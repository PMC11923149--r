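# Train/validation/test partitioning: fold split over sequence-identity
# clusters (no shared cluster between test and train/val within an EC),
# temporal split by deposition date, and clustering comparison.

#' Fold split: partition by sequence-identity clusters
#'
#' Clusters are handled per enzyme classification (a cluster containing
#' several ECs is separated by EC). For an EC with three or more
#' clusters, whole clusters are distributed over train/validation/test;
#' with two clusters, one goes to test (the smaller, to preserve
#' training mass) and the other is divided over train and validation;
#' with a single cluster, the items themselves are divided to keep the
#' target ratio. ECs with a single item go to train with a warning.
#'
#' @param clustering named character vector: item id -> cluster id.
#' @param labels named character vector: item id -> EC label.
#' @param ratios train/val/test proportions (default 0.8/0.1/0.1).
#' @param seed integer seed (shuffles within-cluster divisions and
#'   cluster-to-partition assignment ties).
#' @return named character vector item id -> \code{"train"|"val"|"test"}
#'   with attribute \code{provenance = "fold"}.
#' @export
foldSplit <- function(clustering, labels, ratios = c(0.8, 0.1, 0.1),
                      seed = 1L) {
  items <- names(labels)
  if (!all(items %in% names(clustering)))
    stop("every item needs a cluster assignment")
  ratios <- ratios / sum(ratios)
  out <- character(0)
  with_seed(seed, {
    for (ec in unique(labels)) {
      ids <- items[labels == ec]
      cl <- clustering[ids]
      clusters <- split(ids, cl)
      nc <- length(clusters)
      if (length(ids) == 1L) {
        warning(sprintf("EC %s has a single item; assigned to train", ec))
        out[ids] <- "train"
      } else if (nc == 1L) {
        div <- .divide_items(ids, ratios)
        out[names(div)] <- div
      } else if (nc == 2L) {
        sizes <- lengths(clusters)
        testCl <- which.min(sizes)        # smaller cluster -> test
        out[clusters[[testCl]]] <- "test"
        rest <- clusters[[3L - testCl]]
        div <- .divide_items(rest, c(ratios[1L], ratios[2L], 0) /
                               sum(ratios[1L:2L]))
        out[names(div)] <- div
      } else {
        # whole clusters, greedy largest-first to the partition with the
        # biggest remaining deficit; val and test get at least one
        sizes <- lengths(clusters)
        ord <- order(-sizes, stats::runif(nc))
        total <- sum(sizes)
        target <- ratios * total
        got <- c(train = 0, val = 0, test = 0)
        nAssigned <- c(train = 0L, val = 0L, test = 0L)
        assign_to <- character(nc)
        remaining <- nc
        for (ci in ord) {
          deficit <- (target - got) / pmax(target, 1e-9)
          # reserve clusters so val/test are never left empty
          mustHave <- sum(nAssigned[c("val", "test")] == 0L)
          if (remaining <= mustHave)
            pick <- names(which(nAssigned[c("val", "test")] == 0L))[1L]
          else pick <- names(which.max(deficit))
          assign_to[ci] <- pick
          got[pick] <- got[pick] + sizes[ci]
          nAssigned[pick] <- nAssigned[pick] + 1L
          remaining <- remaining - 1L
        }
        for (ci in seq_len(nc)) out[clusters[[ci]]] <- assign_to[ci]
      }
    }
  })
  out <- out[items]
  attr(out, "provenance") <- "fold"
  out
}

# divide item ids into train/val/test by ratio; returns partitions
# named by item id; rounding keeps every non-zero-ratio partition
# non-empty when possible
.divide_items <- function(ids, ratios) {
  n <- length(ids)
  ids <- sample(ids)
  nTest <- if (ratios[3L] > 0) max(round(ratios[3L] * n), 1L) else 0L
  nVal <- if (ratios[2L] > 0) max(round(ratios[2L] * n), 1L) else 0L
  while (nTest + nVal >= n) {        # keep at least one training item
    if (nVal > 0L) nVal <- nVal - 1L else nTest <- nTest - 1L
  }
  part <- rep("train", n)
  if (nVal > 0L) part[seq_len(nVal)] <- "val"
  if (nTest > 0L) part[nVal + seq_len(nTest)] <- "test"
  stats::setNames(part, ids)
}

#' Temporal split: partition by deposition date
#'
#' Oldest items go to train, the next tranche to validation, the newest
#' to test; date ties are broken by item id. Undated items are excluded
#' with a warning (computationally predicted structures without a
#' deposition date cannot be placed on the time axis).
#'
#' @param dates named \code{Date} vector: item id -> deposition date.
#' @param ratios train/val/test proportions.
#' @return named character vector with attribute
#'   \code{provenance = "temporal"}.
#' @export
temporalSplit <- function(dates, ratios = c(0.8, 0.1, 0.1)) {
  if (anyNA(dates)) {
    warning(sum(is.na(dates)), " undated item(s) excluded from temporal split")
    dates <- dates[!is.na(dates)]
  }
  ratios <- ratios / sum(ratios)
  ids <- names(dates)[order(dates, names(dates), method = "radix")]
  n <- length(ids)
  nTrain <- round(ratios[1L] * n)
  nVal <- round(ratios[2L] * n)
  part <- rep("test", n)
  part[seq_len(nTrain)] <- "train"
  if (nVal > 0L) part[nTrain + seq_len(min(nVal, n - nTrain))] <- "val"
  out <- stats::setNames(part, ids)
  attr(out, "provenance") <- "temporal"
  out
}

#' Jaccard similarity of two clusterings
#'
#' Defined over co-clustered item pairs: the number of unordered pairs
#' co-clustered in both clusterings divided by the number co-clustered
#' in at least one.
#'
#' @param a,b named vectors item id -> cluster id over the same items.
#' @return similarity in [0, 1] (1 when no pairs are co-clustered in
#'   either, i.e. identical all-singleton clusterings).
#' @export
clusteringJaccard <- function(a, b) {
  if (!setequal(names(a), names(b)))
    stop("universe mismatch: clusterings cover different items")
  b <- b[names(a)]
  pairs_in <- function(sizes) sum(sizes * (sizes - 1) / 2)
  both <- pairs_in(table(paste(a, b, sep = "\r")))
  na_ <- pairs_in(table(a))
  nb_ <- pairs_in(table(b))
  union <- na_ + nb_ - both
  if (union == 0) return(1)
  both / union
}

#' Verify a fold split against a clustering
#'
#' Reports clusters that leak across partitions: for any EC with at
#' least two clusters, a cluster with items in test and in train or
#' validation is a violation; for ECs with three or more clusters a
#' cluster split across any two partitions is a violation. Single-
#' cluster ECs are exempt (the ratio rule divides them by design).
#'
#' @param split named partition vector (from \code{\link{foldSplit}}).
#' @param clustering named cluster vector.
#' @param labels named EC labels.
#' @return data.frame of violations (ec, cluster, partitions); zero rows
#'   means the split is clean.
#' @export
verifySplit <- function(split, clustering, labels) {
  items <- names(labels)
  bad <- list()
  for (ec in unique(labels)) {
    ids <- items[labels == ec]
    clusters <- split(ids, clustering[ids])
    if (length(clusters) < 2L) next
    for (cn in names(clusters)) {
      parts <- unique(split[clusters[[cn]]])
      violation <- if (length(clusters) >= 3L) length(parts) > 1L
                   else ("test" %in% parts && length(parts) > 1L)
      if (violation)
        bad[[length(bad) + 1L]] <- data.frame(
          ec = ec, cluster = cn,
          partitions = paste(sort(parts), collapse = "+"),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(bad))
    return(data.frame(ec = character(0), cluster = character(0),
                      partitions = character(0)))
  do.call(rbind, bad)
}

#' Read / write split and cluster files
#'
#' Cluster files use the two-column TSV dialect of sequence-clustering
#' tools (representative_id, member_id, no header); split files are CSV
#' (item_id, partition).
#'
#' @param path file path.
#' @return \code{readClusterTSV}: named vector member -> representative
#'   (cluster id). \code{readSplitCSV}: named partition vector.
#' @export
readClusterTSV <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.character(tab[[1L]]), as.character(tab[[2L]]))
}

#' @rdname readClusterTSV
#' @param clustering named vector member -> cluster id.
#' @export
writeClusterTSV <- function(clustering, path) {
  utils::write.table(data.frame(rep = unname(clustering),
                                member = names(clustering)),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname readClusterTSV
#' @export
readSplitCSV <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- stats::setNames(tab$partition, tab$item_id)
  if (!is.null(tab$provenance)) attr(out, "provenance") <- tab$provenance[1L]
  out
}

#' @rdname readClusterTSV
#' @param split named partition vector.
#' @export
writeSplitCSV <- function(split, path) {
  utils::write.csv(data.frame(item_id = names(split),
                              partition = unname(split),
                              provenance = attr(split, "provenance") %||% NA),
                   path, row.names = FALSE)
  invisible(path)
}

#' Greedy sequence-identity clustering (test fixture helper)
#'
#' A small greedy clusterer over a k-mer Jaccard proxy for sequence
#' identity: sequences join the first existing cluster whose
#' representative shares at least \code{minIdentity} k-mer Jaccard
#' similarity, else found a new cluster. Provided so fixtures can be
#' clustered without an external tool; it is not a replacement for a
#' production sequence-clustering program.
#'
#' @param seqs named character vector of sequences.
#' @param minIdentity similarity threshold (default 0.3).
#' @param k k-mer length (default 3).
#' @return named vector sequence id -> cluster id (representative id).
#' @export
greedyIdentityCluster <- function(seqs, minIdentity = 0.3, k = 3L) {
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(s)
    unique(substring(s, seq_len(nchar(s) - k + 1L), k:nchar(s)))
  })
  reps <- character(0)
  out <- character(length(seqs))
  names(out) <- names(seqs)
  for (id in names(seqs)) {
    placed <- FALSE
    for (r in reps) {
      jac <- length(intersect(kmers[[id]], kmers[[r]])) /
             length(union(kmers[[id]], kmers[[r]]))
      if (jac >= minIdentity) {
        out[id] <- r; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      out[id] <- id
    }
  }
  out
}
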