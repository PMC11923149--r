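# internal helpers shared across modules

# shifted softplus: ssp(x) = ln(0.5 e^x + 0.5); numerically stable for
# large |x| (ssp(x) -> x - ln 2 for x >> 0, -> exp(x)/2 for x << 0)
ssp <- function(x) {
  out <- x
  pos <- x > 30
  neg <- x < -30
  mid <- !pos & !neg
  out[mid] <- log1p(exp(x[mid])) - log(2)
  out[pos] <- x[pos] - log(2)
  out[neg] <- exp(x[neg]) / 2
  out
}

# derivative of ssp is the logistic sigmoid
ssp_grad <- function(x) stats::plogis(x)

sigmoid <- function(x) stats::plogis(x)

# deterministic seeded RNG scope: runs expr with a local RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# random displacement vectors: uniform direction on the sphere, radius
# uniform in [0, amplitude]; n x 3 matrix
random_displacements <- function(n, amplitude) {
  if (amplitude == 0 || n == 0L) return(matrix(0, n, 3L))
  v <- matrix(stats::rnorm(3L * n), n, 3L)
  v <- v / pmax(sqrt(rowSums(v^2)), 1e-12)
  v * stats::runif(n, 0, amplitude)
}

# rowsum that keeps zero rows for absent groups; group in 1..ngroups
scatter_sum <- function(values, group, ngroups) {
  out <- matrix(0, ngroups, ncol(values))
  if (nrow(values)) {
    rs <- rowsum(values, group = group)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

# pairwise Euclidean distances for the (j, i) pairs of an edge matrix
edge_lengths <- function(positions, edges) {
  if (nrow(edges) == 0L) return(numeric(0))
  sqrt(rowSums((positions[edges[, 1L], , drop = FALSE] -
                positions[edges[, 2L], , drop = FALSE])^2))
}

# random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
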