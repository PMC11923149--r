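# Basis expansions encoding geometry for the message-passing networks:
# Gaussian radial basis functions (continuous-filter network) and
# Fourier-Bessel radial / spherical bases (directional network).

#' Gaussian radial basis configuration
#'
#' Component k of the expansion of a distance d is
#' \code{exp(-gamma * (d - mu_k)^2)}. Two layouts are supported: the
#' default \code{count} evenly spaced centers on \code{[0, cutoff]} (50
#' Gaussians), or the dense published grid 0..30 Angstrom every 0.1
#' (\code{grid = TRUE}, 301 centers). gamma defaults to 10 per
#' Angstrom^2; the quadratic exponent makes per-Angstrom units
#' dimensionally inconsistent, so the value is interpreted on the
#' inverse-square scale.
#'
#' @param count number of centers (ignored if \code{grid}).
#' @param cutoff upper end of the center range (Angstrom).
#' @param gamma width parameter (1/Angstrom^2).
#' @param grid use the dense 0..30 every 0.1 grid.
#' @return list with \code{centers}, \code{gamma}, \code{count}.
#' @export
rbfConfig <- function(count = 50L, cutoff = 15, gamma = 10, grid = FALSE) {
  centers <- if (grid) seq(0, 30, by = 0.1) else seq(0, cutoff, length.out = count)
  if (gamma <= 0) stop("gamma must be > 0")
  list(centers = centers, gamma = gamma, count = length(centers))
}

#' Expand distances in a Gaussian radial basis
#'
#' @param d numeric vector of distances (Angstrom, >= 0).
#' @param cfg an \code{\link{rbfConfig}}.
#' @return length(d) x count matrix; entry (n, k) is
#'   \code{exp(-gamma (d_n - mu_k)^2)}.
#' @examples
#' cfg <- rbfConfig(count = 5, cutoff = 4)
#' rbfExpand(cfg$centers[3], cfg)[, 3] == 1
#' @export
rbfExpand <- function(d, cfg) {
  if (any(d < 0)) stop("distances must be >= 0")
  out <- exp(-cfg$gamma * (outer(d, cfg$centers, "-"))^2)
  out
}

## ---- Fourier-Bessel bases for the directional network ----

# spherical Bessel function j_l(x), l = 0..7, explicit stable forms
spherical_bessel_j <- function(l, x) {
  small <- abs(x) < 1e-8
  x[small] <- 1e-8                     # j_l(0) limits: 1 for l=0, 0 else
  out <- switch(as.character(l),
    "0" = sin(x) / x,
    "1" = sin(x) / x^2 - cos(x) / x,
    {
      # upward recurrence j_{l+1} = (2l+1)/x j_l - j_{l-1}; stable for
      # x above the first root region used here
      jm <- sin(x) / x
      j <- sin(x) / x^2 - cos(x) / x
      for (ll in 1L:(l - 1L)) {
        jn <- (2 * ll + 1) / x * j - jm
        jm <- j; j <- jn
      }
      j
    })
  if (l == 0L) out[small] <- 1 else out[small] <- 0
  out
}

# first n positive roots of j_l, by interlacing with the roots of j_{l-1}
bessel_j_roots <- function(l, n) {
  if (l == 0L) return(pi * seq_len(n))
  prev <- bessel_j_roots(l - 1L, n + 1L)
  vapply(seq_len(n), function(k) {
    stats::uniroot(function(x) spherical_bessel_j(l, x),
                   lower = prev[k] + 1e-9, upper = prev[k + 1L] - 1e-9,
                   tol = 1e-12)$root
  }, numeric(1))
}

# Legendre polynomial P_l(x) by recurrence (for Y_l0)
legendre_p <- function(l, x) {
  if (l == 0L) return(rep(1, length(x)))
  if (l == 1L) return(x)
  pm <- rep(1, length(x)); p <- x
  for (ll in 1L:(l - 1L)) {
    pn <- ((2 * ll + 1) * x * p - ll * pm) / (ll + 1)
    pm <- p; p <- pn
  }
  p
}

# smooth polynomial envelope u(d) with u(cutoff) = 0 (exponent p = 6)
envelope <- function(d, cutoff, p = 6) {
  x <- pmin(d / cutoff, 1)
  1 - (p + 1) * (p + 2) / 2 * x^p + p * (p + 2) * x^(p + 1) -
    p * (p + 1) / 2 * x^(p + 2)
}

#' Spherical / radial Fourier-Bessel configuration
#'
#' @param numSpherical number of spherical harmonics degrees (default 7).
#' @param numRadial number of radial basis functions (default 6).
#' @param cutoff interaction cutoff in Angstrom.
#' @return list with precomputed spherical Bessel roots.
#' @export
sbfConfig <- function(numSpherical = 7L, numRadial = 6L, cutoff = 15) {
  if (numSpherical < 1L || numRadial < 1L) stop("basis sizes must be >= 1")
  roots <- lapply(0:(numSpherical - 1L), bessel_j_roots, n = numRadial)
  list(numSpherical = numSpherical, numRadial = numRadial, cutoff = cutoff,
       roots = roots)
}

#' Radial Fourier-Bessel expansion of distances
#'
#' \code{sqrt(2/c) sin(n pi d / c) / d}, n = 1..numRadial, smoothed by a
#' polynomial envelope that vanishes at the cutoff.
#'
#' @param d distances (Angstrom).
#' @param cfg an \code{\link{sbfConfig}}.
#' @return length(d) x numRadial matrix.
#' @export
besselRadialBasis <- function(d, cfg) {
  c0 <- cfg$cutoff
  dsafe <- pmax(d, 1e-8)
  n <- seq_len(cfg$numRadial)
  env <- envelope(d, c0)
  out <- sqrt(2 / c0) * sin(outer(dsafe, n * pi / c0)) / dsafe
  out * env
}

#' Spherical Fourier-Bessel expansion of (distance, angle) pairs
#'
#' Basis element (l, n) is \code{j_l(z_ln d / c) * P_l(cos angle)} with
#' z_ln the n-th positive root of j_l, enveloped in d. Encodes the joint
#' geometry of a directional message (k -> j -> i): d is the k-j
#' distance, angle the angle at j.
#'
#' @param d distances (Angstrom).
#' @param angle angles in radians, \code{[0, pi]}.
#' @param cfg an \code{\link{sbfConfig}}.
#' @return length(d) x (numSpherical * numRadial) matrix, (l, n) pairs in
#'   column-major order l fastest.
#' @export
sphericalFourierBessel <- function(d, angle, cfg) {
  stopifnot(length(d) == length(angle))
  c0 <- cfg$cutoff
  env <- envelope(d, c0)
  cols <- vector("list", cfg$numSpherical * cfg$numRadial)
  idx <- 1L
  for (n in seq_len(cfg$numRadial)) {
    for (l in 0:(cfg$numSpherical - 1L)) {
      z <- cfg$roots[[l + 1L]][n]
      cols[[idx]] <- spherical_bessel_j(l, z * d / c0) *
        legendre_p(l, cos(angle)) * env
      idx <- idx + 1L
    }
  }
  do.call(cbind, cols)
}
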