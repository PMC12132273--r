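#' Latent-family configuration
#'
#' Bundles the choices that define the variational family of an iterative
#' VAE: the latent dimensionality K, the posterior/prior distribution family,
#' the KL weight beta controlling the rate-distortion trade-off, and the
#' clamp applied to membrane potentials before exponentiation.
#'
#' @param K Positive integer, number of latent units (neurons).
#' @param family One of `"poisson"` (spike counts, rates `exp(u)`),
#'   `"gaussian"` (real latents, mean `u`, unit variance), or
#'   `"gaussian_relu"` (Gaussian draws rectified after sampling).
#' @param beta Non-negative KL weight.
#' @param u_clamp Length-2 numeric `(lo, hi)` bounding membrane potentials.
#'   The default `c(-8, 8)` keeps rates below ~3000 spikes per step, far
#'   beyond physiological range, while preventing float overflow.
#' @return An object of class `latent_config`.
#' @export
latent_config <- function(K, family = c("poisson", "gaussian", "gaussian_relu"),
                          beta = 1, u_clamp = c(-8, 8)) {
  family <- match.arg(family)
  if (length(K) != 1L || !is.finite(K) || K < 1 || K != round(K))
    stop("K must be a positive integer", call. = FALSE)
  if (length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("beta must be a non-negative real", call. = FALSE)
  if (length(u_clamp) != 2L || any(!is.finite(u_clamp)) || u_clamp[1] >= u_clamp[2])
    stop("u_clamp must be (lo, hi) with lo < hi", call. = FALSE)
  structure(list(K = as.integer(K), family = family, beta = beta,
                 u_clamp = as.numeric(u_clamp)),
            class = "latent_config")
}

#' @export
print.latent_config <- function(x, ...) {
  cat(sprintf("<latent_config> K=%d family=%s beta=%g u_clamp=[%g, %g]\n",
              x$K, x$family, x$beta, x$u_clamp[1], x$u_clamp[2]))
  invisible(x)
}

clamp_u <- function(u, u_clamp) pmin(pmax(u, u_clamp[1]), u_clamp[2])

check_finite <- function(x, name) {
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(x)
}

#' Firing rates from membrane potentials
#'
#' The canonical Poisson parameterization `r = exp(u)` after clamping `u`
#' to the configured range. Works elementwise on vectors or matrices
#' (columns = batch elements).
#'
#' @param u Numeric vector or matrix of membrane potentials.
#' @param cfg A [latent_config()].
#' @return Strictly positive rates, same shape as `u`.
#' @export
rates_from_potentials <- function(u, cfg) {
  check_finite(u, "u")
  exp(clamp_u(u, cfg$u_clamp))
}

#' Sample latent variables from the approximate posterior
#'
#' For the Poisson family, draws independent Poisson counts with mean
#' `exp(clamp(u))`. For the Gaussian family, draws `N(u, 1)`; for
#' `gaussian_relu`, the Gaussian draw is rectified at zero after sampling.
#'
#' @param u Membrane potentials (vector or matrix; columns are batch
#'   elements). The Poisson mean is `exp(u)` after clamping; the Gaussian
#'   mean is `u` itself.
#' @param cfg A [latent_config()].
#' @param eps Optional test hook: pre-drawn standard-normal noise of the
#'   same shape as `u` for the Gaussian families (`eps = 0` gives the
#'   zero-noise pass-through `z = u`). Ignored for the Poisson family.
#' @return Latent sample `z`, same shape as `u`. Integer-valued (stored as
#'   numeric) for the Poisson family.
#' @export
sample_posterior <- function(u, cfg, eps = NULL) {
  check_finite(u, "u")
  n <- length(u)
  z <- switch(cfg$family,
    poisson = {
      r <- exp(clamp_u(u, cfg$u_clamp))
      zz <- stats::rpois(n, r)
      storage.mode(zz) <- "double"
      zz
    },
    gaussian = ,
    gaussian_relu = {
      if (is.null(eps)) eps <- stats::rnorm(n)
      zz <- u + eps
      if (cfg$family == "gaussian_relu") zz <- pmax(zz, 0)
      zz
    },
    stop("unknown latent family: ", cfg$family, call. = FALSE)
  )
  if (is.matrix(u)) dim(z) <- dim(u)
  z
}

#' KL divergence between Poisson posteriors parameterized by log rates
#'
#' Computes `sum_i [ e^{u_i} (u_i - u0_i) - e^{u_i} + e^{u0_i} ]`, the KL
#' divergence from `Poisson(e^u)` to `Poisson(e^{u0})`. Non-negative, and
#' zero iff `u == u0`.
#'
#' @param u,u0 Posterior and prior log rates; vectors of equal length or
#'   matrices of equal shape (columns = batch elements).
#' @return A scalar for vector input; a per-column vector for matrix input.
#' @export
poisson_kl <- function(u, u0) {
  if (length(u) != length(u0))
    stop("u and u0 must have the same length", call. = FALSE)
  kl <- exp(u) * (u - u0) - exp(u) + exp(u0)
  if (is.matrix(u)) colSums(kl) else sum(kl)
}

gaussian_kl <- function(u, u0) {
  if (length(u) != length(u0))
    stop("u and u0 must have the same length", call. = FALSE)
  kl <- 0.5 * (u - u0)^2
  if (is.matrix(u)) colSums(kl) else sum(kl)
}

kl_term <- function(u, u0, cfg) {
  if (cfg$family == "poisson") poisson_kl(u, u0) else gaussian_kl(u, u0)
}

#' Single-sample reconstruction term
#'
#' The Gaussian negative log likelihood up to constants:
#' `0.5 * ||x - Phi z||^2` for one latent sample.
#'
#' @param x Pixel vector of length M, or M x B matrix.
#' @param phi Dictionary, M x K matrix.
#' @param z Latent sample of length K, or K x B matrix.
#' @return A scalar (vector input) or per-column vector (matrix input).
#' @export
reconstruction_term <- function(x, phi, z) {
  phi <- as.matrix(phi)
  if (NROW(x) != nrow(phi) && !(is.null(dim(x)) && length(x) == nrow(phi)))
    stop("dim(x) does not match nrow(phi)", call. = FALSE)
  if (NROW(z) != ncol(phi) && !(is.null(dim(z)) && length(z) == ncol(phi)))
    stop("dim(z) does not match ncol(phi)", call. = FALSE)
  resid <- x - phi %*% (if (is.matrix(z)) z else cbind(z))
  out <- 0.5 * colSums(resid^2)
  if (is.matrix(x) || is.matrix(z)) out else sum(out)
}

#' Variational free energy at a state (single Monte Carlo sample)
#'
#' Draws one latent sample `z` from the posterior at `u` and returns the
#' free-energy breakdown `total = recon + beta * kl`, with the drawn `z`
#' attached for trace recording.
#'
#' @param x Pixel vector (length M).
#' @param phi Dictionary (M x K).
#' @param u,u0 Posterior and prior membrane potentials (length K).
#' @param cfg A [latent_config()].
#' @param eps Optional Gaussian-noise hook forwarded to [sample_posterior()].
#' @return A list of class `free_energy_breakdown` with elements
#'   `recon`, `kl`, `beta`, `total`, and `z`.
#' @export
free_energy <- function(x, phi, u, u0, cfg, eps = NULL) {
  z <- sample_posterior(u, cfg, eps = eps)
  recon <- reconstruction_term(x, phi, z)
  kl <- kl_term(clamp_u(u, cfg$u_clamp), clamp_u(u0, cfg$u_clamp), cfg)
  structure(list(recon = recon, kl = kl, beta = cfg$beta,
                 total = recon + cfg$beta * kl, z = z),
            class = "free_energy_breakdown")
}

#' Fisher information preconditioner
#'
#' For a Poisson distribution in canonical (log-rate) form the Fisher
#' information is the rate itself, so the preconditioner is the diagonal
#' `G(u) = exp(u)`. For the Gaussian families (unit variance, mean `u`) the
#' Fisher matrix is the identity.
#'
#' @param u Membrane potentials.
#' @param cfg A [latent_config()].
#' @return The diagonal of `G(u)` as a vector (or matrix matching `u`).
#' @export
fisher_preconditioner <- function(u, cfg) {
  check_finite(u, "u")
  if (cfg$family == "poisson") exp(clamp_u(u, cfg$u_clamp))
  else u * 0 + 1
}

#' Straight-through gradient of the free energy in membrane potentials
#'
#' Returns the straight-through approximation of the gradient of the
#' single-sample free energy with respect to `u`:
#' `e^u * ( -Phi^T (x - Phi z) + beta (u - u0) )` for the Poisson family
#' (the pathwise Jacobian of the sampling step is taken as the identity in
#' rate space), and the same bracket without the `e^u` factor for the
#' Gaussian families, whose Fisher matrix is the identity.
#'
#' @param x Pixel vector (length M).
#' @param phi Dictionary (M x K).
#' @param u,u0 Posterior and prior membrane potentials (length K).
#' @param z The latent sample drawn at the current state.
#' @param cfg A [latent_config()].
#' @return Numeric vector of length K.
#' @export
free_energy_gradient <- function(x, phi, u, u0, z, cfg) {
  phi <- as.matrix(phi)
  if (length(x) != nrow(phi) || length(z) != ncol(phi) ||
      length(u) != ncol(phi) || length(u0) != ncol(phi))
    stop("dimension mismatch between x, phi, u, u0, z", call. = FALSE)
  uc <- clamp_u(u, cfg$u_clamp)
  u0c <- clamp_u(u0, cfg$u_clamp)
  bracket <- -drop(crossprod(phi, x - phi %*% cbind(z))) + cfg$beta * (uc - u0c)
  if (cfg$family == "poisson") exp(uc) * bracket else bracket
}
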