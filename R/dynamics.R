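#' Inference-dynamics configuration
#'
#' @param mode `"online"` (rolling prior: each step's posterior becomes the
#'   next step's prior, no leak term) or `"static_prior"` (fixed prior with
#'   a beta-weighted leak toward it).
#' @param eta Positive step size. The multiplicative rate-space form is only
#'   defined for `eta = 1`, the unit-step update.
#' @param T Positive integer number of inference iterations.
#' @param record_every Positive integer; record the trace every this many
#'   steps (`record_every = T` keeps essentially the final state only).
#' @return An object of class `dynamics_config`.
#' @export
dynamics_config <- function(mode = c("online", "static_prior"), eta = 1,
                            T = 100L, record_every = 1L) {
  mode <- match.arg(mode)
  if (!is.finite(eta) || eta <= 0) stop("eta must be > 0", call. = FALSE)
  if (!is.finite(T) || T < 1) stop("T must be >= 1", call. = FALSE)
  if (!is.finite(record_every) || record_every < 1)
    stop("record_every must be >= 1", call. = FALSE)
  structure(list(mode = mode, eta = eta, T = as.integer(T),
                 record_every = as.integer(record_every)),
            class = "dynamics_config")
}

#' Initial inference state
#'
#' @param u_init Initial membrane potentials (length K); both posterior and
#'   prior potentials start here.
#' @return A list of class `inference_state` with fields `t`, `u`, `u0`, `z`.
#' @export
inference_state <- function(u_init) {
  structure(list(t = 0L, u = u_init, u0 = u_init, z = NULL),
            class = "inference_state")
}

#' Lateral (recurrent) weights
#'
#' The Gram matrix `W = Phi^T Phi` mediating explaining-away: diagonal
#' entries are squared column norms (self-suppression), off-diagonal entries
#' couple neurons with overlapping tuning.
#'
#' @param phi Dictionary (M x K).
#' @return Symmetric K x K matrix.
#' @export
lateral_weights <- function(phi) {
  check_finite(phi, "phi")
  W <- crossprod(as.matrix(phi))
  (W + t(W)) / 2
}

step_dims_check <- function(state, x, phi, cfg) {
  phi <- as.matrix(phi)
  if (length(x) != nrow(phi))
    stop("length(x) does not match nrow(phi)", call. = FALSE)
  if (length(state$u) != ncol(phi) || ncol(phi) != cfg$K)
    stop("state/phi/config latent dimensions disagree", call. = FALSE)
  invisible(NULL)
}

#' One static-prior natural-gradient step
#'
#' Draws a latent sample at the current potentials and applies the
#' continuous-dynamics Euler step
#' `u <- clamp(u + eta * (Phi^T x - Phi^T Phi z - beta (u - u0)))` with the
#' prior `u0` held fixed.
#'
#' @param state An [inference_state()].
#' @param x Input pixel vector.
#' @param phi Dictionary.
#' @param cfg A [latent_config()].
#' @param dyncfg A [dynamics_config()].
#' @param z Optional pinned latent sample (test hook); drawn from the
#'   posterior when `NULL`.
#' @return The updated `inference_state` (prior unchanged).
#' @export
static_prior_step <- function(state, x, phi, cfg, dyncfg, z = NULL) {
  step_dims_check(state, x, phi, cfg)
  if (is.null(z)) z <- sample_posterior(state$u, cfg)
  uc <- clamp_u(state$u, cfg$u_clamp)
  u0c <- clamp_u(state$u0, cfg$u_clamp)
  drive <- drop(crossprod(phi, x)) - drop(lateral_weights(phi) %*% z) -
    cfg$beta * (uc - u0c)
  u_new <- clamp_u(state$u + dyncfg$eta * drive, cfg$u_clamp)
  structure(list(t = state$t + 1L, u = u_new, u0 = state$u0, z = z),
            class = "inference_state")
}

#' One online (rolling-prior) step
#'
#' The discrete-time update `u <- clamp(u + eta * (Phi^T x - Phi^T Phi z))`.
#' The new state's prior is set to the old posterior (the current posterior
#' becomes the next prior); the KL leak term vanishes in this single-update
#' limit because the prior tracks the posterior.
#'
#' @inheritParams static_prior_step
#' @return The updated `inference_state` with rolling prior.
#' @export
online_step <- function(state, x, phi, cfg, dyncfg, z = NULL) {
  step_dims_check(state, x, phi, cfg)
  if (is.null(z)) z <- sample_posterior(state$u, cfg)
  drive <- drop(crossprod(phi, x)) - drop(lateral_weights(phi) %*% z)
  u_new <- clamp_u(state$u + dyncfg$eta * drive, cfg$u_clamp)
  structure(list(t = state$t + 1L, u = u_new, u0 = state$u, z = z),
            class = "inference_state")
}

#' Multiplicative rate-space form of the online update
#'
#' For the unit step (`eta = 1`) the online potential update is equivalent
#' to the divisive-normalization form
#' `r' = r * exp(Phi^T x) / (exp(W_ii z_i) * prod_{j != i} exp(W_ij z_j))`:
#' co-active neurons suppress each other proportionally to their spike
#' output. No clamping is applied here; the identity with [online_step()]
#' holds wherever the clamp does not bind.
#'
#' @param r_t Current firing rates (strictly positive, length K).
#' @param x Input pixel vector.
#' @param phi Dictionary.
#' @param z_t Latent sample used for the update.
#' @param dyncfg A [dynamics_config()]; must have `eta = 1`.
#' @return Updated firing rates.
#' @export
rate_space_step <- function(r_t, x, phi, z_t, dyncfg) {
  if (dyncfg$eta != 1)
    stop("rate_space_step is defined for the unit step eta = 1 only",
         call. = FALSE)
  if (any(r_t <= 0)) stop("rates must be strictly positive", call. = FALSE)
  ff <- drop(crossprod(as.matrix(phi), x))
  lat <- drop(lateral_weights(phi) %*% z_t)
  r_t * exp(ff) / exp(lat)
}

#' Run iterative inference and record a trace
#'
#' Iterates the configured update for `dyncfg$T` steps starting from
#' `u = u0 = u_init`, recording potentials, samples, rates, the free-energy
#' breakdown, and the update norm every `record_every` steps. Deterministic
#' given `seed`.
#'
#' @param x Input pixel vector (length M).
#' @param phi Dictionary (M x K).
#' @param cfg A [latent_config()].
#' @param dyncfg A [dynamics_config()].
#' @param u_init Initial membrane potentials; defaults to `log(0.5)` per
#'   unit (about half a spike per step).
#' @param seed Optional integer seed for the spike draws.
#' @return An object of class `inference_trace`: a list with per-recorded-step
#'   matrices `u`, `z`, `r` (K x n_rec), vectors `step`, `recon`, `kl`,
#'   `total`, `update_norm`, and a `meta` list.
#' @export
run_inference <- function(x, phi, cfg, dyncfg, u_init = NULL, seed = NULL) {
  phi <- as.matrix(phi)
  if (is.null(u_init)) u_init <- rep(log(0.5), cfg$K)
  if (!is.null(seed)) set.seed(seed)
  state <- inference_state(u_init)
  step_dims_check(state, x, phi, cfg)
  W <- lateral_weights(phi)
  ff <- drop(crossprod(phi, x))
  step_fun <- if (dyncfg$mode == "online") online_step else static_prior_step

  rec_idx <- seq(dyncfg$record_every, dyncfg$T, by = dyncfg$record_every)
  n_rec <- length(rec_idx)
  U <- matrix(NA_real_, cfg$K, n_rec)
  Z <- matrix(NA_real_, cfg$K, n_rec)
  R <- matrix(NA_real_, cfg$K, n_rec)
  recon <- kl <- total <- upd <- numeric(n_rec)

  j <- 1L
  for (t in seq_len(dyncfg$T)) {
    u_before <- state$u
    u0_before <- state$u0
    state <- step_fun(state, x, phi, cfg, dyncfg)
    if (any(!is.finite(state$u)))
      stop(sprintf("non-finite membrane potentials at step %d", t),
           call. = FALSE)
    if (j <= n_rec && t == rec_idx[j]) {
      z <- state$z
      rr <- rates_from_potentials(u_before, cfg)
      rec <- reconstruction_term(x, phi, z)
      kl_t <- kl_term(clamp_u(u_before, cfg$u_clamp),
                      clamp_u(u0_before, cfg$u_clamp), cfg)
      U[, j] <- u_before; Z[, j] <- z; R[, j] <- rr
      recon[j] <- rec; kl[j] <- kl_t
      total[j] <- rec + cfg$beta * kl_t
      upd[j] <- sqrt(sum((state$u - u_before)^2)) / dyncfg$eta
      j <- j + 1L
    }
  }
  structure(list(step = rec_idx, u = U, z = Z, r = R,
                 recon = recon, kl = kl, total = total, update_norm = upd,
                 u_final = state$u,
                 meta = list(mode = dyncfg$mode, eta = dyncfg$eta,
                             T = dyncfg$T, record_every = dyncfg$record_every,
                             seed = seed, family = cfg$family,
                             beta = cfg$beta)),
            class = "inference_trace")
}

#' @export
print.inference_trace <- function(x, ...) {
  cat(sprintf("<inference_trace> %d recorded steps (T=%d, mode=%s, family=%s)\n",
              length(x$step), x$meta$T, x$meta$mode, x$meta$family))
  cat(sprintf("  final free energy %.4f (recon %.4f, kl %.4f)\n",
              utils::tail(x$total, 1), utils::tail(x$recon, 1),
              utils::tail(x$kl, 1)))
  invisible(x)
}

#' @export
as.data.frame.inference_trace <- function(x, ...) {
  data.frame(step = x$step, recon = x$recon, kl = x$kl, total = x$total,
             update_norm = x$update_norm)
}

#' Serialize an inference trace to plain-text files
#'
#' Writes one CSV per recorded array (`u`, `z`, `r`, and the per-step
#' scalars) plus a JSON metadata sidecar into `dir`.
#'
#' @param trace An `inference_trace`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trace <- function(trace, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(trace),
                   file.path(dir, "scalars.csv"), row.names = FALSE)
  for (nm in c("u", "z", "r"))
    utils::write.csv(trace[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(trace$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
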