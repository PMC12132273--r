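#' Coefficient of determination between input and reconstruction
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the mean of `x`;
#' bounded above by 1, equal to 1 iff the residuals vanish, and 0 for the
#' mean-only null reconstruction.
#'
#' @param x Input pixel vector.
#' @param x_hat Reconstruction of the same length.
#' @return A real number <= 1.
#' @export
r2_reconstruction <- function(x, x_hat) {
  if (length(x) != length(x_hat))
    stop("x and x_hat must have the same length", call. = FALSE)
  ss_tot <- sum((x - mean(x))^2)
  if (ss_tot == 0)
    stop("R^2 undefined for constant x (zero total sum of squares)",
         call. = FALSE)
  1 - sum((x - x_hat)^2) / ss_tot
}

#' Fraction of exactly-zero latents
#'
#' The proportion-of-zeros sparsity measure: a proxy for energy efficiency
#' of spike-count codes. Continuous (Gaussian-family) latents have no atom
#' at zero, so their sparsity is 0 almost surely.
#'
#' @param z Latent vector or matrix.
#' @return Fraction in `[0, 1]`.
#' @export
sparsity_fraction <- function(z) {
  check_finite(z, "z")
  mean(z == 0)
}

#' Per-step update norms from an inference trace
#'
#' The Euclidean norm of each applied update `||u_{t+1} - u_t|| / eta`, the
#' discrete proxy for the natural-gradient speed `||G^{-1} grad_u F||` and
#' hence for proximity to the attractor.
#'
#' @param trace An `inference_trace` with consecutively recorded potentials
#'   (`record_every = 1`).
#' @return Numeric vector, one entry per recorded step.
#' @export
update_norm <- function(trace) {
  trace$update_norm
}

moving_average <- function(x, width) {
  if (width <= 1) return(x)
  stats::filter(x, rep(1 / width, width), sides = 2) |>
    as.numeric() |>
    (\(s) ifelse(is.na(s), x, s))()
}

#' Convergence time of a metric trace
#'
#' Smallest step offset `t` (0-based: a constant trace converges at 0) such
#' that every window of `window` consecutive points of the smoothed trace
#' starting at or after `t` has range (max - min) below `tol`.
#'
#' @param r2_trace Numeric metric trace (typically per-step R^2).
#' @param window Window length for the stability check (default 50).
#' @param tol Range tolerance (default 1e-3).
#' @param smooth_width Width of the centered moving average applied before
#'   the check (default 5; 1 disables smoothing).
#' @return Integer 0-based step offset, or `NA_integer_` when the trace
#'   never stabilizes.
#' @export
convergence_time <- function(r2_trace, window = 50L, tol = 1e-3,
                             smooth_width = 5L) {
  L <- length(r2_trace)
  if (L < 2L * window)
    stop("trace shorter than 2*window", call. = FALSE)
  s <- moving_average(r2_trace, smooth_width)
  n_win <- L - window + 1L
  rng <- vapply(seq_len(n_win),
                function(i) {
                  w <- s[i:(i + window - 1L)]
                  max(w) - min(w)
                }, numeric(1))
  ok_from_here <- rev(cummax(rev(rng))) < tol   # all later windows stable too
  idx <- which(ok_from_here)
  if (!length(idx)) return(NA_integer_)
  as.integer(idx[1] - 1L)
}

#' Reconstruction-sparsity landscape
#'
#' Places models in the (R^2, sparsity) plane and computes each model's
#' Euclidean distance to the unachievable optimum (R^2 = 1, sparsity = 1):
#' `distance = sqrt((1 - R2)^2 + (1 - sparsity)^2)`, smaller is better.
#' Negative R^2 values are clipped to 0 with a warning.
#'
#' @param points Data frame with columns `r2` and `sparsity` (any other
#'   columns, e.g. model id, `T_train`, `beta`, are carried through).
#' @return The data frame with a `distance_to_optimum` column, sorted by
#'   distance.
#' @export
landscape <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("r2", "sparsity") %in% names(points)))
    stop("points must have columns 'r2' and 'sparsity'", call. = FALSE)
  if (any(points$r2 < 0)) {
    warning("negative R^2 values clipped to 0")
    points$r2 <- pmax(points$r2, 0)
  }
  if (any(points$sparsity < 0 | points$sparsity > 1))
    stop("sparsity must be in [0, 1]", call. = FALSE)
  points$distance_to_optimum <-
    sqrt((1 - points$r2)^2 + (1 - points$sparsity)^2)
  points[order(points$distance_to_optimum), , drop = FALSE]
}

# Jonker-Volgenant shortest-augmenting-path solution of the rectangular
# assignment problem: minimizes sum_i cost[i, match(i)] over one-to-one
# matchings of the n rows into the m >= n columns. Returns the column
# matched to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("assignment needs nrow <= ncol", call. = FALSE)
  # 1-based port with a virtual column at index 1; columns j in 2..m+1.
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L); way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in which(!used[-1L]) + 1L) {
        cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) { u[p[j] + 1L] <- u[p[j] + 1L] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1L) break
    }
  }
  match_of_row <- integer(n)
  for (j in 2L:(m + 1L)) if (p[j] > 0L) match_of_row[p[j]] <- j - 1L
  match_of_row
}

#' Dictionary recovery score
#'
#' Mean absolute cosine similarity between ground-truth dictionary columns
#' and their optimally assigned (Hungarian matching) estimated columns;
#' invariant to column permutation and sign flips. 1 means perfect recovery,
#' while unrelated random unit vectors score near `E|cos|` of random
#' directions (small for large M).
#'
#' @param phi_hat Estimated dictionary (M x K_hat).
#' @param phi_star Ground-truth dictionary (M x K_true), `K_hat >= K_true`.
#' @return Score in `[0, 1]`, plus a `"matching"` attribute giving the
#'   estimated column matched to each true column.
#' @export
dictionary_recovery_score <- function(phi_hat, phi_star) {
  phi_hat <- as.matrix(phi_hat); phi_star <- as.matrix(phi_star)
  if (nrow(phi_hat) != nrow(phi_star))
    stop("dictionaries must share the pixel dimension", call. = FALSE)
  if (ncol(phi_hat) < ncol(phi_star))
    stop("phi_hat must have at least as many columns as phi_star",
         call. = FALSE)
  A <- normalize_columns(phi_star); Bm <- normalize_columns(phi_hat)
  C <- abs(crossprod(A, Bm))        # K_true x K_hat |cosine| similarities
  match <- solve_assignment(1 - C)  # maximize similarity
  score <- mean(C[cbind(seq_len(ncol(A)), match)])
  attr(score, "matching") <- match
  score
}

#' Batched metric traces of iterative inference on a test set
#'
#' Runs online inference on every test patch simultaneously for `T_test`
#' steps and records, per step, the test-set mean R^2 (computed per patch,
#' then averaged), the sparsity fraction of the sampled latents, the mean
#' update norm, and the mean free energy.
#'
#' @param model An `ivae_model` (or a list with `phi`, `u_init`, `cfg`).
#' @param X_test Test patches, one per row (n x M matrix or
#'   `patch_dataset`).
#' @param T_test Number of inference steps.
#' @param eta Step size.
#' @param seed Seed for the latent draws.
#' @param decode `"sample"` (reconstruction from the sampled spike counts,
#'   the model's representation) or `"mean"` (deterministic decoding from
#'   the firing rates, for MAP-style comparisons).
#' @return An object of class `metric_trace`: data frame with columns
#'   `step`, `r2`, `sparsity`, `update_norm`, `free_energy`, and attributes
#'   `final_r2`, `final_sparsity` (final-state test-set means).
#' @export
evaluate_model <- function(model, X_test, T_test = 1000L, eta = 1,
                           seed = 1L, decode = c("sample", "mean")) {
  decode <- match.arg(decode)
  cfg <- model$cfg
  X <- t(as_patch_matrix(X_test))        # M x B
  B <- ncol(X)
  phi <- model$phi
  set.seed(seed)
  lo <- cfg$u_clamp[1]; hi <- cfg$u_clamp[2]
  W <- crossprod(phi)
  FF <- crossprod(phi, X)
  U <- matrix(model$u_init, cfg$K, B)
  ss_tot <- colSums(sweep(X, 2, colMeans(X))^2)
  if (any(ss_tot == 0))
    stop("R^2 undefined: constant test patch present", call. = FALSE)
  r2 <- spars <- upd <- fe <- numeric(T_test)
  U_prev <- U
  for (t in seq_len(T_test)) {
    Uc <- pmin(pmax(U, lo), hi)
    if (cfg$family == "poisson") {
      R <- exp(Uc)
      Z <- stats::rpois(length(R), R)
      storage.mode(Z) <- "double"; dim(Z) <- dim(R)
    } else {
      Z <- U + matrix(stats::rnorm(length(U)), nrow(U), ncol(U))
      if (cfg$family == "gaussian_relu") Z <- pmax(Z, 0)
    }
    E <- X - phi %*% Z
    if (decode == "sample") {
      r2[t] <- mean(1 - colSums(E^2) / ss_tot)
    } else {
      Emean <- X - phi %*% (if (cfg$family == "poisson") R else U)
      r2[t] <- mean(1 - colSums(Emean^2) / ss_tot)
    }
    spars[t] <- mean(Z == 0)
    U0c <- pmin(pmax(U_prev, lo), hi)
    kl_b <- if (cfg$family == "poisson")
      colSums(exp(Uc) * (Uc - U0c) - exp(Uc) + exp(U0c))
    else colSums(0.5 * (U - U_prev)^2)
    fe[t] <- mean(0.5 * colSums(E^2) + cfg$beta * kl_b)
    S <- U + eta * (FF - W %*% Z)
    U_new <- pmin(pmax(S, lo), hi)
    upd[t] <- mean(sqrt(colSums((U_new - U)^2))) / eta
    U_prev <- U
    U <- U_new
    if (any(!is.finite(U)))
      stop(sprintf("non-finite potentials at evaluation step %d", t),
           call. = FALSE)
  }
  out <- data.frame(step = seq_len(T_test), r2 = r2, sparsity = spars,
                    update_norm = upd, free_energy = fe)
  class(out) <- c("metric_trace", "data.frame")
  attr(out, "final_r2") <- r2[T_test]
  attr(out, "final_sparsity") <- spars[T_test]
  out
}

#' Contrast-dependent response latency to drifting gratings
#'
#' Presents a drifting-grating sequence frame-by-frame to the model's online
#' dynamics and measures, for each contrast, the latency of the evoked
#' response: rate traces are averaged over independent spike-draw trials
#' (a trial-averaged PSTH), a blank (zero-contrast) reference run with the
#' same seeds is subtracted, and the response is the peak-unit elevation of
#' the corrected trace (the best-driven neuron, the analogue of the
#' recorded neuron in a physiology experiment). Latency is the first step
#' at which that response crosses an absolute criterion, a fixed fraction
#' of the spontaneous (blank) rate. Because evoked responses ramp up with a
#' slope proportional to contrast, integration to a fixed threshold yields
#' the contrast-dependent latency characteristic of V1 neurons; the probe
#' checks for that signature.
#'
#' @param model An `ivae_model`.
#' @param contrasts Vector of contrasts in `[0, 1]`.
#' @param grating_spec List of arguments for [drifting_grating()]
#'   (`patch_size` must square to the model's pixel dimension).
#' @param T Number of inference steps (frames are recycled if shorter).
#' @param n_trials Number of independent spike-draw repeats; rate traces are
#'   averaged across trials (the analogue of a trial-averaged PSTH) before
#'   the latency threshold is applied.
#' @param eta Inference step size.
#' @param threshold The latency criterion as a fraction of the mean
#'   spontaneous (blank) rate (default 0.25); a stimulus whose evoked
#'   response never reaches it is flagged not-converged.
#' @param seed Seed for the spike draws.
#' @return Data frame with columns `contrast`, `latency` (step index or NA),
#'   and `converged`.
#' @export
contrast_latency <- function(model, contrasts, grating_spec = list(),
                             T = 200L, n_trials = 5L, eta = 0.1,
                             threshold = 0.25, seed = 1L) {
  cfg <- model$cfg
  W <- crossprod(model$phi)
  K <- length(model$u_init)
  trial_rates <- function(ct) {
    gs <- utils::modifyList(grating_spec, list(contrast = ct, T = T))
    frames <- do.call(drifting_grating, gs)$X   # T x M
    rates <- matrix(0, K, T)
    for (trial in seq_len(n_trials)) {
      set.seed(seed * 1000L + trial)
      U <- model$u_init
      for (t in seq_len(T)) {
        x <- frames[((t - 1L) %% nrow(frames)) + 1L, ]
        rates[, t] <- rates[, t] + rates_from_potentials(U, cfg) / n_trials
        z <- sample_posterior(U, cfg)
        U <- clamp_u(U + eta * (drop(crossprod(model$phi, x)) -
                                  drop(W %*% z)),
                     cfg$u_clamp)
      }
    }
    rates
  }
  blank <- trial_rates(0)
  spont <- mean(blank[, 1])
  thr <- threshold * spont
  res <- lapply(contrasts, function(ct) {
    resp <- apply(trial_rates(ct) - blank, 2, max)  # evoked peak-unit trace
    if (max(resp) <= thr)
      return(data.frame(contrast = ct, latency = NA_integer_,
                        converged = FALSE))
    data.frame(contrast = ct,
               latency = as.integer(which(resp >= thr)[1]),
               converged = TRUE)
  })
  do.call(rbind, res)
}
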