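#' Training configuration
#'
#' @param T_train Positive integer; number of unrolled inference steps per
#'   batch. Acts as the effective model depth.
#' @param epochs,batch_size Positive integers.
#' @param lr Learning rate.
#' @param lr_schedule `"cosine"` (half-cosine decay to zero over training)
#'   or `"constant"`.
#' @param optimizer `"sgd"` (plain gradient steps, whose size shrinks with
#'   the gradient itself near an optimum; the default, markedly more stable
#'   for dictionary learning here) or `"adam"` (adaptive-moment steps).
#' @param warmup_epochs Epochs at the start during which only the initial
#'   potentials are updated while the dictionary is frozen, letting the
#'   learnable prior calibrate to the data scale before dictionary
#'   plasticity begins.
#' @param eta Inference step size used during the unrolled rollout.
#' @param seed Integer seed controlling initialization, shuffling, and
#'   spike draws.
#' @param normalize_dict Re-impose unit-norm dictionary columns after every
#'   optimizer update (keeps the lateral self-weights at 1 and makes beta
#'   comparable across runs).
#' @param loss_scale `"sum"` (default: free energy summed over the
#'   T_train trajectory, so beta grids proportional to T_train are
#'   meaningful) or `"mean"` (divided by T_train).
#' @param beta_warmup Optional linear warm-up of beta from 0 over the first
#'   half of training; off by default (beta is varied across runs, not
#'   within).
#' @return An object of class `train_config`.
#' @export
train_config <- function(T_train = 16L, epochs = 67L, batch_size = 2048L,
                         lr = 1e-2, lr_schedule = c("cosine", "constant"),
                         optimizer = c("sgd", "adam"), warmup_epochs = 17L,
                         eta = 0.1, seed = 1L, normalize_dict = TRUE,
                         loss_scale = c("sum", "mean"), beta_warmup = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  loss_scale <- match.arg(loss_scale)
  optimizer <- match.arg(optimizer)
  if (T_train < 1 || batch_size < 1 || epochs < 1)
    stop("T_train, epochs and batch_size must be >= 1", call. = FALSE)
  structure(list(T_train = as.integer(T_train), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_schedule = lr_schedule, optimizer = optimizer,
                 warmup_epochs = as.integer(warmup_epochs),
                 eta = eta, seed = as.integer(seed),
                 normalize_dict = isTRUE(normalize_dict),
                 loss_scale = loss_scale, beta_warmup = isTRUE(beta_warmup)),
            class = "train_config")
}

# Forward/backward pass of the unrolled online inference trajectory.
#
# X: M x B batch; phi: M x K; u_init: length-K. The loss is
# sum_t mean_b [ recon_t + beta * kl_t ] with the rolling prior
# u0_t = u_{t-1}; gradients flow through both the posterior and the prior
# side of each KL term (full unrolled backpropagation).
# When `frozen` is supplied (lists Z/R or eps per step from a reference
# forward), the sampling step is replaced by its straight-through surrogate
# z~ = z0 + r(u) - r0 (Poisson) or z = u + eps0 (Gaussian), making the
# rollout a deterministic differentiable function of (phi, u_init) whose
# exact gradient the backward pass computes -- this is what the frozen-draw
# finite-difference oracle in the tests differentiates.
ivae_rollout_grad <- function(X, phi, u_init, cfg, T_train, eta = 1,
                              frozen = NULL, grad = TRUE, beta = NULL) {
  X <- as.matrix(X); phi <- as.matrix(phi)
  M <- nrow(X); B <- ncol(X); K <- ncol(phi)
  if (nrow(phi) != M || length(u_init) != K || K != cfg$K)
    stop("dimension mismatch in rollout", call. = FALSE)
  if (is.null(beta)) beta <- cfg$beta
  lo <- cfg$u_clamp[1]; hi <- cfg$u_clamp[2]
  poisson <- cfg$family == "poisson"
  relu <- cfg$family == "gaussian_relu"
  W <- crossprod(phi)
  FF <- crossprod(phi, X)

  Us <- vector("list", T_train); Zs <- vector("list", T_train)
  Rs <- vector("list", T_train); Es <- vector("list", T_train)
  maskU <- vector("list", T_train + 1L)
  store <- list(Z = vector("list", T_train), R = vector("list", T_train),
                eps = vector("list", T_train))
  U <- matrix(u_init, K, B)
  maskU[[1L]] <- matrix(TRUE, K, B)
  U_prev <- U   # prior at step 1 equals the initial potentials
  recon_sum <- kl_sum <- 0
  recon_steps <- kl_steps <- numeric(T_train)

  for (t in seq_len(T_train)) {
    Uc <- pmin(pmax(U, lo), hi)
    if (poisson) {
      R <- exp(Uc)
      if (is.null(frozen)) {
        Z0 <- stats::rpois(K * B, R)
        storage.mode(Z0) <- "double"; dim(Z0) <- c(K, B)
        Ztil <- Z0
        store$Z[[t]] <- Z0; store$R[[t]] <- R
      } else {
        Ztil <- frozen$Z[[t]] + R - frozen$R[[t]]
      }
    } else {
      R <- NULL
      if (is.null(frozen)) {
        eps <- matrix(stats::rnorm(K * B), K, B)
        store$eps[[t]] <- eps
      } else eps <- frozen$eps[[t]]
      Ztil <- U + eps
      if (relu) Ztil <- pmax(Ztil, 0)
    }
    E <- X - phi %*% Ztil
    recon_b <- 0.5 * colSums(E^2)
    U0c <- pmin(pmax(U_prev, lo), hi)
    kl_b <- if (poisson) colSums(exp(Uc) * (Uc - U0c) - exp(Uc) + exp(U0c))
            else colSums(0.5 * (U - U_prev)^2)
    recon_steps[t] <- mean(recon_b); kl_steps[t] <- mean(kl_b)
    recon_sum <- recon_sum + recon_steps[t]
    kl_sum <- kl_sum + kl_steps[t]

    Us[[t]] <- U; Zs[[t]] <- Ztil; Rs[[t]] <- R; Es[[t]] <- E
    S <- U + eta * (FF - W %*% Ztil)
    U_prev <- U
    U <- pmin(pmax(S, lo), hi)
    maskU[[t + 1L]] <- (S > lo) & (S < hi)
    if (any(!is.finite(U)))
      stop(sprintf("non-finite membrane potentials at unrolled step %d", t),
           call. = FALSE)
  }
  loss <- recon_sum + beta * kl_sum

  out <- list(loss = loss, recon = recon_sum, kl = kl_sum,
              recon_steps = recon_steps, kl_steps = kl_steps,
              frozen = store, u_final = U)

  if (grad) {
    gPhi <- matrix(0, M, K)
    Lam <- matrix(0, K, B)            # adjoint of U_{t+1}
    prior_carry <- matrix(0, K, B)    # dKL_{t+1} / dU_t (rolling-prior path)
    for (t in rev(seq_len(T_train))) {
      U <- Us[[t]]; Ztil <- Zs[[t]]; E <- Es[[t]]
      a <- maskU[[t + 1L]] * Lam          # adjoint of the pre-clamp update
      if (t < T_train) {
        gPhi <- gPhi + eta * (X %*% t(a) -
                              phi %*% (Ztil %*% t(a) + a %*% t(Ztil)))
      }
      dZ <- -crossprod(phi, E) - eta * (W %*% a)
      gPhi <- gPhi - E %*% t(Ztil)
      U_prev <- if (t > 1L) Us[[t - 1L]] else Us[[1L]]
      if (poisson) {
        Uc <- pmin(pmax(U, lo), hi)
        U0c <- pmin(pmax(U_prev, lo), hi)
        mR <- (U > lo) & (U < hi)
        dKL <- beta * (mR * exp(Uc) * (Uc - U0c))
        dUz <- dZ * exp(Uc) * mR
        mR_prev <- (U_prev > lo) & (U_prev < hi)
        prior_next <- beta * (mR_prev * (exp(U0c) - exp(Uc)))
      } else {
        dKL <- beta * (U - U_prev)
        dUz <- if (relu) dZ * (Ztil > 0) else dZ
        prior_next <- -dKL
      }
      Lam <- a + dUz + dKL + prior_carry
      prior_carry <- prior_next
    }
    # at t = 1 the prior equals the initial potentials themselves
    out$grad_phi <- gPhi / B
    out$grad_u_init <- rowSums(Lam + prior_carry) / B
  }
  out
}

#' Accumulated free energy over the unrolled inference trajectory
#'
#' Runs online inference for `T_train` steps on each batch element and
#' returns the trajectory loss `sum_t F_t` (averaged over the batch)
#' together with its straight-through gradients with respect to the
#' dictionary and the initial potentials. Each step's KL is taken against
#' the previous step's potentials (the rolling prior), and gradients flow
#' through the entire unrolled trajectory, prior side included.
#'
#' @param X Batch of pixel vectors, M x B matrix (columns are samples).
#' @param phi Dictionary (M x K).
#' @param u_init Initial membrane potentials (length K).
#' @param cfg A [latent_config()].
#' @param T_train Number of unrolled steps.
#' @param eta Inference step size.
#' @param seed Optional seed for the latent draws.
#' @param frozen Optional frozen-draw record (from a previous call's
#'   `$frozen`) replacing sampling by its straight-through surrogate; used
#'   by finite-difference checks.
#' @param grad Compute gradients (default `TRUE`).
#' @return A list with `loss`, `recon`, `kl`, per-step breakdowns,
#'   `grad_phi`, `grad_u_init`, and the `frozen` draw record.
#' @export
unrolled_loss <- function(X, phi, u_init, cfg, T_train, eta = 1,
                          seed = NULL, frozen = NULL, grad = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  ivae_rollout_grad(X, phi, u_init, cfg, T_train, eta = eta,
                    frozen = frozen, grad = grad)
}

adam_new <- function(dim) list(m = array(0, dim), v = array(0, dim), t = 0L)

adam_update <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$step <- lr * mhat / (sqrt(vhat) + eps)
  state
}

normalize_columns <- function(phi) {
  nrm <- sqrt(colSums(phi^2))
  nrm[nrm == 0] <- 1
  sweep(phi, 2, nrm, "/")
}

#' Fit an iterative VAE by backpropagation through the inference trajectory
#'
#' Learns the dictionary and the initial membrane potentials by Adam on the
#' accumulated free energy of the unrolled online inference rollout: one
#' optimizer update per batch, gradients accumulated across all `T_train`
#' steps (not just the final state). Dictionary columns are re-normalized to
#' unit length after every update unless disabled.
#'
#' @param dataset A `patch_dataset` (see [synth_patches()]) or a numeric
#'   matrix with one patch per row.
#' @param cfg A [latent_config()].
#' @param tcfg A [train_config()].
#' @param phi_init Optional initial dictionary; defaults to random unit-norm
#'   columns.
#' @param u_init_start Initial value of the learnable initial potentials
#'   (scalar or length-K); default `log(0.5)`, about half a spike per step.
#' @param verbose Print per-epoch progress.
#' @return An object of class `ivae_model`: list with `phi`, `u_init`,
#'   `cfg`, `tcfg`, and a per-epoch `history` data frame (mean trajectory
#'   free energy and its reconstruction and KL parts).
#' @export
fit_ivae <- function(dataset, cfg, tcfg = train_config(), phi_init = NULL,
                     u_init_start = log(0.5), verbose = FALSE) {
  X <- t(as_patch_matrix(dataset))           # M x n
  M <- nrow(X); n <- ncol(X)
  set.seed(tcfg$seed)
  phi <- if (is.null(phi_init)) {
    normalize_columns(matrix(stats::rnorm(M * cfg$K), M, cfg$K))
  } else as.matrix(phi_init)
  u_init <- rep(u_init_start, length.out = cfg$K)

  tcfg$batch_size <- min(tcfg$batch_size, n)
  n_batches <- max(1L, floor(n / tcfg$batch_size))
  total_updates <- tcfg$epochs * n_batches
  adam <- tcfg$optimizer == "adam"
  if (adam) {
    opt_phi <- adam_new(dim(phi))
    opt_u <- adam_new(cfg$K)
  }
  upd <- 0L
  hist_loss <- hist_recon <- hist_kl <- numeric(tcfg$epochs)
  scale_div <- if (tcfg$loss_scale == "mean") tcfg$T_train else 1

  # prior calibration phase: dictionary frozen, only u_init adapts
  for (ep in seq_len(tcfg$warmup_epochs)) {
    perm <- sample.int(n)
    for (b in seq_len(n_batches)) {
      idx <- perm[((b - 1L) * tcfg$batch_size + 1L):(b * tcfg$batch_size)]
      res <- ivae_rollout_grad(X[, idx, drop = FALSE], phi, u_init, cfg,
                               tcfg$T_train, eta = tcfg$eta)
      u_init <- u_init - tcfg$lr * res$grad_u_init / scale_div
    }
  }

  for (ep in seq_len(tcfg$epochs)) {
    perm <- sample.int(n)
    ep_loss <- ep_recon <- ep_kl <- 0
    beta_ep <- cfg$beta
    if (tcfg$beta_warmup)
      beta_ep <- cfg$beta * min(1, (ep - 1) / max(1, tcfg$epochs / 2))
    for (b in seq_len(n_batches)) {
      idx <- perm[((b - 1L) * tcfg$batch_size + 1L):(b * tcfg$batch_size)]
      res <- ivae_rollout_grad(X[, idx, drop = FALSE], phi, u_init, cfg,
                               tcfg$T_train, eta = tcfg$eta, beta = beta_ep)
      if (!is.finite(res$loss))
        stop(sprintf("non-finite loss at epoch %d, batch %d", ep, b),
             call. = FALSE)
      lr_t <- if (tcfg$lr_schedule == "cosine")
        tcfg$lr * 0.5 * (1 + cos(pi * upd / max(1L, total_updates)))
      else tcfg$lr
      if (adam) {
        opt_phi <- adam_update(opt_phi, res$grad_phi / scale_div, lr_t)
        phi <- phi - opt_phi$step
        opt_u <- adam_update(opt_u, res$grad_u_init / scale_div, lr_t)
        u_init <- u_init - opt_u$step
      } else {
        phi <- phi - lr_t * res$grad_phi / scale_div
        u_init <- u_init - lr_t * res$grad_u_init / scale_div
      }
      if (tcfg$normalize_dict) phi <- normalize_columns(phi)
      upd <- upd + 1L
      ep_loss <- ep_loss + res$loss / scale_div
      ep_recon <- ep_recon + res$recon / scale_div
      ep_kl <- ep_kl + res$kl / scale_div
    }
    hist_loss[ep] <- ep_loss / n_batches
    hist_recon[ep] <- ep_recon / n_batches
    hist_kl[ep] <- ep_kl / n_batches
    if (verbose)
      message(sprintf("epoch %3d/%d  F=%.4f  recon=%.4f  kl=%.4f",
                      ep, tcfg$epochs, hist_loss[ep], hist_recon[ep],
                      hist_kl[ep]))
  }
  structure(list(phi = phi, u_init = u_init, cfg = cfg, tcfg = tcfg,
                 history = data.frame(epoch = seq_len(tcfg$epochs),
                                      free_energy = hist_loss,
                                      recon = hist_recon, kl = hist_kl)),
            class = "ivae_model")
}

#' @export
print.ivae_model <- function(x, ...) {
  cat(sprintf("<ivae_model> family=%s K=%d beta=%g T_train=%d epochs=%d\n",
              x$cfg$family, x$cfg$K, x$cfg$beta, x$tcfg$T_train,
              x$tcfg$epochs))
  cat(sprintf("  final mean trajectory free energy: %.4f\n",
              utils::tail(x$history$free_energy, 1)))
  invisible(x)
}

soft_threshold <- function(m, lambda) sign(m) * pmax(abs(m) - lambda, 0)

#' Locally competitive algorithm (LCA) sparse coding baseline
#'
#' Deterministic, non-spiking precursor of the iterative Poisson VAE:
#' internal potentials follow
#' `m <- m + eta * (Phi^T x - (Phi^T Phi - I) s - m)` with the code
#' `s = soft_threshold(m, lambda)`, converging to a MAP sparse code.
#'
#' @param x Input pixel vector.
#' @param phi Dictionary (M x K).
#' @param lambda_thresh Non-negative soft threshold (sparsity penalty).
#' @param T Number of iterations.
#' @param eta Step size in (0, 1].
#' @return A list with the final code `s`, the reconstruction `x_hat`, and
#'   the final potentials `m`.
#' @export
lca_baseline <- function(x, phi, lambda_thresh, T = 200L, eta = 0.1) {
  if (lambda_thresh < 0) stop("lambda_thresh must be >= 0", call. = FALSE)
  phi <- as.matrix(phi)
  K <- ncol(phi)
  ff <- drop(crossprod(phi, x))
  G <- crossprod(phi) - diag(K)
  m <- numeric(K)
  for (t in seq_len(T)) {
    s <- soft_threshold(m, lambda_thresh)
    m <- m + eta * (ff - drop(G %*% s) - m)
    if (any(!is.finite(m)))
      stop(sprintf("LCA diverged at step %d", t), call. = FALSE)
  }
  s <- soft_threshold(m, lambda_thresh)
  list(s = s, x_hat = drop(phi %*% s), m = m)
}
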