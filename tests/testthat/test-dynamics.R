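test_that("lateral weights are the symmetric PSD Gram matrix", {
  # orthonormal columns give the identity
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:3]
  expect_equal(lateral_weights(Q), diag(3), tolerance = 1e-12)
  expect_equal(lateral_weights(matrix(c(1, 1))), matrix(2))
  set.seed(1)
  phi <- matrix(rnorm(32), 8, 4)
  W <- lateral_weights(phi)
  expect_equal(W, t(W))
  expect_true(all(eigen(W, symmetric = TRUE)$values >= -1e-10))
  expect_equal(diag(W), colSums(phi^2))
})

test_that("static-prior step implements the leaky natural-gradient update", {
  cfg <- latent_config(1, "poisson", beta = 0)
  dyn <- dynamics_config("static_prior", eta = 1, T = 1)
  phi <- matrix(c(1, 1))
  st <- inference_state(0)
  # pinned draw z = 3: u' = 0 + (3 - 2*3) = -3
  st2 <- static_prior_step(st, c(1, 2), phi, cfg, dyn, z = 3)
  expect_equal(st2$u, -3)
  expect_equal(st2$u0, 0)           # prior untouched
  # null drive at a fixed point
  cfgb <- latent_config(2, "poisson", beta = 0.5, u_clamp = c(-60, 8))
  stf <- inference_state(c(-50, -50))
  phi2 <- matrix(rnorm(6), 3, 2)
  stf2 <- static_prior_step(stf, c(0, 0, 0), phi2, cfgb, dyn, z = c(0, 0))
  expect_equal(stf2$u, stf$u)
  # random instance equals -G^{-1} grad F composed from core operations
  set.seed(2)
  for (i in 1:10) {
    phi3 <- matrix(rnorm(12), 4, 3)
    x <- rnorm(4); u <- runif(3, -1, 1); u0 <- runif(3, -1, 1)
    cfg3 <- latent_config(3, "poisson", beta = 0.8, u_clamp = c(-60, 60))
    z <- sample_posterior(u, cfg3)
    st3 <- structure(list(t = 0L, u = u, u0 = u0, z = NULL),
                     class = "inference_state")
    eta <- 0.3
    dyn3 <- dynamics_config("static_prior", eta = eta, T = 1)
    out <- static_prior_step(st3, x, phi3, cfg3, dyn3, z = z)
    nat_grad <- -free_energy_gradient(x, phi3, u, u0, z, cfg3) /
      fisher_preconditioner(u, cfg3)
    expect_equal(out$u, u + eta * nat_grad, tolerance = 1e-10)
  }
})

test_that("online step rolls the prior and drops the leak term", {
  cfg <- latent_config(1, "poisson")
  dyn <- dynamics_config("online", eta = 1, T = 1)
  phi <- matrix(c(1, 1))
  st <- inference_state(0)
  st2 <- online_step(st, c(1, 2), phi, cfg, dyn, z = 3)
  expect_equal(st2$u, -3)
  expect_equal(st2$u0, 0)           # new prior = old posterior
  st3 <- online_step(st2, c(1, 2), phi, cfg, dyn, z = 0)
  expect_equal(st3$u0, -3)
  # K=8, M=16 random instance vs direct matrix arithmetic
  set.seed(3)
  phi8 <- matrix(rnorm(16 * 8), 16, 8)
  x <- rnorm(16); u <- runif(8, -1, 1); z <- rpois(8, 1)
  cfg8 <- latent_config(8, "poisson", u_clamp = c(-60, 60))
  st8 <- structure(list(t = 0L, u = u, u0 = u, z = NULL),
                   class = "inference_state")
  out <- online_step(st8, x, phi8, cfg8, dyn, z = z)
  expect_equal(out$u,
               u + drop(t(phi8) %*% x) - drop(t(phi8) %*% phi8 %*% z),
               tolerance = 1e-10)
})

test_that("potential and rate-space updates are the same dynamic", {
  dyn <- dynamics_config("online", eta = 1, T = 1)
  # hand-computed toy: r=1, exp(phi^T x)=e^3, denominator e^6 -> e^{-3}
  phi <- matrix(c(1, 1))
  r2 <- rate_space_step(1, c(1, 2), phi, 3, dyn)
  expect_equal(r2, exp(-3))
  # no normalization without spikes
  expect_equal(rate_space_step(2, c(1, 2), phi, 0, dyn), 2 * exp(3))
  expect_error(rate_space_step(1, c(1, 2), phi, 3,
                               dynamics_config("online", eta = 0.5)),
               "unit step")
  # equivalence on random states (clamp non-binding)
  set.seed(4)
  cfg <- latent_config(4, "poisson", u_clamp = c(-20, 20))
  for (i in 1:200) {
    phi4 <- matrix(rnorm(24) / 3, 6, 4)
    x <- rnorm(6) / 2; u <- runif(4, -1.5, 1.5); z <- rpois(4, 1.5)
    st <- structure(list(t = 0L, u = u, u0 = u, z = NULL),
                    class = "inference_state")
    u_next <- online_step(st, x, phi4, cfg, dyn, z = z)$u
    r_next <- rate_space_step(exp(u), x, phi4, z, dyn)
    expect_equal(exp(u_next), r_next, tolerance = 1e-10)
  }
})

test_that("run_inference traces are deterministic and well-formed", {
  tp <- toy_problem(seed = 6)
  dyn <- dynamics_config("online", eta = 0.2, T = 40)
  tr1 <- run_inference(tp$x, tp$phi, tp$cfg, dyn, seed = 9)
  tr2 <- run_inference(tp$x, tp$phi, tp$cfg, dyn, seed = 9)
  expect_identical(tr1$u, tr2$u)
  expect_identical(tr1$z, tr2$z)
  expect_equal(tr1$step, 1:40)
  expect_equal(tr1$total, tr1$recon + tp$cfg$beta * tr1$kl)
  # T = 1 equals a single step application
  dyn1 <- dynamics_config("online", eta = 0.2, T = 1)
  tr <- run_inference(tp$x, tp$phi, tp$cfg, dyn1, seed = 11)
  set.seed(11)
  st <- online_step(inference_state(rep(log(0.5), 3)), tp$x, tp$phi, tp$cfg,
                    dyn1)
  expect_equal(tr$z[, 1], st$z)
  expect_equal(tr$u_final, st$u)
  # record_every thins the trace
  dynr <- dynamics_config("online", eta = 0.2, T = 40, record_every = 10)
  trr <- run_inference(tp$x, tp$phi, tp$cfg, dynr, seed = 9)
  expect_equal(trr$step, c(10, 20, 30, 40))
})

test_that("inference converges on data drawn from the model", {
  set.seed(7)
  spec <- synthetic_spec(M = 16, K_true = 4, n_patches = 1, noise_sigma = 0,
                         seed = 7)
  ds <- synth_patches(spec)
  x <- ds$X[1, ]
  cfg <- latent_config(4, "poisson", beta = 1)
  dyn <- dynamics_config("online", eta = 0.1, T = 1000)
  tr <- run_inference(x, ds$phi_star, cfg, dyn, seed = 8)
  expect_lt(mean(tr$update_norm[901:1000]), mean(tr$update_norm[1:100]))
})

test_that("strong spikers self-suppress when input is absent", {
  set.seed(8)
  phi <- matrix(rnorm(12), 4, 3)
  phi <- sweep(phi, 2, sqrt(colSums(phi^2)), "/")
  cfg <- latent_config(3, "poisson")
  dyn <- dynamics_config("online", eta = 0.5, T = 1)
  u <- c(3, -1, -1)
  st <- structure(list(t = 0L, u = u, u0 = u, z = NULL),
                  class = "inference_state")
  out <- online_step(st, c(0, 0, 0, 0), phi, cfg, dyn, z = c(20, 0, 0))
  expect_lt(out$u[1], u[1])
})

test_that("mean-field fixed point solves phi^T x = W exp(u)", {
  # deterministic map obtained by replacing z with its mean r
  set.seed(9)
  phi <- matrix(rnorm(8), 4, 2)
  phi <- sweep(phi, 2, sqrt(colSums(phi^2)), "/")
  a <- c(1.5, 0.7)
  x <- drop(phi %*% a)
  W <- crossprod(phi)
  eta <- 0.2
  u <- log(c(0.5, 0.5))
  for (t in 1:2000)
    u <- u + eta * (drop(crossprod(phi, x)) - drop(W %*% exp(u)))
  # root-finding oracle: exp(u*) = W^{-1} phi^T x (positive here)
  u_star <- log(drop(solve(W, crossprod(phi, x))))
  expect_equal(u, u_star, tolerance = 1e-8)
  expect_equal(exp(u), a, tolerance = 1e-8)
})

test_that("dimension mismatches are rejected", {
  cfg <- latent_config(2, "poisson")
  dyn <- dynamics_config("online")
  st <- inference_state(c(0, 0))
  expect_error(online_step(st, c(1, 2, 3), matrix(rnorm(4), 2, 2), cfg, dyn),
               "match")
  expect_error(online_step(inference_state(0), c(1, 2),
                           matrix(rnorm(4), 2, 2), cfg, dyn), "disagree")
})
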