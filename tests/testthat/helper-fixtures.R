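# Small deterministic fixtures shared across test files.

toy_problem <- function(M = 6, K = 3, seed = 1, beta = 0.7,
                        family = "poisson") {
  set.seed(seed)
  phi <- matrix(rnorm(M * K), M, K)
  phi <- sweep(phi, 2, sqrt(colSums(phi^2)), "/")
  list(phi = phi,
       x = rnorm(M),
       u = rnorm(K, 0, 0.5),
       u0 = rnorm(K, 0, 0.5),
       cfg = latent_config(K, family, beta = beta))
}

# Brute-force Poisson KL by direct pmf summation, truncated far into the
# tail; independent of the closed form under test.
pmf_sum_poisson_kl <- function(u, u0, kmax = 400) {
  sum(vapply(seq_along(u), function(i) {
    l1 <- exp(u[i]); l2 <- exp(u0[i])
    k <- 0:kmax
    p1 <- dpois(k, l1)
    sum(p1 * (dpois(k, l1, log = TRUE) - dpois(k, l2, log = TRUE)))
  }, numeric(1)))
}
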