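# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: quadrature instead of Monte Carlo, full
# state enumeration instead of MCMC, direct formula arithmetic instead of
# the packaged implementations.

# E[(1 - psi (1 - (1-p)^J))^S] by nested Gauss-ready adaptive quadrature
# over the two independent normals on the logit scale.
quad_missed <- function(S, J, occ_mu, occ_sd, det_mu = -2, det_sd = 1) {
  inner <- function(b) {
    vapply(b, function(bb) {
      psi <- plogis(bb)
      stats::integrate(function(a) {
        (1 - psi * (1 - (1 - plogis(a))^J))^S * dnorm(a, det_mu, det_sd)
      }, -Inf, Inf)$value
    }, numeric(1))
  }
  stats::integrate(function(b) inner(b) * dnorm(b, occ_mu, occ_sd),
                   -Inf, Inf)$value
}

# E[(1 - psi)^S] by quadrature.
quad_absent <- function(S, occ_mu, occ_sd) {
  stats::integrate(function(b) (1 - plogis(b))^S * dnorm(b, occ_mu, occ_sd),
                   -Inf, Inf)$value
}

# Brute-force posterior over all (w, z) configurations of the augmented
# model with fixed species parameters and Omega ~ Beta(a, b) marginalized.
# Returns the posterior pmf of N = sum(w).
enum_posterior_N <- function(y, psi, p, a = 1, b = 1) {
  S <- dim(y)[1]; J <- dim(y)[2]; M <- dim(y)[3]
  psi <- rep(psi, length.out = M)
  p <- rep(p, length.out = M)
  post <- setNames(numeric(M + 1), 0:M)
  for (wbits in 0:(2^M - 1)) {
    w <- as.integer(intToBits(wbits))[1:M]
    for (zbits in 0:(2^(S * M) - 1)) {
      z <- matrix(as.integer(intToBits(zbits))[1:(S * M)], S, M)
      pz <- 1
      for (k in 1:M) for (i in 1:S) {
        pk <- w[k] * psi[k]
        pz <- pz * ifelse(z[i, k] == 1, pk, 1 - pk)
      }
      if (pz == 0) next
      py <- 1
      for (k in 1:M) for (i in 1:S) for (j in 1:J) {
        pr <- z[i, k] * p[k]
        py <- py * ifelse(y[i, j, k] == 1, pr, 1 - pr)
      }
      pw <- beta(a + sum(w), b + M - sum(w)) / beta(a, b)
      post[sum(w) + 1] <- post[sum(w) + 1] + pw * pz * py
    }
  }
  post / sum(post)
}

# As above but the posterior marginal P(z[i,k] = 1 | y): used to check
# conditional site richness.
enum_posterior_z <- function(y, psi, p, a = 1, b = 1) {
  S <- dim(y)[1]; J <- dim(y)[2]; M <- dim(y)[3]
  psi <- rep(psi, length.out = M)
  p <- rep(p, length.out = M)
  pz_marg <- matrix(0, S, M)
  tot <- 0
  for (wbits in 0:(2^M - 1)) {
    w <- as.integer(intToBits(wbits))[1:M]
    for (zbits in 0:(2^(S * M) - 1)) {
      z <- matrix(as.integer(intToBits(zbits))[1:(S * M)], S, M)
      pz <- 1
      for (k in 1:M) for (i in 1:S) {
        pk <- w[k] * psi[k]
        pz <- pz * ifelse(z[i, k] == 1, pk, 1 - pk)
      }
      if (pz == 0) next
      py <- 1
      for (k in 1:M) for (i in 1:S) for (j in 1:J) {
        pr <- z[i, k] * p[k]
        py <- py * ifelse(y[i, j, k] == 1, pr, 1 - pr)
      }
      pr_state <- beta(a + sum(w), b + M - sum(w)) / beta(a, b) * pz * py
      pz_marg <- pz_marg + z * pr_state
      tot <- tot + pr_state
    }
  }
  pz_marg / tot
}

# The tiny 2-site, 2-visit, 2-observed + 1-augmented instance used by the
# enumeration checks.
tiny_instance <- function() {
  y <- array(0L, c(2, 2, 2))
  y[1, 1, 1] <- 1L
  y[2, 2, 2] <- 1L
  list(data = augment(occ_data(y), 1), psi = 0.5, p = 0.3)
}

# A small but informative simulated dataset for sampler-level tests.
small_fit_data <- function(seed = 42, S = 30, J = 3, n_species = 20,
                           n_aug = 30) {
  sp <- occ_scenario_ideal("Occ1", S = S, J = J, n_species = n_species)
  sim <- simulate_dataset(sp, seed = seed)
  list(sim = sim, aug = augment(sim$data, n_aug))
}
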