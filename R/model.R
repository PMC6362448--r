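#' Augment detection data with all-zero pseudo-species
#'
#' Parameter-expanded data augmentation: appends \code{n_aug} "potential
#' species" with all-zero detection histories, so that the total number of
#' species in the model is M = n_observed + n_aug and the unknown community
#' size N = sum(w) can be sampled. M only needs to be comfortably larger
#' than plausible N; [augmentation_adequate()] checks this after fitting.
#'
#' @param data an [occ_data()] or a binary S x J x K array.
#' @param n_aug number of pseudo-species to append (>= 0).
#' @return an [occ_data()] with \code{M = n_observed + n_aug};
#'   \code{n_observed} is unchanged, so augmenting twice by a and b equals
#'   augmenting once by a + b.
#' @export
augment <- function(data, n_aug) {
  stop_if_not_scalar_count(n_aug, "n_aug", min = 0)
  if (is.array(data)) data <- occ_data(data)
  stopifnot(inherits(data, "occ_data"))
  if (n_aug == 0) return(data)
  newy <- array(0L, dim = c(data$S, data$J, data$M + n_aug))
  newy[, , seq_len(data$M)] <- data$y
  out <- data
  out$y <- newy
  out$n_aug <- data$n_aug + as.integer(n_aug)
  out$M <- data$M + as.integer(n_aug)
  out$n_species <- out$M
  out$species <- c(data$species,
                   paste0("aug", data$n_aug + seq_len(n_aug)))
  out
}

#' MCMC settings
#'
#' @param n_chains number of chains.
#' @param n_iter total iterations per chain, including burn-in.
#' @param n_burn burn-in iterations discarded (adaptation of proposal
#'   scales happens only here, so the post-burn-in kernel is fixed and the
#'   stationary distribution is preserved).
#' @param thin keep every thin-th post-burn-in draw.
#' @param max_extra_blocks if convergence (max Rhat < 1.1) fails, up to this
#'   many additional blocks of \code{n_iter - n_burn} iterations are drawn,
#'   each time discarding all earlier draws as burn-in.
#' @param seed integer; chain c uses \code{seed + c}.
#' @param adapt adapt random-walk proposal scales during burn-in toward
#'   20--45\% acceptance.
#' @param adapt_batch adaptation window (iterations).
#' @param retain character subset of \code{c("w", "z", "species")}: latent
#'   draws to keep (off by default; "z" is needed for
#'   [region_richness()]/conditional [site_richness()], "w" + "species" for
#'   expected site richness).
#' @return object of class \code{occ_mcmc_config}.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 6000, n_burn = 1500,
                        thin = 1, max_extra_blocks = 3, seed = 1,
                        adapt = TRUE, adapt_batch = 50,
                        retain = character()) {
  stopifnot(n_iter > n_burn, n_burn >= 0, thin >= 1, n_chains >= 1,
            max_extra_blocks >= 0,
            all(retain %in% c("w", "z", "species")))
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin),
                 max_extra_blocks = as.integer(max_extra_blocks),
                 seed = as.integer(seed), adapt = adapt,
                 adapt_batch = as.integer(adapt_batch), retain = retain),
            class = "occ_mcmc_config")
}

#' @rdname mcmc_config
#' @details \code{mcmc_config_full()} returns full-scale simulation-study
#'   settings (3 chains of 50,000 kept iterations after 25,000 burn-in,
#'   thinned by 25); expect long runtimes.
#' @export
mcmc_config_full <- function(seed = 1, retain = character()) {
  mcmc_config(n_chains = 3, n_iter = 75000, n_burn = 25000, thin = 25,
              max_extra_blocks = 3, seed = seed, retain = retain)
}

#' Conditional probability that a species is present at a site
#'
#' Full conditional of the latent presence indicator z for one species at
#' one site, given its community membership w, occupancy probability psi,
#' per-visit detection probabilities p and the visit detections y. Any
#' detection forces z = 1 (no false positives); w = 0 forces z = 0; an
#' all-zero history otherwise gives
#' \code{psi * prod(1-p) / (psi * prod(1-p) + 1 - psi)}.
#'
#' @param psi occupancy probability.
#' @param p per-visit detection probabilities (length J).
#' @param y binary detections (length J).
#' @param w community membership (0/1).
#' @return probability that z = 1.
#' @export
cond_prob_z <- function(psi, p, y, w) {
  stopifnot(w %in% c(0, 1), length(p) == length(y))
  if (any(y == 1)) {
    if (w == 0) stop("inconsistent input: detections recorded for a ",
                     "species with w = 0", call. = FALSE)
    return(1)
  }
  if (w == 0) return(0)
  q0 <- prod(1 - p)
  psi * q0 / (psi * q0 + 1 - psi)
}

#' Conditional inclusion probability for an all-zero species
#'
#' Full conditional of the community-membership indicator w for a species
#' with no detections, with its presence states z marginalized out:
#' \deqn{P(w=1 | y=0) = \Omega \prod_i (1 - \psi_i p^{*\prime}_i) /
#'   (\Omega \prod_i (1 - \psi_i p^{*\prime}_i) + 1 - \Omega)}
#' where \eqn{p^{*\prime}_i = 1 - \prod_j (1 - p_{ij})} is the cumulative
#' detection probability at site i. Marginalizing z avoids the absorbing
#' w = 0 / z = 0 configuration of naive joint Gibbs updates.
#'
#' @param omega inclusion probability.
#' @param psi per-site occupancy probabilities (length S, or scalar).
#' @param p per-visit detection probabilities: scalar, length-S vector, or
#'   S x J matrix.
#' @param J number of visits (needed when \code{p} is not a matrix).
#' @return probability that w = 1.
#' @export
cond_prob_w <- function(omega, psi, p, J = NULL) {
  if (is.matrix(p)) {
    pstar <- 1 - apply(1 - p, 1, prod)
  } else {
    stopifnot(!is.null(J))
    pstar <- 1 - (1 - p)^J
  }
  lq <- sum(log1p(-psi * pstar))
  plogis(qlogis(omega) + lq)
}

#' Gibbs draw of the inclusion probability Omega
#'
#' With w_k ~ Bernoulli(Omega) and a Beta(a, b) prior, the full conditional
#' is Beta(a + sum(w), b + M - sum(w)).
#'
#' @param w binary membership vector (length M).
#' @param prior_a,prior_b Beta prior parameters.
#' @return one draw of Omega.
#' @export
gibbs_omega <- function(w, prior_a = 1, prior_b = 1) {
  stopifnot(all(w %in% c(0, 1)))
  rbeta(1, prior_a + sum(w), prior_b + length(w) - sum(w))
}

# ---------------------------------------------------------------------------
# Sampler internals

# Shrinkage slice sampler for a hyper-sd with uniform prior on (0, U].
# Target: prod_k N(e_k; mu, s) restricted to (0, U].
slice_sigma <- function(e, mu, s0, U) {
  M <- length(e)
  SS <- sum((e - mu)^2)
  g <- function(s) -M * log(s) - SS / (2 * s^2)
  y <- g(s0) - stats::rexp(1)
  lo <- 1e-12
  hi <- U
  for (i in 1:1000) {
    s1 <- runif(1, lo, hi)
    if (g(s1) >= y) return(s1)
    if (s1 < s0) lo <- s1 else hi <- s1
  }
  s0
}

# Intercept-only chain on a balanced design (every visit realized): the
# Bernoulli layers collapse to per-species sufficient statistics — the
# number of occupied sites and the total detections — so every update is
# O(M) and the S x M presence matrix is never materialized. Targets the
# same posterior as run_chain(); used automatically when applicable.
run_chain_fast <- function(mod, priors, st, n_iter, n_burn, thin, adapt,
                           adapt_batch, retain) {
  S <- mod$S; J <- mod$J; M <- mod$M
  pa <- priors$omega_beta[1]; pb <- priors$omega_beta[2]
  mu_sd <- priors$mu_prior_sd; U <- priors$sigma_support
  det_k <- mod$det_k
  und <- !det_k
  ndet <- colSums(mod$det_site)     # sites with >= 1 detection, per species
  dets <- colSums(mod$yf)           # total detections, per species

  n_keep <- (n_iter - n_burn) %/% thin
  par_names <- c("omega", "N", "mu_beta_int", "sigma_beta_int",
                 "mu_alpha_int", "sigma_alpha_int")
  pars <- matrix(NA_real_, n_keep, length(par_names),
                 dimnames = list(NULL, par_names))
  w_dr <- if ("w" %in% retain) matrix(NA_integer_, n_keep, M)
  b_dr <- if ("species" %in% retain) array(NA_real_, c(n_keep, M, 1))
  a_dr <- if ("species" %in% retain) array(NA_real_, c(n_keep, M, 1))

  w <- st$w; omega <- st$omega
  b <- st$beta[, 1]; a <- st$alpha[, 1]
  mu_b <- st$mu_b[1]; sig_b <- st$sig_b[1]
  mu_a <- st$mu_a[1]; sig_a <- st$sig_a[1]
  scl_b <- st$scl_b[, 1]; scl_a <- st$scl_a[, 1]
  acc_b <- numeric(M); acc_a <- numeric(M)
  att_b <- numeric(M); att_a <- numeric(M)
  sig_hits <- 0L; sig_draws <- 0L

  ki <- 0L
  for (it in seq_len(n_iter)) {
    psi <- plogis(b)
    l1p <- -log1pexp(a)                     # log(1 - p)
    q0 <- exp(J * l1p)                      # P(no detection | occupied)

    # -- w, collapsed over z, for undetected species
    if (any(und)) {
      lw1 <- S * log1p(-psi * (1 - q0))
      pw1 <- plogis(qlogis(omega) + lw1)
      w[und] <- as.numeric(runif(sum(und)) < pw1[und])
    }

    # -- occupied-site counts (z | w, summed over sites)
    pz <- plogis(b + J * l1p)
    occ <- ifelse(w == 1, ndet + rbinom(M, S - ndet, pz), 0)

    # -- Omega
    omega <- rbeta(1, pa + sum(w), pb + M - sum(w))

    wl <- w == 1
    # -- occupancy intercepts
    prop <- b + scl_b * rnorm(M)
    llr <- occ * (prop - b) - S * (log1pexp(prop) - log1pexp(b)) +
      dnorm(prop, mu_b, sig_b, log = TRUE) -
      dnorm(b, mu_b, sig_b, log = TRUE)
    acc <- wl & (log(runif(M)) < llr)
    b[acc] <- prop[acc]
    b[!wl] <- rnorm(sum(!wl), mu_b, sig_b)
    acc_b <- acc_b + acc
    att_b <- att_b + wl

    # -- detection intercepts
    occ_any <- occ > 0
    Tk <- occ * J
    prop <- a + scl_a * rnorm(M)
    llr <- dets * (prop - a) - Tk * (log1pexp(prop) - log1pexp(a)) +
      dnorm(prop, mu_a, sig_a, log = TRUE) -
      dnorm(a, mu_a, sig_a, log = TRUE)
    acc <- occ_any & (log(runif(M)) < llr)
    a[acc] <- prop[acc]
    a[!occ_any] <- rnorm(sum(!occ_any), mu_a, sig_a)
    acc_a <- acc_a + acc
    att_a <- att_a + occ_any

    # -- hyperparameters
    prec <- M / sig_b^2 + 1 / mu_sd^2
    mu_b <- rnorm(1, (sum(b) / sig_b^2) / prec, sqrt(1 / prec))
    sig_b <- slice_sigma(b, mu_b, sig_b, U)
    prec <- M / sig_a^2 + 1 / mu_sd^2
    mu_a <- rnorm(1, (sum(a) / sig_a^2) / prec, sqrt(1 / prec))
    sig_a <- slice_sigma(a, mu_a, sig_a, U)
    sig_draws <- sig_draws + 2L
    sig_hits <- sig_hits + (sig_b > 0.99 * U) + (sig_a > 0.99 * U)

    if (adapt && it <= n_burn && it %% adapt_batch == 0) {
      scl_b <- pmin(pmax(scl_b * exp(pmin(pmax(acc_b / pmax(att_b, 1) - 0.3,
                                               -0.25), 0.25)), 1e-3), 50)
      scl_a <- pmin(pmax(scl_a * exp(pmin(pmax(acc_a / pmax(att_a, 1) - 0.3,
                                               -0.25), 0.25)), 1e-3), 50)
      acc_b[] <- 0; acc_a[] <- 0; att_b[] <- 0; att_a[] <- 0
    }

    if (it > n_burn && (it - n_burn) %% thin == 0) {
      ki <- ki + 1L
      pars[ki, ] <- c(omega, sum(w), mu_b, sig_b, mu_a, sig_a)
      if (!is.null(w_dr)) w_dr[ki, ] <- w
      if (!is.null(b_dr)) b_dr[ki, , 1] <- b
      if (!is.null(a_dr)) a_dr[ki, , 1] <- a
    }
  }

  if (sig_draws > 0 && sig_hits / sig_draws > 0.01) {
    warning(sprintf(
      "hyper-sd at the upper prior support bound in %.1f%% of draws; the",
      100 * sig_hits / sig_draws),
      " uniform prior constraint is active - consider a larger ",
      "sigma_support", call. = FALSE)
  }
  st_out <- list(w = w, z = mod$det_site * 1, omega = omega,
                 beta = matrix(b, M, 1), alpha = matrix(a, M, 1),
                 mu_b = mu_b, sig_b = sig_b, mu_a = mu_a, sig_a = sig_a,
                 scl_b = matrix(scl_b, M, 1), scl_a = matrix(scl_a, M, 1),
                 rng = get(".Random.seed", envir = .GlobalEnv))
  list(pars = pars, w = w_dr, z = NULL, beta = b_dr, alpha = a_dr,
       state = st_out)
}

# Model constants shared by all chains.
build_model <- function(data, occ_terms, det_terms, fixed) {
  S <- data$S; J <- data$J; M <- data$M
  yf <- matrix(as.numeric(data$y), S * J, M)      # rows: site fastest
  maskf <- as.numeric(data$mask)                  # length S*J
  yf <- yf * maskf
  site_index <- rep(seq_len(S), times = J)
  det_site <- rowsum(yf, site_index) > 0          # S x M
  det_k <- colSums(det_site) > 0
  if (data$n_observed < M && any(det_k[(data$n_observed + 1):M])) {
    stop("augmented pseudo-species must have all-zero histories",
         call. = FALSE)
  }
  X <- matrix(1, S, 1, dimnames = list(NULL, "int"))
  if (!is.null(occ_terms)) {
    sc <- data$site_covariates
    if (is.null(sc) || !all(occ_terms %in% colnames(sc))) {
      stop("occ_terms must name columns of site_covariates", call. = FALSE)
    }
    X <- cbind(X, as.matrix(sc[, occ_terms, drop = FALSE]))
  }
  V <- matrix(1, S * J, 1, dimnames = list(NULL, "int"))
  if (!is.null(det_terms)) {
    vc <- data$visit_covariates
    if (is.null(vc) || !all(det_terms %in% dimnames(vc)[[3]])) {
      stop("det_terms must name slices of visit_covariates", call. = FALSE)
    }
    V <- cbind(V, matrix(vc[, , det_terms, drop = FALSE], S * J,
                         length(det_terms),
                         dimnames = list(NULL, det_terms)))
  }
  fx <- NULL
  if (!is.null(fixed)) {
    psi <- fixed$psi
    if (is.matrix(psi)) psi <- matrix(psi, S, M) else
      psi <- matrix(rep(psi, length.out = M), S, M, byrow = TRUE)
    p <- fixed$p
    if (is.matrix(p)) p <- matrix(p, S * J, M) else
      p <- matrix(rep(p, length.out = M), S * J, M, byrow = TRUE)
    fx <- list(eta_occ = qlogis(psi), eta_det = qlogis(p))
  }
  list(S = S, J = J, M = M, n_obs = data$n_observed,
       yf = yf, maskf = maskf, site_index = site_index,
       det_site = det_site, det_k = det_k, X = X, V = V, fixed = fx)
}

init_state <- function(mod) {
  S <- mod$S; M <- mod$M
  w <- as.numeric(mod$det_k)
  z <- mod$det_site * 1           # initialize presence to the detections
  omega <- (sum(w) + 1) / (M + 2)
  st <- list(w = w, z = z, omega = omega)
  if (is.null(mod$fixed)) {
    P <- ncol(mod$X); Q <- ncol(mod$V)
    ndet <- colSums(mod$det_site)
    beta <- matrix(0, M, P)
    beta[, 1] <- qlogis((ndet + 0.5) / (S + 1))
    nvis <- rowsum(mod$maskf, mod$site_index)[, 1]   # visits per site
    trials <- colSums(mod$det_site * nvis)
    dets <- colSums(mod$yf)
    alpha <- matrix(0, M, Q)
    alpha[, 1] <- qlogis(pmin(pmax((dets + 0.5) / (trials + 1), 0.02),
                              0.98))
    obs <- which(mod$det_k)
    st$beta <- beta
    st$alpha <- alpha
    st$mu_b <- c(if (length(obs)) mean(beta[obs, 1]) else 0, rep(0, P - 1))
    st$sig_b <- rep(1, P)
    st$mu_a <- c(if (length(obs)) mean(alpha[obs, 1]) else 0, rep(0, Q - 1))
    st$sig_a <- rep(1, Q)
    st$scl_b <- matrix(0.5, M, P)
    st$scl_a <- matrix(0.5, M, Q)
  }
  st
}

# One chain. Continues from `state`; does not seed the RNG itself.
run_chain <- function(mod, priors, st, n_iter, n_burn, thin, adapt,
                      adapt_batch, retain) {
  S <- mod$S; M <- mod$M
  fixed <- !is.null(mod$fixed)
  X <- mod$X; V <- mod$V
  P <- if (fixed) 0L else ncol(X)
  Q <- if (fixed) 0L else ncol(V)
  pa <- priors$omega_beta[1]; pb <- priors$omega_beta[2]
  mu_sd <- priors$mu_prior_sd; U <- priors$sigma_support
  yf <- mod$yf; maskf <- mod$maskf; si <- mod$site_index
  det_site <- mod$det_site; det_k <- mod$det_k
  und <- !det_k

  n_keep <- (n_iter - n_burn) %/% thin
  par_names <- c("omega", "N")
  if (!fixed) {
    par_names <- c(par_names,
                   paste0("mu_beta_", colnames(X)),
                   paste0("sigma_beta_", colnames(X)),
                   paste0("mu_alpha_", colnames(V)),
                   paste0("sigma_alpha_", colnames(V)))
  }
  pars <- matrix(NA_real_, n_keep, length(par_names),
                 dimnames = list(NULL, par_names))
  w_dr <- if ("w" %in% retain) matrix(NA_integer_, n_keep, M)
  z_dr <- if ("z" %in% retain) array(NA_integer_, c(n_keep, S, M))
  b_dr <- if ("species" %in% retain && !fixed) array(NA_real_,
                                                     c(n_keep, M, P))
  a_dr <- if ("species" %in% retain && !fixed) array(NA_real_,
                                                     c(n_keep, M, Q))

  w <- st$w; z <- st$z; omega <- st$omega
  if (!fixed) {
    beta <- st$beta; alpha <- st$alpha
    mu_b <- st$mu_b; sig_b <- st$sig_b
    mu_a <- st$mu_a; sig_a <- st$sig_a
    scl_b <- st$scl_b; scl_a <- st$scl_a
    eta_occ <- X %*% t(beta)
    eta_det <- V %*% t(alpha)
    acc_b <- matrix(0, M, P); acc_a <- matrix(0, M, Q)
    att_b <- numeric(M); att_a <- numeric(M)
    sig_hits <- 0L; sig_draws <- 0L; n_nonfinite <- 0L
  } else {
    eta_occ <- mod$fixed$eta_occ
    eta_det <- mod$fixed$eta_det
  }

  ki <- 0L
  for (it in seq_len(n_iter)) {
    psi <- plogis(eta_occ)
    l1mp <- -log1pexp(eta_det) * maskf
    lq0 <- rowsum(l1mp, si)                       # S x M: log P(no det | z=1)

    # -- w, collapsed over z, for species with no detections
    if (any(und)) {
      lw1 <- colSums(log1p(-psi * (1 - exp(lq0))))
      pw1 <- plogis(qlogis(omega) + lw1)
      w[und] <- as.numeric(runif(sum(und)) < pw1[und])
    }

    # -- z | w
    pz <- plogis(eta_occ + lq0)
    z <- (matrix(runif(S * M), S, M) < pz) * 1
    z[det_site] <- 1
    z[, w == 0] <- 0

    # -- Omega
    omega <- rbeta(1, pa + sum(w), pb + M - sum(w))

    if (!fixed) {
      wl <- w == 1
      # -- occupancy effects: MH for members, prior draw for non-members
      ll_occ_old <- colSums(z * eta_occ - log1pexp(eta_occ))
      for (cc in seq_len(P)) {
        old <- beta[, cc]
        prop <- old + scl_b[, cc] * rnorm(M)
        eta_new <- eta_occ + outer(X[, cc], prop - old)
        ll_new <- colSums(z * eta_new - log1pexp(eta_new))
        llr <- ll_new - ll_occ_old +
          dnorm(prop, mu_b[cc], sig_b[cc], log = TRUE) -
          dnorm(old, mu_b[cc], sig_b[cc], log = TRUE)
        bad <- is.nan(llr)
        if (any(bad)) { n_nonfinite <- n_nonfinite + sum(bad); llr[bad] <- -Inf }
        acc <- wl & (log(runif(M)) < llr)
        newcol <- old
        newcol[acc] <- prop[acc]
        newcol[!wl] <- rnorm(sum(!wl), mu_b[cc], sig_b[cc])
        beta[, cc] <- newcol
        eta_occ <- eta_occ + outer(X[, cc], newcol - old)
        if (cc < P) ll_occ_old <- colSums(z * eta_occ - log1pexp(eta_occ))
        acc_b[, cc] <- acc_b[, cc] + acc
      }
      att_b <- att_b + wl

      # -- detection effects: MH for species with occupied sites
      occ_any <- colSums(z) > 0
      wgt <- z[si, , drop = FALSE] * maskf
      ll_det_old <- colSums(wgt * (yf * eta_det - log1pexp(eta_det)))
      for (cc in seq_len(Q)) {
        old <- alpha[, cc]
        prop <- old + scl_a[, cc] * rnorm(M)
        eta_new <- eta_det + outer(V[, cc], prop - old)
        ll_new <- colSums(wgt * (yf * eta_new - log1pexp(eta_new)))
        llr <- ll_new - ll_det_old +
          dnorm(prop, mu_a[cc], sig_a[cc], log = TRUE) -
          dnorm(old, mu_a[cc], sig_a[cc], log = TRUE)
        bad <- is.nan(llr)
        if (any(bad)) { n_nonfinite <- n_nonfinite + sum(bad); llr[bad] <- -Inf }
        acc <- occ_any & (log(runif(M)) < llr)
        newcol <- old
        newcol[acc] <- prop[acc]
        newcol[!occ_any] <- rnorm(sum(!occ_any), mu_a[cc], sig_a[cc])
        alpha[, cc] <- newcol
        eta_det <- eta_det + outer(V[, cc], newcol - old)
        if (cc < Q) {
          ll_det_old <- colSums(wgt * (yf * eta_det - log1pexp(eta_det)))
        }
        acc_a[, cc] <- acc_a[, cc] + acc
      }
      att_a <- att_a + occ_any

      # -- hyperparameters: conjugate mu, slice-sampled sigma
      for (cc in seq_len(P)) {
        e <- beta[, cc]
        prec <- M / sig_b[cc]^2 + 1 / mu_sd^2
        mu_b[cc] <- rnorm(1, (sum(e) / sig_b[cc]^2) / prec, sqrt(1 / prec))
        sig_b[cc] <- slice_sigma(e, mu_b[cc], sig_b[cc], U)
      }
      for (cc in seq_len(Q)) {
        e <- alpha[, cc]
        prec <- M / sig_a[cc]^2 + 1 / mu_sd^2
        mu_a[cc] <- rnorm(1, (sum(e) / sig_a[cc]^2) / prec, sqrt(1 / prec))
        sig_a[cc] <- slice_sigma(e, mu_a[cc], sig_a[cc], U)
      }
      sig_draws <- sig_draws + P + Q
      sig_hits <- sig_hits + sum(sig_b > 0.99 * U) + sum(sig_a > 0.99 * U)

      # -- proposal-scale adaptation, burn-in only
      if (adapt && it <= n_burn && it %% adapt_batch == 0) {
        rate_b <- acc_b / pmax(att_b, 1)
        scl_b <- pmin(pmax(scl_b * exp(pmin(pmax(rate_b - 0.3, -0.25),
                                            0.25)), 1e-3), 50)
        rate_a <- acc_a / pmax(att_a, 1)
        scl_a <- pmin(pmax(scl_a * exp(pmin(pmax(rate_a - 0.3, -0.25),
                                            0.25)), 1e-3), 50)
        acc_b[] <- 0; acc_a[] <- 0; att_b[] <- 0; att_a[] <- 0
      }
    }

    if (it > n_burn && (it - n_burn) %% thin == 0) {
      ki <- ki + 1L
      row <- c(omega, sum(w))
      if (!fixed) row <- c(row, mu_b, sig_b, mu_a, sig_a)
      pars[ki, ] <- row
      if (!is.null(w_dr)) w_dr[ki, ] <- w
      if (!is.null(z_dr)) z_dr[ki, , ] <- z
      if (!is.null(b_dr)) b_dr[ki, , ] <- beta
      if (!is.null(a_dr)) a_dr[ki, , ] <- alpha
    }
  }

  st_out <- list(w = w, z = z, omega = omega)
  if (!fixed) {
    if (n_nonfinite > 0) {
      warning(n_nonfinite,
              " non-finite log-posterior proposals were rejected",
              call. = FALSE)
    }
    if (sig_draws > 0 && sig_hits / sig_draws > 0.01) {
      warning(sprintf(
        "hyper-sd at the upper prior support bound in %.1f%% of draws; the",
        100 * sig_hits / sig_draws),
        " uniform prior constraint is active - consider a larger ",
        "sigma_support", call. = FALSE)
    }
    st_out <- c(st_out, list(beta = beta, alpha = alpha, mu_b = mu_b,
                             sig_b = sig_b, mu_a = mu_a, sig_a = sig_a,
                             scl_b = scl_b, scl_a = scl_a))
  }
  st_out$rng <- get(".Random.seed", envir = .GlobalEnv)
  list(pars = pars, w = w_dr, z = z_dr, beta = b_dr, alpha = a_dr,
       state = st_out)
}

#' Fit the augmented multispecies occupancy-detection model
#'
#' Metropolis-within-Gibbs sampler for the data-augmented community model.
#' Per sweep: (1) community-membership indicators w of undetected species
#' are updated with their presence states z marginalized out (see
#' [cond_prob_w()]); (2) z is refreshed given w; (3) Omega by conjugate
#' Beta Gibbs; (4) per-species occupancy and detection coefficients by
#' adaptive random-walk Metropolis for community members (non-members are
#' resampled from the hyperdistribution, their exact conditional, which
#' keeps the hyperparameter update valid over all M species); (5)
#' hyper-means by normal-normal conjugate Gibbs and hyper-sds by shrinkage
#' slice sampling under their uniform prior. Latent states are initialized
#' at the observed detections with all augmented species excluded (w = 0).
#'
#' After the first run, convergence is checked with [gelman_rubin()]
#' (threshold 1.1) on all retained scalar parameters; if needed, additional
#' blocks are drawn (earlier draws discarded as burn-in) up to
#' \code{config$max_extra_blocks}, after which a still-unconverged fit is
#' returned flagged (\code{converged = FALSE}) with a warning.
#'
#' @param data an [occ_data()], normally after [augment()].
#' @param priors an [occ_priors()], default [prior_set()] "set3".
#' @param config an [mcmc_config()].
#' @param occ_terms,det_terms optional covariate names (columns of
#'   \code{data$site_covariates} / slices of \code{data$visit_covariates})
#'   entering the occupancy and detection logit-linear predictors; an
#'   intercept is always included and every coefficient carries a normal
#'   species random effect.
#' @param fixed optional list with \code{psi} and \code{p} (scalar, length-M
#'   vector, or full matrix): fixes the species parameters and samples only
#'   w, z and Omega — used for exact validation against enumeration on tiny
#'   instances.
#' @return object of class \code{occ_fit}.
#' @export
run_mcmc <- function(data, priors = prior_set("set3"),
                     config = mcmc_config(), occ_terms = NULL,
                     det_terms = NULL, fixed = NULL) {
  stopifnot(inherits(data, "occ_data"), inherits(priors, "occ_priors"),
            inherits(config, "occ_mcmc_config"))
  mod <- build_model(data, occ_terms, det_terms, fixed)
  fast <- is.null(fixed) && ncol(mod$X) == 1 && ncol(mod$V) == 1 &&
    all(mod$maskf == 1) && !("z" %in% config$retain)
  runner <- if (fast) run_chain_fast else run_chain
  nc <- config$n_chains
  res <- vector("list", nc)
  for (ch in seq_len(nc)) {
    set.seed(config$seed + ch)
    st <- init_state(mod)
    res[[ch]] <- runner(mod, priors, st, config$n_iter, config$n_burn,
                        config$thin, config$adapt, config$adapt_batch,
                        config$retain)
  }
  rhat <- chain_rhat(res)
  blocks <- 1L
  while (!converged_rhat(rhat) && blocks <= config$max_extra_blocks) {
    block_len <- config$n_iter - config$n_burn
    for (ch in seq_len(nc)) {
      assign(".Random.seed", res[[ch]]$state$rng, envir = .GlobalEnv)
      res[[ch]] <- runner(mod, priors, res[[ch]]$state, block_len, 0L,
                          config$thin, FALSE, config$adapt_batch,
                          config$retain)
    }
    rhat <- chain_rhat(res)
    blocks <- blocks + 1L
  }
  converged <- converged_rhat(rhat)
  if (!converged) {
    warning("chains not converged (max Rhat = ",
            sprintf("%.3f", max(rhat[is.finite(rhat)], 1)),
            ") after ", blocks, " block(s); result is flagged",
            call. = FALSE)
  }
  fit <- structure(
    list(draws = list(pars = lapply(res, `[[`, "pars"),
                      w = if ("w" %in% config$retain)
                        lapply(res, `[[`, "w"),
                      z = if ("z" %in% config$retain)
                        lapply(res, `[[`, "z"),
                      beta = if ("species" %in% config$retain &&
                                 is.null(fixed))
                        lapply(res, `[[`, "beta"),
                      alpha = if ("species" %in% config$retain &&
                                  is.null(fixed))
                        lapply(res, `[[`, "alpha")),
         rhat = rhat, converged = converged, n_blocks = blocks,
         config = config, priors = priors,
         S = mod$S, J = mod$J, M = mod$M, n_observed = mod$n_obs,
         X = mod$X, V = mod$V),
    class = "occ_fit")
  fit
}

#' Posterior draws of community size N
#'
#' Pools the retained draws of N = sum(w) across chains.
#'
#' @param fit an \code{occ_fit}.
#' @return numeric vector of draws.
#' @export
n_draws <- function(fit) {
  unlist(lapply(fit$draws$pars, function(m) m[, "N"]), use.names = FALSE)
}

chain_rhat <- function(res) {
  pn <- colnames(res[[1]]$pars)
  vapply(pn, function(p) {
    gelman_rubin(sapply(res, function(r) r$pars[, p]))
  }, numeric(1))
}

# NaN (all chains constant and equal) counts as converged: the posterior is
# degenerate for that quantity. Inf (chains stuck at different constants)
# does not.
converged_rhat <- function(rhat) {
  r <- rhat[!is.nan(rhat)]
  length(r) == 0 || all(r < 1.1)
}

#' @export
print.occ_fit <- function(x, ...) {
  cat(sprintf(
    "Multispecies occupancy fit: S = %d, J = %d, %d observed + %d augmented (M = %d)\n",
    x$S, x$J, x$n_observed, x$M - x$n_observed, x$M))
  cat(sprintf("  %d chains x %d kept draws; priors %s; %sconverged (max Rhat %.3f, %d block%s)\n",
              length(x$draws$pars), nrow(x$draws$pars[[1]]),
              x$priors$label, if (x$converged) "" else "NOT ",
              max(x$rhat[is.finite(x$rhat)], 1), x$n_blocks,
              if (x$n_blocks > 1) "s" else ""))
  print(richness_summary(x))
  invisible(x)
}

#' @export
summary.occ_fit <- function(object, ...) {
  pn <- colnames(object$draws$pars[[1]])
  pooled <- do.call(rbind, object$draws$pars)
  tab <- t(vapply(pn, function(p) {
    d <- pooled[, p]
    c(mean = mean(d), sd = sd(d),
      `2.5%` = unname(quantile(d, 0.025)),
      `50%` = unname(quantile(d, 0.5)),
      `97.5%` = unname(quantile(d, 0.975)),
      Rhat = unname(object$rhat[p]))
  }, numeric(6)))
  tab
}
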