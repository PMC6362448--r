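#' Cumulative detection probability over repeat visits
#'
#' Probability of at least one detection at an occupied site over J visits
#' with per-visit detection probability p: \code{p* = 1 - (1 - p)^J}.
#'
#' @param p per-visit detection probability, in \[0, 1\] (vectorized).
#' @param J number of visits, >= 1.
#' @return probability in \[0, 1\], nondecreasing in both arguments.
#' @export
cumulative_detection <- function(p, J) {
  stopifnot(all(p >= 0 & p <= 1), all(J >= 1))
  1 - (1 - p)^J
}

#' Probability that a species is completely missed
#'
#' Probability of not a single detection of a species over J visits at each
#' of S sites, with constant occupancy probability psi and per-visit
#' detection probability p:
#' \code{m = (1 - psi * (1 - (1 - p)^J))^S}. Each site independently either
#' is unoccupied, or is occupied and yields no detection across its J
#' visits.
#'
#' @param psi,p occupancy and per-visit detection probabilities (vectorized).
#' @param S,J number of sites and visits.
#' @return probability in \[0, 1\], nonincreasing in each argument.
#' @export
#' @examples
#' prob_missed(0.5, 0.5, S = 2, J = 1)  # 0.5625
prob_missed <- function(psi, p, S, J) {
  stopifnot(all(psi >= 0 & psi <= 1), all(p >= 0 & p <= 1),
            all(S >= 1), all(J >= 1))
  (1 - psi * cumulative_detection(p, J))^S
}

# Draw (psi, p) for a scenario, optionally with antithetic pairing of the
# underlying normals. Returns list(psi, p, pairs): when pairs is TRUE the
# first half and second half are antithetic mates.
draw_mc_sample <- function(spec, n_mc, antithetic) {
  anti <- antithetic && spec$det_family == "logit-normal"
  if (anti) {
    nh <- ceiling(n_mc / 2)
    zo <- rnorm(nh); zd <- rnorm(nh)
    psi <- plogis(clamp_logit(spec$occ_mu + spec$occ_sigma * c(zo, -zo)))
    p <- plogis(clamp_logit(spec$det_params$mean +
                              spec$det_params$sd * c(zd, -zd)))
    list(psi = psi, p = p, pairs = TRUE, nh = nh)
  } else {
    psi <- plogis(clamp_logit(rnorm(n_mc, spec$occ_mu, spec$occ_sigma)))
    p <- draw_detectability(spec$det_family, spec$det_params, n_mc)
    list(psi = psi, p = p, pairs = FALSE, nh = n_mc)
  }
}

mc_mean_se <- function(m, sample) {
  if (sample$pairs) {
    pm <- (m[seq_len(sample$nh)] + m[sample$nh + seq_len(sample$nh)]) / 2
    structure(mean(pm), se = sd(pm) / sqrt(sample$nh))
  } else {
    structure(mean(m), se = sd(m) / sqrt(length(m)))
  }
}

#' Expected fraction of species completely missed under a scenario
#'
#' Monte-Carlo mean of [prob_missed()] over the scenario's species-parameter
#' distributions: the expected proportion of the community that yields no
#' detection at any of the S sites over J visits. For ideal (logit-normal
#' detectability) scenarios, antithetic variates are used by default: the
#' integrand is monotone in both underlying normals, so pairing each draw
#' with its sign-flipped mate substantially reduces Monte-Carlo variance at
#' no extra cost.
#'
#' @param spec an [occ_scenario()]; \code{spec$S}, \code{spec$J} define the
#'   design.
#' @param n_mc number of Monte-Carlo species draws (values below 1e4 trigger
#'   a warning: integer-percent rounding becomes unreliable).
#' @param seed optional seed.
#' @param antithetic use antithetic variates where applicable (logit-normal
#'   detectability), default TRUE.
#' @return the Monte-Carlo proportion, with the standard error in attribute
#'   \code{"se"}.
#' @export
expected_missed_fraction <- function(spec, n_mc = 1e6, seed = NULL,
                                     antithetic = TRUE) {
  stopifnot(inherits(spec, "occ_scenario"))
  if (n_mc < 1e4) {
    warning("n_mc < 1e4: Monte-Carlo error too large for reliable ",
            "integer-percent rounding", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  s <- draw_mc_sample(spec, n_mc, antithetic)
  mc_mean_se(prob_missed(s$psi, s$p, spec$S, spec$J), s)
}

#' Expected fraction of species absent from all sampled sites
#'
#' Monte-Carlo mean of \code{(1 - psi)^S} over the occupancy distribution:
#' the expected proportion of community species not present in any of the S
#' sampled sites (independent of J). These are species that no amount of
#' survey effort at the sampled sites could reveal.
#'
#' @inheritParams expected_missed_fraction
#' @return proportion with standard-error attribute \code{"se"}.
#' @export
expected_absent_fraction <- function(spec, n_mc = 1e6, seed = NULL,
                                     antithetic = TRUE) {
  stopifnot(inherits(spec, "occ_scenario"))
  if (n_mc < 1e4) {
    warning("n_mc < 1e4: Monte-Carlo error too large for reliable ",
            "integer-percent rounding", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (antithetic) {
    nh <- ceiling(n_mc / 2)
    z <- rnorm(nh)
    psi <- plogis(clamp_logit(spec$occ_mu + spec$occ_sigma * c(z, -z)))
    s <- list(pairs = TRUE, nh = nh)
  } else {
    psi <- plogis(clamp_logit(rnorm(n_mc, spec$occ_mu, spec$occ_sigma)))
    s <- list(pairs = FALSE, nh = n_mc)
  }
  mc_mean_se((1 - psi)^spec$S, s)
}

#' Expected missed/absent fractions over a design grid
#'
#' Computes the expected proportion of species completely missed, and the
#' proportion absent from all sampled sites, for each combination of
#' occupancy regime, number of sites S and number of visits J — the summary
#' table that frames the simulation study. Within an occupancy regime a
#' single Monte-Carlo species sample is reused across all (S, J) cells
#' (common random numbers), so differences between cells are not blurred by
#' sampling noise.
#'
#' @param scenarios named list of [occ_scenario()] objects supplying the
#'   occupancy regimes and detectability (their own S, J are ignored);
#'   default the two standard regimes.
#' @param S,J design grids.
#' @param n_mc,seed,antithetic Monte-Carlo controls, see
#'   [expected_missed_fraction()].
#' @return data.frame with columns scenario, S, J, missed, absent (raw
#'   proportions), missed_pct, absent_pct (integer percent, rounded half
#'   away from zero, as such tables are conventionally printed).
#' @export
table1_grid <- function(scenarios = list(Occ1 = occ_scenario_ideal("Occ1"),
                                         Occ2 = occ_scenario_ideal("Occ2")),
                        S = c(25, 50, 150), J = c(2, 4, 6),
                        n_mc = 1e6, seed = NULL, antithetic = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (nm in names(scenarios)) {
    sp <- scenarios[[nm]]
    smp <- draw_mc_sample(sp, n_mc, antithetic)
    for (s in S) {
      abs_frac <- mc_mean_se((1 - smp$psi)^s, smp)
      for (j in J) {
        mis <- mc_mean_se(prob_missed(smp$psi, smp$p, s, j), smp)
        out[[length(out) + 1]] <- data.frame(
          scenario = nm, S = s, J = j,
          missed = as.numeric(mis), absent = as.numeric(abs_frac),
          missed_pct = round_half_up(100 * as.numeric(mis)),
          absent_pct = round_half_up(100 * as.numeric(abs_frac)))
      }
    }
  }
  do.call(rbind, out)
}

#' Posterior summary of community richness N
#'
#' Summarizes the posterior draws of N = sum(w): lower median (smallest
#' value whose cumulative posterior mass reaches 0.5 — a deterministic
#' tie-break for a discrete quantity) and the equal-tailed 95% credible
#' interval (2.5% and 97.5% type-1 quantiles). Since every retained draw
#' satisfies N >= number of observed species, the interval lower bound does
#' too.
#'
#' @param x an \code{occ_fit} from [run_mcmc()], or a numeric vector of N
#'   draws.
#' @param ... passed to methods; for the numeric method, \code{M} and
#'   \code{n_detected} may be supplied for bookkeeping.
#' @return object of class \code{richness_summary}: list with
#'   \code{median}, \code{ci_low}, \code{ci_high}, \code{n_detected},
#'   \code{augmentation_ok}, \code{rhat_max}.
#' @export
richness_summary <- function(x, ...) UseMethod("richness_summary")

#' @rdname richness_summary
#' @export
richness_summary.occ_fit <- function(x, ...) {
  N <- n_draws(x)
  adequacy <- augmentation_adequate(N, x$M)
  summ_N(N, n_detected = x$n_observed,
         augmentation_ok = adequacy$adequate,
         rhat_max = max(x$rhat, na.rm = TRUE))
}

#' @rdname richness_summary
#' @param M,n_detected bookkeeping for the numeric method.
#' @export
richness_summary.numeric <- function(x, M = NULL, n_detected = NA_integer_,
                                     ...) {
  ok <- if (is.null(M)) NA else augmentation_adequate(x, M)$adequate
  summ_N(x, n_detected = n_detected, augmentation_ok = ok,
         rhat_max = NA_real_)
}

summ_N <- function(N, n_detected, augmentation_ok, rhat_max) {
  q <- unname(quantile(N, c(0.025, 0.5, 0.975), type = 1))
  structure(list(median = q[2], ci_low = q[1], ci_high = q[3],
                 n_detected = n_detected,
                 augmentation_ok = augmentation_ok,
                 rhat_max = rhat_max),
            class = "richness_summary")
}

#' @export
print.richness_summary <- function(x, ...) {
  cat(sprintf("N: median %g, 95%% CI [%g, %g] (%s detected)\n",
              x$median, x$ci_low, x$ci_high,
              ifelse(is.na(x$n_detected), "?", x$n_detected)))
  if (isFALSE(x$augmentation_ok)) {
    cat("  warning: posterior presses against the augmentation ceiling M\n")
  }
  if (is.finite(x$rhat_max) && x$rhat_max >= 1.1) {
    cat(sprintf("  warning: max Rhat = %.3f (>= 1.1)\n", x$rhat_max))
  }
  invisible(x)
}

#' Per-site richness summaries from a fitted model
#'
#' Two site-level richness predictions: \code{"expected"} sums
#' \code{w_k * psi_ik} over species within each retained draw (the expected
#' number of community species present at the site), and
#' \code{"conditional"} sums the latent presence indicators \code{z_ik}
#' (richness conditional on the observed data; species detected at a site
#' contribute exactly 1). Requires latent draws to have been retained, see
#' the \code{retain} argument of [mcmc_config()].
#'
#' @param fit an \code{occ_fit}.
#' @param mode \code{"expected"} or \code{"conditional"}.
#' @return data.frame with one row per site: posterior mean, median and
#'   equal-tailed 95% interval of site richness.
#' @export
site_richness <- function(fit, mode = c("expected", "conditional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "occ_fit"))
  if (mode == "conditional") {
    z <- fit$draws$z
    if (is.null(z)) {
      stop("conditional site richness needs retained z draws; refit with ",
           "mcmc_config(retain = \"z\")", call. = FALSE)
    }
    # z: list per chain of kept x S x M arrays
    Ni <- do.call(rbind, lapply(z, function(a) {
      apply(a, c(1, 2), sum)  # kept x S
    }))
  } else {
    w <- fit$draws$w; beta <- fit$draws$beta
    if (is.null(w) || is.null(beta)) {
      stop("expected site richness needs retained w and species-effect ",
           "draws; refit with mcmc_config(retain = c(\"w\", \"species\"))",
           call. = FALSE)
    }
    X <- fit$X
    Ni <- do.call(rbind, lapply(seq_along(w), function(ch) {
      nk <- nrow(w[[ch]])
      t(vapply(seq_len(nk), function(d) {
        psi <- plogis(X %*% t(beta[[ch]][d, , , drop = TRUE]))  # S x M
        as.numeric(psi %*% w[[ch]][d, ])
      }, numeric(fit$S)))
    }))
  }
  data.frame(site = seq_len(fit$S),
             mean = colMeans(Ni),
             median = apply(Ni, 2, median),
             ci_low = apply(Ni, 2, quantile, 0.025),
             ci_high = apply(Ni, 2, quantile, 0.975))
}

#' Posterior richness of a region defined by a site subset
#'
#' For each retained draw, counts the species with at least one latent
#' presence indicator z = 1 among the given sites — the number of species
#' estimated to occur somewhere in the region spanned by that site set.
#' With all sampled sites, this is bounded above by the community size
#' N = sum(w) of the same draw (community members need not be present at any
#' sampled site).
#'
#' @param fit an \code{occ_fit} with retained z draws.
#' @param sites integer vector of site indices (non-empty).
#' @return list with \code{draws} (per-draw counts) and \code{summary} (a
#'   [richness_summary()]).
#' @export
region_richness <- function(fit, sites) {
  stopifnot(inherits(fit, "occ_fit"))
  if (length(sites) == 0) stop("empty site subset", call. = FALSE)
  if (any(sites < 1 | sites > fit$S)) stop("site index out of range",
                                           call. = FALSE)
  z <- fit$draws$z
  if (is.null(z)) {
    stop("region richness needs retained z draws; refit with ",
         "mcmc_config(retain = \"z\")", call. = FALSE)
  }
  counts <- unlist(lapply(z, function(a) {
    sub <- a[, sites, , drop = FALSE]
    apply(sub, 1, function(m) sum(colSums(matrix(m, ncol = dim(a)[3])) > 0))
  }))
  list(draws = counts,
       summary = richness_summary(as.numeric(counts), M = fit$M,
                                  n_detected = fit$n_observed))
}
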