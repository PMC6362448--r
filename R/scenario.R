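#' Scenario specification for community simulation
#'
#' Describes the generative process for a simulated community and its
#' sampling: the number of species in the community, the logit-scale
#' hyperparameters of the occupancy random effect, the family and parameters
#' of the species detectability distribution, and the survey design (S sites,
#' J visits per site).
#'
#' Occupancy probabilities are always drawn as
#' \code{psi_k = plogis(rnorm(., occ_mu, occ_sigma))}. Detection
#' probabilities are drawn from one of five families on the logit scale (see
#' [draw_detectability()]); \code{"logit-normal"} is the ideal scenario the
#' fitted model assumes, the others deliberately violate it.
#'
#' @param n_species true community size (the quantity the model estimates).
#' @param occ_mu,occ_sigma mean and standard deviation of the logit-scale
#'   occupancy random effect; \code{occ_sigma >= 0} (zero gives a point
#'   mass).
#' @param det_family one of \code{"logit-normal"}, \code{"mixture"},
#'   \code{"heavy-tail"}, \code{"steep-tail"}, \code{"skewed"}.
#' @param det_params named list of family parameters, see
#'   [draw_detectability()].
#' @param S,J number of sampled sites and of survey visits per site.
#' @param seed optional integer seed attached to the scenario.
#' @param id optional scenario label used in results tables.
#' @return an object of class \code{occ_scenario}.
#' @seealso [occ_scenario_ideal()] for the two standard occupancy regimes,
#'   [det_violation()] for the alternative detectability catalogue.
#' @export
#' @examples
#' sp <- occ_scenario_ideal("Occ1", S = 25, J = 2)
#' pars <- draw_species_params(sp, seed = 1)
#' mean(pars$psi)
occ_scenario <- function(n_species = 100, occ_mu = -1, occ_sigma = 0.3,
                         det_family = "logit-normal",
                         det_params = list(mean = -2, sd = 1),
                         S = 25, J = 2, seed = NULL, id = NULL) {
  stop_if_not_scalar_count(n_species, "n_species")
  stop_if_not_scalar_count(S, "S")
  stop_if_not_scalar_count(J, "J")
  if (!is.numeric(occ_sigma) || occ_sigma < 0) {
    stop("`occ_sigma` must be >= 0", call. = FALSE)
  }
  check_det_params(det_family, det_params)
  structure(
    list(n_species = as.integer(n_species), occ_mu = occ_mu,
         occ_sigma = occ_sigma, det_family = det_family,
         det_params = det_params, S = as.integer(S), J = as.integer(J),
         seed = seed, id = id %||% det_family),
    class = "occ_scenario")
}

#' @export
print.occ_scenario <- function(x, ...) {
  cat("Community scenario '", x$id, "'\n", sep = "")
  cat(sprintf("  %d species; logit(psi) ~ N(%g, %g)\n",
              x$n_species, x$occ_mu, x$occ_sigma))
  cat(sprintf("  detectability: %s (%s)\n", x$det_family,
              paste(names(x$det_params), unlist(lapply(x$det_params, paste,
                    collapse = ",")), sep = "=", collapse = "; ")))
  cat(sprintf("  design: S = %d sites, J = %d visits\n", x$S, x$J))
  invisible(x)
}

#' Standard occupancy regimes
#'
#' The two stock occupancy scenarios used throughout the simulation study:
#' \code{"Occ1"} has \code{logit(psi) ~ N(-1, 0.3)} (mean occupancy 0.27),
#' \code{"Occ2"} has \code{logit(psi) ~ N(-2, 0.6)} (mean occupancy 0.13).
#' Both use the ideal logit-normal detectability \code{logit(p) ~ N(-2, 1)}
#' (mean single-visit detection probability 0.15) unless overridden.
#'
#' @param occ \code{"Occ1"} or \code{"Occ2"}.
#' @param S,J,n_species,seed passed to [occ_scenario()].
#' @param det_family,det_params detectability override, default ideal.
#' @return an \code{occ_scenario}.
#' @export
occ_scenario_ideal <- function(occ = c("Occ1", "Occ2"), S = 25, J = 2,
                               n_species = 100, seed = NULL,
                               det_family = "logit-normal",
                               det_params = list(mean = -2, sd = 1)) {
  occ <- match.arg(occ)
  hp <- switch(occ, Occ1 = c(-1, 0.3), Occ2 = c(-2, 0.6))
  occ_scenario(n_species = n_species, occ_mu = hp[1], occ_sigma = hp[2],
               det_family = det_family, det_params = det_params,
               S = S, J = J, seed = seed, id = occ)
}

det_families <- c("logit-normal", "mixture", "heavy-tail", "steep-tail",
                  "skewed")

check_det_params <- function(family, params) {
  if (!family %in% det_families) {
    stop("unknown detectability family '", family, "'; must be one of ",
         paste(det_families, collapse = ", "), call. = FALSE)
  }
  need <- function(nms) {
    miss <- setdiff(nms, names(params))
    if (length(miss)) {
      stop("det_params for family '", family, "' must include: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  switch(family,
    "logit-normal" = {
      need(c("mean", "sd"))
      if (params$sd < 0) stop("logit-normal sd must be >= 0", call. = FALSE)
    },
    "mixture" = {
      need(c("weights", "means", "sds"))
      w <- params$weights
      if (abs(sum(w) - 1) > 1e-8) {
        stop("mixture weights must sum to 1", call. = FALSE)
      }
      if (any(w < 0)) stop("mixture weights must be >= 0", call. = FALSE)
      if (length(params$means) != length(w) ||
          length(params$sds) != length(w)) {
        stop("mixture weights, means, sds must have equal length",
             call. = FALSE)
      }
      if (any(params$sds <= 0)) {
        stop("mixture component scales must be > 0", call. = FALSE)
      }
    },
    "heavy-tail" = {
      need(c("df", "location", "scale"))
      if (params$df <= 0 || params$scale <= 0) {
        stop("heavy-tail df and scale must be > 0", call. = FALSE)
      }
    },
    "steep-tail" = {
      need(c("mean", "sd", "lower", "upper"))
      if (params$sd <= 0) stop("steep-tail sd must be > 0", call. = FALSE)
      if (params$lower >= params$upper) {
        stop("steep-tail truncation bounds must satisfy lower < upper",
             call. = FALSE)
      }
    },
    "skewed" = {
      need(c("location", "scale", "shape"))
      if (params$scale <= 0) stop("skewed scale must be > 0", call. = FALSE)
    })
  invisible(TRUE)
}

#' Draw per-visit detection probabilities from a detectability family
#'
#' Samples species detection probabilities on the logit scale from one of
#' five distribution families. \code{"logit-normal"} is the distribution the
#' fitted model assumes for its detection random effect; the other four are
#' deliberate violations used to probe estimator robustness:
#' \describe{
#'   \item{mixture}{normal mixture on the logit scale
#'     (\code{weights}, \code{means}, \code{sds}); with one component it
#'     reduces exactly to the logit-normal. Bimodal detectability scenarios
#'     are expressed in this family, see [det_violation()].}
#'   \item{heavy-tail}{location-scale Student-t on the logit scale
#'     (\code{df}, \code{location}, \code{scale}): fatter tails than any
#'     normal.}
#'   \item{steep-tail}{normal truncated to \code{[lower, upper]} on the
#'     logit scale: steeper (bounded) tails.}
#'   \item{skewed}{skew-normal on the logit scale (\code{location},
#'     \code{scale}, \code{shape}), sampled through the half-normal
#'     representation \code{delta*|z0| + sqrt(1-delta^2)*z1} with
#'     \code{delta = shape/sqrt(1+shape^2)}.}
#' }
#' Logit draws are clamped to +/-36 so returned probabilities are strictly
#' inside (0, 1) in double precision.
#'
#' @param family family name, see above.
#' @param det_params named parameter list for the family.
#' @param n number of species to draw.
#' @param seed optional seed.
#' @return numeric vector of length \code{n}, strictly inside (0, 1).
#' @export
#' @examples
#' p <- draw_detectability("heavy-tail",
#'                         list(df = 3, location = -2, scale = 1), 1000, 1)
#' range(p)
draw_detectability <- function(family, det_params, n, seed = NULL) {
  check_det_params(family, det_params)
  if (!is.null(seed)) set.seed(seed)
  x <- switch(family,
    "logit-normal" = rnorm(n, det_params$mean, det_params$sd),
    "mixture" = {
      k <- sample.int(length(det_params$weights), n, replace = TRUE,
                      prob = det_params$weights)
      rnorm(n, det_params$means[k], det_params$sds[k])
    },
    "heavy-tail" = det_params$location + det_params$scale * rt(n, det_params$df),
    "steep-tail" = {
      lo <- pnorm(det_params$lower, det_params$mean, det_params$sd)
      hi <- pnorm(det_params$upper, det_params$mean, det_params$sd)
      qnorm(runif(n, lo, hi), det_params$mean, det_params$sd)
    },
    "skewed" = {
      delta <- det_params$shape / sqrt(1 + det_params$shape^2)
      z <- delta * abs(rnorm(n)) + sqrt(1 - delta^2) * rnorm(n)
      det_params$location + det_params$scale * z
    })
  plogis(clamp_logit(x))
}

#' Catalogue of detectability-assumption violations
#'
#' Default parameterizations for the five alternative detectability
#' distributions: Student-t ("heavy-tail"), truncated normal ("steep-tail"),
#' skew-normal ("skewed"), and two logit-scale normal mixtures —
#' \code{"bimodal-low"} (first mode near zero detection probability) and
#' \code{"bimodal-high"} (first mode away from zero, the shape that misleads
#' the fitted logit-normal model most strongly: the fitted normal places
#' substantial mass near p = 0 that the generating distribution does not
#' have, so the model infers many more missed species than there are).
#' Locations can be shifted to hit a target expected missed fraction with
#' [tune_det_location()].
#'
#' @param name violation name.
#' @return list with elements \code{det_family} and \code{det_params},
#'   suitable for splicing into [occ_scenario()].
#' @export
det_violation <- function(name = c("heavy-tail", "steep-tail", "skewed",
                                   "bimodal-low", "bimodal-high")) {
  name <- match.arg(name)
  switch(name,
    "heavy-tail" = list(det_family = "heavy-tail",
                        det_params = list(df = 3, location = -2, scale = 1)),
    "steep-tail" = list(det_family = "steep-tail",
                        det_params = list(mean = -2, sd = 2,
                                          lower = -4, upper = 0)),
    "skewed" = list(det_family = "skewed",
                    det_params = list(location = -3, scale = 1.5, shape = 4)),
    "bimodal-low" = list(det_family = "mixture",
                         det_params = list(weights = c(0.6, 0.4),
                                           means = c(-3.5, -0.5),
                                           sds = c(0.5, 0.5))),
    "bimodal-high" = list(det_family = "mixture",
                          det_params = list(weights = c(0.5, 0.5),
                                            means = c(-1.4, 0.4),
                                            sds = c(0.35, 0.35))))
}

#' Shift a detectability distribution to hit a target missed fraction
#'
#' Adds a common offset to the location parameter(s) of the scenario's
#' detectability distribution, chosen by root finding so that the expected
#' fraction of species completely missed by the scenario's survey design
#' (see [expected_missed_fraction()]) equals \code{target}. This is how
#' violation scenarios are calibrated to a chosen difficulty (e.g. ~2% or
#' ~9% of species missed at S = 25) so that ideal and violating scenarios
#' are compared at matched information content.
#'
#' @param spec an [occ_scenario()].
#' @param target target expected missed fraction, in (0, 1).
#' @param n_mc Monte-Carlo size per evaluation (a fixed internal seed makes
#'   the objective deterministic and monotone in the offset).
#' @param interval search interval for the logit-scale offset.
#' @return the scenario with shifted detectability locations; the fitted
#'   offset is attached as attribute \code{"offset"}.
#' @export
tune_det_location <- function(spec, target, n_mc = 2e5,
                              interval = c(-8, 8)) {
  stopifnot(inherits(spec, "occ_scenario"), target > 0, target < 1)
  shift <- function(delta) {
    sp <- spec
    sp$det_params <- shift_location(sp$det_family, sp$det_params, delta)
    sp
  }
  f <- function(delta) {
    as.numeric(expected_missed_fraction(shift(delta), n_mc = n_mc,
                                        seed = 20200101L)) - target
  }
  delta <- stats::uniroot(f, interval, tol = 1e-4)$root
  out <- shift(delta)
  attr(out, "offset") <- delta
  out
}

shift_location <- function(family, params, delta) {
  switch(family,
    "logit-normal" = { params$mean <- params$mean + delta; params },
    "mixture" = { params$means <- params$means + delta; params },
    "heavy-tail" = { params$location <- params$location + delta; params },
    "steep-tail" = {
      params$mean <- params$mean + delta
      params$lower <- params$lower + delta
      params$upper <- params$upper + delta
      params
    },
    "skewed" = { params$location <- params$location + delta; params })
}

#' Draw species-level occupancy and detection probabilities
#'
#' Realizes the community: per-species occupancy probabilities from the
#' logit-normal occupancy regime and per-visit detection probabilities from
#' the scenario's detectability family.
#'
#' @param spec an [occ_scenario()].
#' @param n number of species (defaults to \code{spec$n_species}).
#' @param seed optional seed (defaults to \code{spec$seed}).
#' @return an object of class \code{occ_truth}: list with numeric vectors
#'   \code{psi} and \code{p} (length \code{n}); the presence matrix fields
#'   are filled in by [simulate_detections()].
#' @export
draw_species_params <- function(spec, n = spec$n_species,
                                seed = spec$seed) {
  stopifnot(inherits(spec, "occ_scenario"))
  if (!is.null(seed)) set.seed(seed)
  psi <- plogis(clamp_logit(rnorm(n, spec$occ_mu, spec$occ_sigma)))
  p <- draw_detectability(spec$det_family, spec$det_params, n)
  structure(list(psi = psi, p = p, z_true = NULL,
                 present_in_sample = NULL, detected = NULL),
            class = "occ_truth")
}
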