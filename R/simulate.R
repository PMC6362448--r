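#' Detection/non-detection data container
#'
#' Holds a binary detection array \code{y[site, visit, species]} together
#' with a visit mask (FALSE marks visits that did not take place, supporting
#' unequal survey effort across sites) and optional covariate tables.
#' Augmentation bookkeeping (\code{n_observed}, \code{M}) is maintained by
#' [augment()].
#'
#' @param y binary array S x J x K (species detected then, after
#'   augmentation, all-zero pseudo-species).
#' @param mask logical S x J matrix, TRUE where the visit took place;
#'   default all TRUE. \code{y} must be 0 at masked-out visits.
#' @param species optional species labels (length K).
#' @param site_covariates optional data.frame with S rows.
#' @param visit_covariates optional numeric array S x J x V with covariate
#'   names on the third dimnames.
#' @return object of class \code{occ_data}.
#' @export
occ_data <- function(y, mask = NULL, species = NULL,
                     site_covariates = NULL, visit_covariates = NULL) {
  if (!is.array(y) || length(dim(y)) != 3) {
    stop("`y` must be a 3-d array (site x visit x species)", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) {
    stop("`y` must be binary (0/1)", call. = FALSE)
  }
  S <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  if (is.null(mask)) mask <- matrix(TRUE, S, J)
  mask <- matrix(as.logical(mask), S, J)
  if (any(y[rep(!mask, K)] != 0)) {
    stop("detections recorded at masked-out visits", call. = FALSE)
  }
  if (!is.null(site_covariates) && nrow(site_covariates) != S) {
    stop("site_covariates must have one row per site", call. = FALSE)
  }
  structure(
    list(y = y, mask = mask, S = S, J = J,
         n_species = K, n_observed = K, n_aug = 0L, M = K,
         species = species %||% paste0("sp", seq_len(K)),
         site_covariates = site_covariates,
         visit_covariates = visit_covariates),
    class = "occ_data")
}

#' @export
print.occ_data <- function(x, ...) {
  cat(sprintf("Detection data: %d sites x %d visits x %d species", x$S, x$J,
              x$n_species))
  if (x$n_aug > 0) {
    cat(sprintf(" (%d observed + %d augmented, M = %d)", x$n_observed,
                x$n_aug, x$M))
  }
  cat(sprintf("\n  %d detections over %d realized visits\n",
              sum(x$y), sum(x$mask)))
  invisible(x)
}

#' Simulate replicated detection surveys for a realized community
#'
#' Given species occupancy and detection probabilities, draws the latent
#' presence matrix \code{z[i,k] ~ Bernoulli(psi_k)} and the detection records
#' \code{y[i,j,k] ~ Bernoulli(z[i,k] * p_k)} — so no false positives are
#' possible: a species absent from a site can only produce zeros there.
#'
#' @param truth an \code{occ_truth} from [draw_species_params()] (fields
#'   \code{psi}, \code{p} populated).
#' @param S,J number of sites and visits.
#' @param seed optional seed.
#' @return list with elements \code{data} (an [occ_data()]) and
#'   \code{truth} (the input completed with \code{z_true},
#'   \code{present_in_sample} and \code{detected} indicators).
#' @export
simulate_detections <- function(truth, S, J, seed = NULL) {
  stopifnot(inherits(truth, "occ_truth"))
  if (is.null(truth$psi) || is.null(truth$p)) {
    stop("truth must have psi and p populated", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(truth$psi)
  stopifnot(length(truth$p) == n)
  z <- matrix(rbinom(S * n, 1L, rep(truth$psi, each = S)), S, n)
  # detections only where present
  y <- array(0L, dim = c(S, J, n))
  pr <- rep(truth$p, each = S * J)
  zrep <- aperm(array(z, dim = c(S, n, J)), c(1, 3, 2))  # S x J x n
  y[] <- rbinom(S * J * n, 1L, pr) * zrep
  truth$z_true <- z
  truth$present_in_sample <- colSums(z) > 0
  truth$detected <- apply(y, 3, function(m) any(m == 1L))
  list(data = occ_data(y), truth = truth)
}

#' Simulate a complete dataset from a scenario
#'
#' Draws the community (species psi and p), then the survey data, from a
#' single RNG stream keyed by \code{seed}. This is the generator used by the
#' evaluation grid: one stream per dataset keyed by (scenario, replicate).
#'
#' @param spec an [occ_scenario()].
#' @param seed integer seed; defaults to \code{spec$seed}.
#' @return as [simulate_detections()].
#' @export
simulate_dataset <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "occ_scenario"))
  if (!is.null(seed)) set.seed(seed)
  truth <- draw_species_params(spec, seed = NULL)
  simulate_detections(truth, spec$S, spec$J, seed = NULL)
}
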