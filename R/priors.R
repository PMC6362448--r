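#' Prior configuration for the augmented community model
#'
#' A prior set fixes: the standard deviation of the zero-mean normal priors
#' on all hyper-means (the mu's of the logit-scale random effects), the
#' upper support bound U of the uniform priors on the hyper-standard
#' deviations (the sigma's), and the Beta(a, b) prior on the inclusion
#' probability Omega. Under Beta(1, 1) (uniform) the implied prior on
#' N = sum(w) is discrete uniform on {0, ..., M}; Beta(0.001, 1) instead
#' concentrates prior mass on small N, guarding against the improper-
#' posterior pathologies of the constant prior.
#'
#' @param mu_prior_sd standard deviation of the N(0, sd) prior on each
#'   hyper-mean.
#' @param sigma_support upper bound U of the uniform (0, U] prior on each
#'   hyper-sd.
#' @param omega_beta length-2 vector (a, b) of the Beta prior on Omega.
#' @param label free-text label.
#' @return object of class \code{occ_priors}.
#' @seealso [prior_set()] for the three standard regimes.
#' @export
occ_priors <- function(mu_prior_sd, sigma_support = 5,
                       omega_beta = c(1, 1), label = "custom") {
  stopifnot(mu_prior_sd > 0, sigma_support > 0, all(omega_beta > 0),
            length(omega_beta) == 2)
  structure(list(mu_prior_sd = mu_prior_sd, sigma_support = sigma_support,
                 omega_beta = omega_beta, label = label),
            class = "occ_priors")
}

#' The three standard prior regimes
#'
#' \describe{
#'   \item{set1}{common practice: very wide N(0, sd = 31) priors on the
#'     hyper-means (precision 0.001), uniform (0, 5] on the hyper-sds,
#'     uniform Beta(1, 1) on Omega (discrete-uniform prior on N).}
#'   \item{set2}{as set1 but N(0, sd = 2.25) on the hyper-means, keeping
#'     low prior mass outside \[-5, 5\] on the logit scale (very wide
#'     logit-scale priors are U-shaped on the probability scale and bias
#'     toward extreme probabilities).}
#'   \item{set3}{as set2 but Beta(0.001, 1) on Omega, which avoids the
#'     improper-posterior risk of the constant prior on N.}
#' }
#'
#' @param label \code{"set1"}, \code{"set2"}, \code{"set3"} (or 1:3).
#' @param sigma_support optional override of the sigma-prior upper bound
#'   (default 5; 10 is sometimes needed for rich covariate models).
#' @return an [occ_priors()] object.
#' @export
prior_set <- function(label, sigma_support = 5) {
  if (is.numeric(label)) label <- paste0("set", label)
  switch(label,
    set1 = occ_priors(31, sigma_support, c(1, 1), "set1"),
    set2 = occ_priors(2.25, sigma_support, c(1, 1), "set2"),
    set3 = occ_priors(2.25, sigma_support, c(0.001, 1), "set3"),
    stop("unknown prior set '", label, "' (use set1, set2 or set3)",
         call. = FALSE))
}

#' @export
print.occ_priors <- function(x, ...) {
  cat(sprintf(
    "Priors '%s': mu ~ N(0, sd %g); sigma ~ U(0, %g]; Omega ~ Beta(%g, %g)\n",
    x$label, x$mu_prior_sd, x$sigma_support, x$omega_beta[1],
    x$omega_beta[2]))
  invisible(x)
}

#' Log prior density of the hyperparameter state
#'
#' Sum of the normal log-densities of the hyper-means, the uniform terms for
#' the hyper-sds (-Inf outside the support, rejection semantics), and the
#' Beta log-density for Omega.
#'
#' @param state list with numeric \code{mu} (hyper-means), \code{sigma}
#'   (hyper-sds) and scalar \code{omega}.
#' @param priors an [occ_priors()].
#' @return scalar log-density (possibly -Inf).
#' @export
log_prior <- function(state, priors) {
  stopifnot(inherits(priors, "occ_priors"))
  if (any(state$sigma <= 0) || any(state$sigma > priors$sigma_support)) {
    return(-Inf)
  }
  sum(dnorm(state$mu, 0, priors$mu_prior_sd, log = TRUE)) -
    length(state$sigma) * log(priors$sigma_support) +
    dbeta(state$omega, priors$omega_beta[1], priors$omega_beta[2],
          log = TRUE)
}
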