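#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-part R-hat from m parallel chains of length n: with W the
#' mean within-chain variance and B/n the variance of the chain means,
#' \code{Rhat = sqrt(((n-1)/n * W + B/n) / W)}. Values near 1 indicate the
#' chains are sampling the same distribution; the conventional
#' no-evidence-of-non-convergence rule is Rhat < 1.1. Computed on the
#' retained (post-thinning) draws.
#'
#' Degenerate cases: chains stuck at different constants give Inf (zero
#' within-chain, positive between-chain variance — this genuinely happens
#' for the community-size indicator sums when membership indicators mix
#' very slowly); chains all constant and equal give NaN.
#'
#' @param x iterations x chains numeric matrix, or a list of equal-length
#'   chain vectors.
#' @return scalar R-hat.
#' @export
gelman_rubin <- function(x) {
  if (is.list(x)) {
    if (length(unique(lengths(x))) != 1) {
      stop("chains must have equal length", call. = FALSE)
    }
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  if (n < 10) stop("need at least 10 iterations", call. = FALSE)
  W <- mean(apply(x, 2, var))
  B_over_n <- var(colMeans(x))
  var_plus <- (n - 1) / n * W + B_over_n
  sqrt(var_plus / W)
}

#' Data-augmentation adequacy check
#'
#' The augmentation ceiling M is adequate when the posterior of N is not
#' pressed against it. Rule: divide the interval between the lowest sampled
#' N and M into 10 equal-width sections; augmentation is satisfactory if
#' the posterior mass in the upper section is below 1%.
#'
#' @param N_draws posterior draws of N (pooled across chains).
#' @param M maximum number of species allowed.
#' @return list with \code{upper_mass} (posterior mass in the top tenth of
#'   \[min(N), M\]) and \code{adequate} (logical). If min(N) = M the
#'   interval is degenerate: flagged inadequate with a warning.
#' @export
augmentation_adequate <- function(N_draws, M) {
  stopifnot(length(N_draws) > 0, all(N_draws <= M))
  lo <- min(N_draws)
  if (lo == M) {
    warning("degenerate adequacy interval: min(N) = M", call. = FALSE)
    return(list(upper_mass = 1, adequate = FALSE))
  }
  width <- (M - lo) / 10
  mass <- mean(N_draws > M - width)
  list(upper_mass = mass, adequate = mass < 0.01)
}

#' Diagnostics table for a fitted model
#'
#' R-hat and a crude effective sample size (pooled draws divided by the
#' integrated autocorrelation time estimated from the pooled chain) for
#' every retained scalar parameter.
#'
#' @param fit an \code{occ_fit}.
#' @return data.frame with columns parameter, rhat, ess.
#' @export
diagnostics_table <- function(fit) {
  stopifnot(inherits(fit, "occ_fit"))
  pn <- colnames(fit$draws$pars[[1]])
  ess <- vapply(pn, function(p) {
    sum(vapply(fit$draws$pars, function(m) ess_acf(m[, p]), numeric(1)))
  }, numeric(1))
  data.frame(parameter = pn, rhat = unname(fit$rhat[pn]),
             ess = unname(ess), row.names = NULL)
}

# Initial-positive-sequence ESS for one chain.
ess_acf <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  L <- if (length(pos)) pos[1] - 1 else length(ac)
  tau <- 1 + 2 * sum(ac[seq_len(L)])
  n / max(tau, 1)
}

#' Batch-means Monte-Carlo standard error of a chain mean
#'
#' Splits the chain into consecutive batches and uses the standard
#' deviation of batch means; robust to the autocorrelation of MCMC output.
#'
#' @param x numeric chain.
#' @param n_batch number of batches.
#' @return standard error of \code{mean(x)}.
#' @export
mcse_batch <- function(x, n_batch = 30) {
  n <- length(x)
  b <- max(floor(n / n_batch), 1)
  nb <- n %/% b
  means <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * b + 1):(i * b)]),
                  numeric(1))
  sd(means) / sqrt(nb)
}
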