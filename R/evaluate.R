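#' Run a simulation-evaluation grid
#'
#' Drives the simulation study: for every scenario and replicate it
#' simulates a dataset (one RNG stream per dataset, keyed by the base seed,
#' the scenario index and the replicate index), then analyses it under each
#' prior set. Data augmentation is chosen adaptively: the fit is repeated
#' with increasing augmentation until [augmentation_adequate()] passes or
#' the largest level is reached, mirroring the study protocol (50 up to
#' 500 added pseudo-species).
#'
#' @param scenarios list of [occ_scenario()] objects (give them \code{id}s).
#' @param prior_sets list of [occ_priors()] objects.
#' @param n_replicates replicate datasets per scenario.
#' @param config an [mcmc_config()]; its seed is the grid base seed.
#' @param aug_levels increasing augmentation sizes tried per fit.
#' @param results_dir optional directory for per-cell CSV checkpoints;
#'   completed cells (matching files) are skipped, making long grids
#'   resumable.
#' @param verbose print progress lines.
#' @return data.frame with one row per (scenario, replicate, prior set):
#'   true/present/detected species counts, posterior median and 95% CI for
#'   N, augmentation level and adequacy, max Rhat, convergence flag, seed.
#' @export
run_grid <- function(scenarios, prior_sets = list(prior_set("set3")),
                     n_replicates = 3, config = mcmc_config(),
                     aug_levels = c(50, 150, 300, 500),
                     results_dir = NULL, verbose = FALSE) {
  stopifnot(length(scenarios) > 0, length(prior_sets) > 0)
  if (!is.null(results_dir) && !dir.exists(results_dir)) {
    dir.create(results_dir, recursive = TRUE)
  }
  rows <- list()
  for (s_idx in seq_along(scenarios)) {
    spec <- scenarios[[s_idx]]
    sid <- spec$id %||% paste0("scenario", s_idx)
    for (rep_i in seq_len(n_replicates)) {
      seed_i <- (config$seed * 1000L + s_idx * 100L + rep_i) %%
        .Machine$integer.max
      sim <- simulate_dataset(spec, seed = seed_i)
      for (p_idx in seq_along(prior_sets)) {
        pr <- prior_sets[[p_idx]]
        key <- sprintf("%s_rep%d_%s", sid, rep_i, pr$label)
        ckpt <- if (!is.null(results_dir)) {
          file.path(results_dir, paste0(key, ".csv"))
        }
        if (!is.null(ckpt) && file.exists(ckpt)) {
          rows[[key]] <- read.csv(ckpt)
          next
        }
        row <- tryCatch(
          fit_cell(sim, spec, pr, config, aug_levels, sid, rep_i, seed_i),
          error = function(e) {
            data.frame(scenario = sid, replicate = rep_i,
                       prior = pr$label, n_species_true = spec$n_species,
                       n_present = NA, n_detected = NA, median = NA,
                       ci_low = NA, ci_high = NA, n_aug = NA,
                       augmentation_ok = NA, rhat_max = NA,
                       converged = NA, seed = seed_i,
                       error = conditionMessage(e))
          })
        if (is.null(row$error)) row$error <- NA_character_
        if (verbose) {
          message(sprintf("%s: N median %s [%s, %s]", key, row$median,
                          row$ci_low, row$ci_high))
        }
        if (!is.null(ckpt)) write.csv(row, ckpt, row.names = FALSE)
        rows[[key]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fit_cell <- function(sim, spec, priors, config, aug_levels, sid, rep_i,
                     seed_i) {
  dat0 <- sim$data
  fit <- NULL
  used_aug <- NA
  for (aug in aug_levels) {
    fit <- run_mcmc(augment(dat0, aug), priors = priors, config = config)
    used_aug <- aug
    if (augmentation_adequate(n_draws(fit), fit$M)$adequate) break
  }
  rs <- richness_summary(fit)
  data.frame(scenario = sid, replicate = rep_i, prior = priors$label,
             n_species_true = spec$n_species,
             n_present = sum(sim$truth$present_in_sample),
             n_detected = sum(sim$truth$detected),
             median = rs$median, ci_low = rs$ci_low, ci_high = rs$ci_high,
             n_aug = used_aug, augmentation_ok = rs$augmentation_ok,
             rhat_max = rs$rhat_max, converged = fit$converged,
             seed = seed_i)
}

#' Performance summaries over grid results
#'
#' Per (scenario, prior) cell and pooled: mean bias of the posterior median,
#' mean credible-interval width, empirical coverage of the true community
#' size by the 95% interval, and the number of intervals whose upper bound
#' reaches each of the given thresholds (a symptom of runaway
#' overestimation).
#'
#' @param results data.frame from [run_grid()].
#' @param thresholds upper-bound thresholds to count.
#' @return data.frame, one row per (scenario, prior) plus a pooled row.
#' @export
summarize_performance <- function(results, thresholds = c(300, 500)) {
  stopifnot(nrow(results) >= 1)
  ok <- !is.na(results$median)
  results <- results[ok, , drop = FALSE]
  one <- function(df, sid, pid) {
    row <- data.frame(scenario = sid, prior = pid, n = nrow(df),
                      bias_median = mean(df$median - df$n_species_true),
                      ci_width = mean(df$ci_high - df$ci_low),
                      coverage = mean(df$ci_low <= df$n_species_true &
                                        df$n_species_true <= df$ci_high))
    for (th in thresholds) {
      row[[paste0("n_upper_ge_", th)]] <- sum(df$ci_high >= th)
    }
    row
  }
  keys <- unique(results[, c("scenario", "prior")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- results[results$scenario == keys$scenario[i] &
                     results$prior == keys$prior[i], , drop = FALSE]
    one(sub, keys$scenario[i], keys$prior[i])
  }))
  rbind(out, one(results, "(all)", "(all)"))
}
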