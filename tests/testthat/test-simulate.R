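test_that("zero-variance occupancy regime collapses to a point mass", {
  sp <- occ_scenario(n_species = 50, occ_mu = -1, occ_sigma = 0, S = 5,
                     J = 2)
  tr <- draw_species_params(sp, seed = 1)
  expect_equal(tr$psi, rep(plogis(-1), 50))
})

test_that("scenario validation rejects malformed inputs", {
  expect_error(occ_scenario(occ_sigma = -0.1), "occ_sigma")
  expect_error(occ_scenario(S = 0), "S")
  expect_error(occ_scenario(det_family = "cauchy"), "unknown")
  expect_error(
    occ_scenario(det_family = "mixture",
                 det_params = list(weights = c(0.5, 0.4),
                                   means = c(-2, 0), sds = c(1, 1))),
    "sum to 1")
  expect_error(
    occ_scenario(det_family = "mixture",
                 det_params = list(weights = c(0.5, 0.5),
                                   means = c(-2, 0), sds = c(1, 0))),
    "scales")
  expect_error(draw_detectability("heavy-tail", list(df = 3), 10),
               "must include")
})

test_that("species parameter draws are reproducible and in (0,1)", {
  sp <- occ_scenario_ideal("Occ2", S = 10, J = 2, n_species = 200)
  a <- draw_species_params(sp, seed = 7)
  b <- draw_species_params(sp, seed = 7)
  expect_identical(a$psi, b$psi)
  expect_identical(a$p, b$p)
  expect_true(all(a$psi > 0 & a$psi < 1))
  expect_true(all(a$p > 0 & a$p < 1))
})

test_that("one-component mixture is distributionally the logit-normal", {
  n <- 2e4
  m <- draw_detectability("mixture",
                          list(weights = 1, means = -2, sds = 1), n,
                          seed = 11)
  ln <- draw_detectability("logit-normal", list(mean = -2, sd = 1), n,
                           seed = 12)
  ks <- suppressWarnings(stats::ks.test(m, ln))
  expect_gt(ks$p.value, 0.01)
})

test_that("bimodal family with first mode away from zero has two modes > 0.1", {
  v <- det_violation("bimodal-high")
  p <- draw_detectability(v$det_family, v$det_params, 5e4, seed = 3)
  d <- density(p, n = 512)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  modes <- d$x[peaks][d$y[peaks] > 0.2 * max(d$y)]
  expect_gte(length(modes), 2)
  expect_true(all(modes > 0.1))
})

test_that("heavy-tail family has excess kurtosis on the logit scale", {
  n <- 1e6
  ht <- qlogis(draw_detectability("heavy-tail",
                                  list(df = 3, location = -2, scale = 1),
                                  n, seed = 5))
  set.seed(5)
  nm <- rnorm(n, -2, 1)
  kurt <- function(x) mean((x - mean(x))^4) / var(x)^2 - 3
  expect_gt(kurt(ht), kurt(nm) + 1)
})

test_that("degenerate probabilities give saturated / empty data", {
  tr <- structure(list(psi = rep(1, 4), p = rep(1, 4)), class = "occ_truth")
  out <- simulate_detections(tr, S = 3, J = 2, seed = 1)
  expect_true(all(out$data$y == 1))
  expect_equal(sum(out$truth$detected), 4)

  tr0 <- structure(list(psi = rep(0, 4), p = rep(0.9, 4)),
                   class = "occ_truth")
  out0 <- simulate_detections(tr0, S = 3, J = 2, seed = 1)
  expect_true(all(out0$data$y == 0))
  expect_true(all(!out0$truth$present_in_sample))
})

test_that("simulated surveys never produce false positives", {
  sp <- occ_scenario_ideal("Occ2", S = 12, J = 3, n_species = 40)
  for (seed in 1:5) {
    out <- simulate_dataset(sp, seed = seed)
    ysum <- apply(out$data$y, c(1, 3), sum)
    expect_true(all(ysum[out$truth$z_true == 0] == 0))
    expect_true(all(out$truth$detected <= out$truth$present_in_sample))
    expect_equal(out$truth$present_in_sample,
                 colSums(out$truth$z_true) > 0)
  }
})

test_that("detection frequency at occupied sites converges to p", {
  tr <- structure(list(psi = rep(1, 3), p = c(0.2, 0.5, 0.8)),
                  class = "occ_truth")
  S <- 200; J <- 5
  out <- simulate_detections(tr, S = S, J = J, seed = 9)
  freq <- apply(out$data$y, 3, mean)  # all sites occupied
  for (k in 1:3) {
    ci <- stats::binom.test(sum(out$data$y[, , k]), S * J)$conf.int
    expect_true(tr$p[k] >= ci[1] && tr$p[k] <= ci[2])
  }
})

test_that("fraction never detected matches the missed-species expectation", {
  sp <- occ_scenario_ideal("Occ1", S = 25, J = 2, n_species = 100)
  miss <- vapply(1:20, function(r) {
    out <- simulate_dataset(sp, seed = 1000 + r)
    mean(!out$truth$detected)
  }, numeric(1))
  expected <- as.numeric(expected_missed_fraction(sp, n_mc = 1e5,
                                                  seed = 1))
  se <- sd(miss) / sqrt(length(miss))
  expect_lt(abs(mean(miss) - expected), 4 * se + 0.005)
})

test_that("location tuner hits the requested missed fraction", {
  v <- det_violation("bimodal-low")
  sp <- occ_scenario(n_species = 50, occ_mu = -1, occ_sigma = 0.3,
                     det_family = v$det_family, det_params = v$det_params,
                     S = 25, J = 2)
  tuned <- tune_det_location(sp, target = 0.09, n_mc = 1e5)
  got <- as.numeric(expected_missed_fraction(tuned, n_mc = 1e5, seed = 2))
  expect_lt(abs(got - 0.09), 0.01)
})
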