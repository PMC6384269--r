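ipf_fdg <- function() {
  make_input_function(input_function_params(100, c(4, 0.5, 0.01), c(20, 10)),
                      t_end = 60)
}

test_that("points on an exact line are recovered perfectly", {
  sched <- fdg_schedule()
  # constant plasma activity: theta equals the frame midpoint, so a tissue
  # curve equal to Cp * (K*t + b) puts every Patlak point on ratio = K*theta + b
  cp0 <- 5
  ipf <- plasma_input(seq(0, 60, by = 0.5), rep(cp0, 121))
  tissue <- tac(sched, cp0 * (0.05 * sched$mid + 0.3))
  fit <- patlak_fit(tissue, ipf, t_star = 10)
  expect_equal(fit$K, 0.05, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("noiseless irreversible kinetics recover the closed-form Ki", {
  ipf <- ipf_fdg()
  sched <- fdg_schedule()
  pars <- compartment_params(0.102, 0.13, 0.062, vb = 0)
  ki <- 0.102 * 0.062 / (0.13 + 0.062)  # 0.03294
  fit <- patlak_fit(simulate_tissue_tac(ipf, pars, sched), ipf, t_star = 10)
  expect_lt(abs(fit$K - ki) / ki, 0.03)
  expect_gt(fit$r_squared, 0.999)
  # fully reversible tracer: slope tends to zero
  rev <- compartment_params(0.102, 0.13, 0, vb = 0)
  fit_rev <- patlak_fit(simulate_tissue_tac(ipf, rev, sched), ipf, t_star = 10)
  expect_lt(abs(fit_rev$K), 0.002)
})

test_that("estimated K converges monotonically toward Ki as t_star grows", {
  ipf <- ipf_fdg()
  sched <- fdg_schedule()
  pars <- compartment_params(0.102, 0.13, 0.062, vb = 0)
  sim <- simulate_tissue_tac(ipf, pars, sched)
  ks <- sapply(seq(5, 20, by = 2.5), function(ts) patlak_fit(sim, ipf, ts)$K)
  expect_true(all(diff(abs(ks - pars$ki)) < 1e-9))
  expect_lt(abs(ks[length(ks)] - pars$ki) / pars$ki, 0.02)
})

test_that("K is invariant to input scaling and proportional to tissue scaling", {
  ipf <- ipf_fdg()
  sched <- fdg_schedule()
  pars <- compartment_params(0.102, 0.13, 0.062, vb = 0)
  sim <- simulate_tissue_tac(ipf, pars, sched)
  fit <- patlak_fit(sim, ipf, 10)
  ipf4 <- plasma_input(ipf$sample_times, 4 * ipf$sample_values)
  sim4 <- tac(sched, 4 * sim$values)
  expect_equal(patlak_fit(sim4, ipf4, 10)$K, fit$K, tolerance = 1e-10)
  sim2 <- tac(sched, 2 * sim$values)
  expect_equal(patlak_fit(sim2, ipf, 10)$K, 2 * fit$K, tolerance = 1e-10)
})

test_that("median relative bias of K stays below 5% at study-like noise", {
  ipf <- ipf_fdg()
  sched <- fdg_schedule()
  pars <- compartment_params(0.102, 0.13, 0.062, vb = 0)
  ks <- sapply(1:200, function(s)
    patlak_fit(simulate_tissue_tac(ipf, pars, sched, noise_sd_scale = 0.05,
                                   seed = s), ipf, 10)$K)
  expect_lt(abs(median((ks - pars$ki) / pars$ki)), 0.05)
})

test_that("degenerate fits are rejected with informative errors", {
  ipf <- ipf_fdg()
  sched <- fdg_schedule()
  sim <- simulate_tissue_tac(ipf, compartment_params(0.1, 0.1, 0.05), sched)
  expect_error(patlak_fit(sim, ipf, t_star = 59), "fewer than 3")
  const <- plasma_input(seq(0, 60, 0.5), rep(5, 121))
  dup <- tac(frame_schedule(c(0, 20, 40), c(20, 40, 60)), c(1, 2, 3))
  expect_s3_class(patlak_fit(dup, const, 0), "patlak_result")
})

test_that("CMR conversion follows CMR = 100*K*Cp/(LC*density)", {
  expect_equal(cmr_from_k(0, 5.1, 0.8)$cmr, 0)
  expect_equal(cmr_from_k(0.05, 5.1, 0.8, 1.0)$cmr, 31.875)
  # doubling LC halves CMR; LC 1.0 vs 0.8 gives an exact 0.8 ratio
  expect_equal(cmr_from_k(0.03, 5.1, 1.0)$cmr / cmr_from_k(0.03, 5.1, 0.8)$cmr, 0.8)
  expect_equal(cmr_from_k(0.06, 5.1, 0.8)$cmr, 2 * cmr_from_k(0.03, 5.1, 0.8)$cmr)
  expect_equal(cmr_from_k(0.03, 2.55, 0.8)$cmr, cmr_from_k(0.03, 5.1, 0.8)$cmr / 2)
  expect_error(cmr_from_k(0.05, 5.1, 0), "lumped")
  expect_error(cmr_from_k(0.05, -1, 0.8), "positive")
  expect_error(cmr_from_k(0.05, 5.1, 0.8, density = 0), "density")
  # negative K propagates (flagging, not clamping)
  expect_lt(cmr_from_k(-0.01, 5.1, 0.8)$cmr, 0)
})

test_that("regional fitting flags unfittable regions instead of dropping them", {
  atlas <- load_atlas()
  ipf <- ipf_fdg()
  sched <- fdg_schedule()
  pars <- compartment_params(0.102, 0.13, 0.062, vb = 0)
  sim <- simulate_tissue_tac(ipf, pars, sched)
  tacs <- setNames(rep(list(sim), nrow(atlas)), atlas$name)
  tacs[[5L]] <- NULL  # one region missing
  res <- fit_regional_k(tacs, ipf, atlas, t_star = 10)
  expect_equal(nrow(res), 43L)
  expect_equal(sum(!res$ok), 1L)
  expect_true(all(abs(res$K_per_min[res$ok] - pars$ki) / pars$ki < 0.03))
})
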