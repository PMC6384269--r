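sim_long <- function(n_subj, slope, bsd, rsd, seed, visits = c(0, 2, 4)) {
  set.seed(seed)
  age0 <- rnorm(n_subj, 71, 5)
  u <- rnorm(n_subj, 0, bsd)
  do.call(rbind, lapply(seq_len(n_subj), function(s)
    data.frame(subject = s, age = age0[s] + visits,
               y = 0.05 + slope * (age0[s] + visits - 71) + u[s] +
                 rnorm(length(visits), 0, rsd))))
}

test_that("noise-free data recover the generating slope exactly", {
  d <- sim_long(12, -0.0006, 0, 0, seed = 4)
  fit <- fit_mixed_linear(d)
  expect_equal(fit$slope, -0.0006, tolerance = 1e-8)
  expect_equal(fit$n_obs, 36L)
  expect_equal(fit$n_subjects, 12L)
})

test_that("slope is invariant to shifting all ages by a constant", {
  d <- sim_long(15, -0.0006, 0.006, 0.004, seed = 8)
  f1 <- fit_mixed_linear(d)
  d2 <- d; d2$age <- d2$age + 100
  f2 <- fit_mixed_linear(d2)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-8)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-6)
})

test_that("a single subject is rejected: the random intercept is unidentifiable", {
  d <- data.frame(subject = 1, age = c(70, 72, 74), y = c(1, 2, 3))
  expect_error(fit_mixed_linear(d), "at least 2 subjects")
})

test_that("type-I error of the slope test is near nominal under the null", {
  p <- vapply(1:400, function(s)
    fit_mixed_linear(sim_long(25, 0, 0.006, 0.004, seed = s))$p_value,
    numeric(1L))
  rej <- mean(p < 0.05)
  # binomial CI around 0.05 at 400 replicates (about +/- 2.5 percentage points),
  # plus slack for the Wald normal reference being slightly liberal here
  expect_lt(rej, 0.095)
  expect_gt(rej, 0.015)
})

test_that("BH step-up matches its definition and the exhaustive oracle", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))  # p(4) = 0.04 <= 0.05 * 4/4
  expect_false(any(bh_fdr(rep(1, 6), 0.05)$reject))
  set.seed(99)
  for (i in 1:200) {
    m <- sample(1:10, 1L)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1L)
    expect_identical(bh_fdr(p, q)$reject, bh_oracle(p, q))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH sits between Bonferroni and unadjusted thresholding", {
  set.seed(123)
  for (i in 1:100) {
    p <- runif(sample(5:40, 1L))^sample(1:3, 1L)
    q <- 0.05
    bh <- sum(bh_fdr(p, q)$reject)
    bonf <- sum(p <= q / length(p))
    raw <- sum(p <= q)
    expect_gte(bh, bonf)
    expect_lte(bh, raw)
  }
})

test_that("regional table has atlas order, FDR flags and gap rows", {
  ch <- simulate_cohort(cohort_spec(seed = 17))
  lt <- build_regional_table(ch, q = 0.05)
  atlas <- load_atlas()
  expect_equal(lt$region, atlas$name)
  expect_true(all(c("T0", "T2", "T4", "SEM", "fixed_effect", "p_value",
                    "fdr_significant") %in% names(lt)))
  expect_true(all(is.finite(lt$p_value)))
  # removing a region's column produces an explicit gap row, not an error
  ch2 <- ch[, setdiff(names(ch), "K.Thalamus")]
  lt2 <- build_regional_table(ch2)
  expect_true(is.na(lt2$fixed_effect[lt2$region == "Thalamus"]))
  expect_equal(nrow(lt2), 43L)
})

test_that("under a global null the regional table rarely rejects after FDR", {
  kt <- load_k_table("glucose")
  null_means <- setNames(kt$T0, kt$region)
  null_slopes <- setNames(rep(0, nrow(kt)), kt$region)
  n_any <- vapply(1:15, function(s) {
    ch <- simulate_cohort(cohort_spec(region_means = null_means,
                                      region_slopes = null_slopes, seed = 100 + s))
    sum(build_regional_table(ch, q = 0.05)$fdr_significant)
  }, numeric(1L))
  # under the global null BH controls the family-wise error at q
  expect_lte(mean(n_any > 0), 0.2)
})

test_that("slopes simulated from the reference table keep their sign", {
  kt <- load_k_table("glucose")
  sp <- function(s) cohort_spec(residual_sd = 0.001, between_subject_sd = 0.002,
                                seed = 200 + s)
  hits <- vapply(1:5, function(s) {
    lt <- build_regional_table(simulate_cohort(sp(s)))
    mean(sign(lt$fixed_effect) == sign(kt$fixed_effect))
  }, numeric(1L))
  expect_gte(mean(hits), 0.9)
})
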