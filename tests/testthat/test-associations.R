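test_that("HOMA-IR follows glucose * insulin / 22.5", {
  expect_equal(homa_ir(4.5, 0), 0)
  expect_equal(homa_ir(4.5, 5), 1.0)
  # ratio of cohort means differs from the mean of per-subject ratios, so this
  # worked value (5.1 mM, 7.1 uU/mL) legitimately exceeds a cohort-mean index
  expect_equal(homa_ir(5.1, 7.1), 1.609, tolerance = 1e-3)
  expect_error(homa_ir(0, 5), "positive")
  expect_error(homa_ir(5, -1), "non-negative")
})

test_that("composite z-scores convert scaled scores against the norm", {
  battery <- load_cognitive_battery()
  wm_tests <- battery$test[battery$domain == "working_memory"]
  all_norm <- setNames(rep(10, length(wm_tests)), wm_tests)
  expect_equal(as.numeric(composite_z(all_norm, "working_memory")), 0)
  one <- setNames(13, wm_tests[1L])
  expect_equal(as.numeric(composite_z(one, "working_memory")), 1.0)
  two <- setNames(c(7, 13), wm_tests[1:2])
  z <- composite_z(two, "working_memory")
  expect_equal(as.numeric(z), 0)
  expect_equal(attr(z, "n_tests"), 2L)
  expect_equal(attr(z, "n_missing"), length(wm_tests) - 2L)
  expect_error(composite_z(c(x = 10), "working_memory"), "no available tests")
  expect_error(composite_z(all_norm, "not_a_domain"), "unknown domain")
})

test_that("subject averaging matches a brute-force per-subject loop", {
  d <- data.frame(subject_id = c("a", "a", "a", "b", "c", "c"),
                  v1 = c(0.040, 0.038, 0.036, 0.05, 1, 2),
                  v2 = c(1, 2, 3, 4, 5, NA))
  avg <- subject_average(d)
  expect_equal(avg$v1[avg$subject_id == "a"], 0.038)
  expect_equal(avg$n_visits, c(3L, 1L, 2L))
  expect_equal(avg$v1[avg$subject_id == "b"], 0.05)  # single visit passthrough
  for (s in unique(d$subject_id)) {
    rows <- d[d$subject_id == s, ]
    expect_equal(avg$v1[avg$subject_id == s], mean(rows$v1))
    expect_equal(avg$v2[avg$subject_id == s], mean(rows$v2, na.rm = TRUE))
  }
})

test_that("Pearson association matches the regression slope test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_association(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_association(x, -x)$r, -1)
  set.seed(42)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  res <- pearson_association(a, b)
  ref <- stats::cor.test(a, b)
  expect_equal(res$r, unname(ref$estimate))
  expect_equal(res$p_value, ref$p.value)
  lmfit <- stats::lm(b ~ a)
  expect_equal(res$slope, unname(stats::coef(lmfit)[2L]))
  expect_equal(res$intercept, unname(stats::coef(lmfit)[1L]))
  expect_error(pearson_association(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_association(rep(1, 5), x), "zero variance")
})

test_that("r is invariant to positive affine maps and flips under negation", {
  set.seed(7)
  x <- rnorm(25); y <- -0.4 * x + rnorm(25)
  r0 <- pearson_association(x, y)$r
  expect_equal(pearson_association(3 * x + 10, 0.5 * y - 2)$r, r0)
  expect_equal(pearson_association(-x, y)$r, -r0)
  # missing subjects are dropped pairwise with n reported
  x[3] <- NA
  expect_equal(pearson_association(x, y)$n, 24L)
})

test_that("the built-in insulin dependence yields a negative K association", {
  signs <- vapply(1:200, function(s) {
    ch <- simulate_cohort(cohort_spec(seed = 400 + s))
    ch$homa <- homa_ir(ch$glucose_mM, ch$insulin_uU_per_mL)
    avg <- subject_average(ch, value_cols = c("homa", "K.Caudate"))
    sign(pearson_association(avg$homa, avg$K.Caudate)$r)
  }, numeric(1L))
  expect_gte(mean(signs < 0), 0.95)
})
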