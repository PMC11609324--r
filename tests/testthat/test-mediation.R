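test_that("family decomposition is exact", {
  # singleton: between = value, within = 0
  d1 <- family_decompose(5, "A")
  expect_equal(d1$between, 5)
  expect_equal(d1$within, 0)
  # pair {2, 4}: mean 3, deviations -1/+1
  d2 <- family_decompose(c(2, 4), c("A", "A"))
  expect_equal(d2$between, c(3, 3))
  expect_equal(d2$within, c(-1, 1))
  # random input: reconstruction and zero within-family sums
  set.seed(31)
  v <- rnorm(200)
  fam <- sample(sprintf("f%02d", 1:40), 200, replace = TRUE)
  d <- family_decompose(v, fam)
  expect_equal(d$between + d$within, v)
  sums <- tapply(d$within, fam, sum)
  expect_true(all(abs(sums) < 1e-10))
})

med_cohort <- function(a = 0.3, b_b = 0.2, b_w = 0.1, c_p = 0.17,
                       n_families = 1700, seed = 1) {
  quick_cohort(n_families = n_families, seed = seed,
               sibling_probs = c(1 - 0.1765, 0.1765, 0),
               beta_map = NULL,
               mediation = list(scale = "int", measure = "ERN3", a = a,
                                b_between = b_b, b_within = b_w,
                                c_prime = c_p))
}

test_that("planted mediation paths are recovered within sampling error", {
  co <- med_cohort(seed = 32)
  fit <- fit_mediation(co, "int_p", "ERN3", "int_y", engine = "fast")
  expect_lt(abs(fit$a - 0.3), 3 * fit$se_a)
  expect_lt(abs(fit$b_between - 0.2), 3 * fit$se_b_between)
  expect_lt(abs(fit$b_within - 0.1), 3 * fit$se_b_within)
  expect_lt(abs(fit$c_prime - 0.17), 3 * fit$se_c_prime)
  expect_equal(fit$indirect, fit$a * fit$b_between)
  expect_equal(fit$total, fit$c_prime + fit$indirect)
  # linear-model identity: total X -> Y effect ~ c' + a * b_between
  expect_lt(abs(fit$total_xy - fit$total), 0.04)
})

test_that("lmer and fast engines agree on mediation paths", {
  co <- med_cohort(n_families = 400, seed = 33)
  f1 <- fit_mediation(co, "int_p", "ERN3", "int_y", engine = "fast")
  f2 <- fit_mediation(co, "int_p", "ERN3", "int_y", engine = "lmer")
  expect_equal(f1$a, f2$a, tolerance = 1e-6)
  expect_equal(f1$b_between, f2$b_between, tolerance = 1e-6)
  expect_equal(f1$b_within, f2$b_within, tolerance = 1e-6)
  expect_equal(f1$loglik_y, f2$loglik_y, tolerance = 1e-5)
})

test_that("singleton-only samples flag b_within as inestimable", {
  co <- quick_cohort(n_families = 200, seed = 34,
                     sibling_probs = c(1, 0, 0))
  expect_warning(
    fit <- fit_mediation(co, "int_p", "ERN3", "int_y", engine = "fast"),
    "inestimable")
  expect_true(is.na(fit$b_within))
  expect_true(fit$singleton_only)
  con <- fit_mediation(co, "int_p", "ERN3", "int_y", engine = "fast",
                       constrain_b = TRUE)
  expect_error(compare_b_paths(fit, con), "singleton")
})

test_that("within-family exposure variation is refused and fixable", {
  co <- quick_cohort(n_families = 150, seed = 35,
                     sibling_probs = c(0.5, 0.5, 0))
  bad <- co
  sib_fam <- names(which(table(bad$family_id) == 2))[1]
  row <- which(bad$family_id == sib_fam)[1]
  bad$int_p[row] <- bad$int_p[row] + 7
  expect_error(fit_mediation(bad, "int_p", "ERN3", "int_y"),
               "varies within family")
  fixed <- subsample_one_per_family(bad, seed = 2)
  expect_lt(nrow(fixed), nrow(bad))
  expect_silent(fit_mediation(fixed, "int_p", "ERN3", "int_y",
                              engine = "fast"))
})

test_that("the likelihood-ratio comparison behaves like a 1-df chi-square", {
  co <- med_cohort(seed = 36)
  free <- fit_mediation(co, "int_p", "ERN3", "int_y", engine = "fast")
  con <- fit_mediation(co, "int_p", "ERN3", "int_y", engine = "fast",
                       constrain_b = TRUE)
  cmp <- compare_b_paths(free, con)
  expect_identical(cmp$df, 1L)
  expect_gte(cmp$statistic, 0)
  expect_true(cmp$p >= 0 && cmp$p <= 1)
  expect_error(compare_b_paths(free, free), "one free and one constrained")

  # grossly different planted paths are detected nearly always
  rej <- vapply(1:10, function(s) {
    cs <- med_cohort(a = 0.3, b_b = 0.5, b_w = 0, c_p = 0.1,
                     n_families = 1500, seed = 400 + s)
    f <- fit_mediation(cs, "int_p", "ERN3", "int_y", engine = "fast")
    k <- fit_mediation(cs, "int_p", "ERN3", "int_y", engine = "fast",
                       constrain_b = TRUE)
    compare_b_paths(f, k)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("indirect-effect intervals are reproducible with sensible edges", {
  co <- med_cohort(n_families = 600, seed = 37)
  fit <- fit_mediation(co, "int_p", "ERN3", "int_y", engine = "fast")
  c1 <- indirect_ci(fit, B = 500, seed = 9)
  c2 <- indirect_ci(fit, B = 500, seed = 9)
  expect_identical(c1$ci, c2$ci)
  # a = 0 with zero SE collapses the interval to [0, 0]
  fit0 <- fit
  fit0$a <- 0
  fit0$se_a <- 0
  c0 <- indirect_ci(fit0, B = 200, seed = 1)
  expect_equal(unname(c0$ci), c(0, 0))
  # bootstrap flavour runs and brackets the Monte-Carlo interval loosely
  cb <- indirect_ci(fit, method = "bootstrap", B = 150, seed = 4)
  expect_lt(cb$ci[1], cb$ci[2])
})

test_that("the mediation grid is complete with monotone FDR", {
  co <- med_cohort(n_families = 250, seed = 38)
  g <- run_mediation_grid(co, B = 200, seed = 10)
  expect_equal(nrow(g), 30L)
  expect_true(all(g$chisq_df == 1))
  expect_true(all(g$p_fdr >= g$p_indirect))
  # baseline adjustment runs and barely moves indirect estimates when the
  # generator has no baseline confounding
  gb <- run_mediation_grid(co, measures = "ERN3", B = 200, seed = 10,
                           adjust_baseline = TRUE)
  expect_equal(nrow(gb), 3L)
  i0 <- g$indirect[g$measure == "ERN3" & g$scale == "int"]
  ib <- gb$indirect[gb$scale == "int"]
  expect_lt(abs(i0 - ib), 0.05)
})
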