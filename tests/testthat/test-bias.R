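test_that("leave-one-out produces one re-pooled row per omitted study", {
  e <- fixture_effects(function(s) rep(TRUE, nrow(s)), "recessive")
  lo <- leave_one_out(e)
  expect_equal(nrow(lo), 11)
  expect_setequal(lo$omitted_study, e$study_id)
  # no single omission moves the pooled OR outside the all-study CI
  all_res <- select_and_pool(e)
  expect_true(all(lo$or > all_res$ci_low & lo$or < all_res$ci_high))
})

test_that("leave-one-out on identical studies is constant, and method re-selection works", {
  e3 <- effects_from_cells(rep(30, 3), rep(20, 3), rep(25, 3), rep(25, 3))
  lo <- leave_one_out(e3)
  expect_equal(length(unique(lo$or)), 1)
  expect_equal(length(unique(lo$method)), 1)
  expect_error(leave_one_out(e3[1:2, ]), "at least three")

  # one outlying study carries all the heterogeneity; dropping it flips
  # the selected model from random to fixed
  out <- effects_from_cells(c(30, 32, 31, 300), c(20, 21, 19, 40),
                            c(25, 26, 24, 40), c(25, 24, 26, 300))
  expect_equal(select_and_pool(out)$method, "dl_random")
  lo2 <- leave_one_out(out)
  expect_equal(lo2$method[4], "mh_fixed")
  expect_equal(unique(lo2$method[1:3]), "dl_random")
})

test_that("Egger's regression matches metafor's classical form on the fixture", {
  skip_if_not_installed("metafor")
  for (m in c("allele", "recessive")) {
    e <- fixture_effects(function(s) rep(TRUE, nrow(s)), m)
    got <- egger_test(e)
    ref <- metafor::regtest(x = e$ln_or, sei = e$se, model = "lm")
    expect_equal(got$egger_p, ref$pval, tolerance = 1e-10)
  }
})

test_that("Egger intercept is order-invariant and antisymmetric under effect inversion", {
  e <- fixture_effects(function(s) rep(TRUE, nrow(s)), "homozygous")
  shuf <- e[sample(nrow(e)), ]
  expect_equal(egger_test(shuf)$egger_intercept,
               egger_test(e)$egger_intercept, tolerance = 1e-12)
  inv <- e
  inv$ln_or <- -inv$ln_or
  expect_equal(egger_test(inv)$egger_intercept,
               -egger_test(e)$egger_intercept, tolerance = 1e-12)
  expect_error(egger_test(e[1:2, ]), "at least three")
})

test_that("equal standard errors degenerate Egger's regression, flagged as such", {
  e <- effects_from_cells(c(30, 28, 33), c(20, 22, 17), c(25, 24, 26),
                          c(25, 26, 24))
  e$se <- rep(0.3, 3)
  deg <- egger_test(e)
  expect_true(deg$degenerate)
  expect_equal(deg$egger_intercept, mean(e$ln_or / e$se))
  expect_true(is.na(deg$egger_p))
})

test_that("Begg's rank correlation matches metafor's tau and its exact p matches cor.test", {
  skip_if_not_installed("metafor")
  e <- fixture_effects(function(s) rep(TRUE, nrow(s)), "allele")
  got <- begg_test(e)
  ref <- metafor::ranktest(x = e$ln_or, vi = e$se^2, exact = FALSE)
  expect_equal(got$begg_tau, unname(ref$tau), tolerance = 1e-10)
  # metafor omits the +/-1 continuity correction; p-values agree closely
  expect_equal(got$begg_p, unname(ref$pval), tolerance = 0.1)

  e6 <- e[1:6, ]
  ex <- begg_test(e6, exact = TRUE)
  f <- 1 / e6$se^2
  dev <- (e6$ln_or - sum(f * e6$ln_or) / sum(f)) / sqrt(e6$se^2 - 1 / sum(f))
  ct <- suppressWarnings(cor.test(dev, e6$se^2, method = "kendall",
                                  exact = TRUE))
  expect_equal(ex$begg_p_exact, unname(ct$p.value), tolerance = 1e-10)
  expect_error(begg_test(e, exact = TRUE), "k <= 8")
})

test_that("Begg's statistic is a rank statistic: order-invariant, monotone-invariant", {
  e <- fixture_effects(function(s) rep(TRUE, nrow(s)), "dominant")
  base <- begg_test(e)
  shuf <- e[rev(seq_len(nrow(e))), ]
  expect_equal(begg_test(shuf)$begg_tau, base$begg_tau, tolerance = 1e-10)
  expect_equal(begg_test(shuf)$begg_p, base$begg_p, tolerance = 1e-10)
  # tau depends on the variances only through their ranks: recomputing the
  # correlation against any strictly monotone transform of se^2 (deviates
  # held fixed) changes nothing
  f <- 1 / e$se^2
  dev <- (e$ln_or - sum(f * e$ln_or) / sum(f)) / sqrt(e$se^2 - 1 / sum(f))
  tau_raw <- cor(dev, e$se^2, method = "kendall")
  tau_warp <- cor(dev, exp(3 * e$se^2) - 1, method = "kendall")
  expect_equal(tau_warp, tau_raw, tolerance = 1e-12)
  expect_equal(base$begg_tau, tau_raw, tolerance = 1e-10)
})

test_that("perfectly concordant ranks give tau = 1", {
  e <- effects_from_cells(c(10, 30, 90), c(20, 30, 40), c(15, 30, 60),
                          c(15, 30, 70))
  # construct strictly increasing deviates with increasing variances
  e$ln_or <- c(0.1, 0.5, 2.0)
  e$se <- c(0.1, 0.3, 0.9)
  expect_equal(begg_test(e)$begg_tau, 1)
})

test_that("a censored literature of small studies produces detectable funnel asymmetry", {
  rej <- vapply(1:120, function(r) {
    spec <- simulation_spec(k = 20, n_case = c(30, 1000),
                            n_control = c(30, 1000), p_t = 0.45,
                            censor_rule = list(), seed = 52000 + r)
    e <- study_effects(build_model_table(simulate_meta(spec), "allele"))
    egger_test(e)$egger_p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.5)
})

test_that("funnel coordinates cover every study and guides meet the pooled estimate", {
  e <- fixture_effects(function(s) rep(TRUE, nrow(s)), "allele")
  f <- funnel_data(e)
  expect_equal(nrow(f$points), 11)
  expect_equal(f$guides$lower[f$guides$se == 0], f$center)
  expect_equal(f$guides$upper[f$guides$se == 0], f$center)
  one <- funnel_data(e[1, ])
  expect_equal(nrow(one$points), 1)
  expect_equal(one$center, e$ln_or[1])
})
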