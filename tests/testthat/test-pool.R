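test_that("a single study pools to itself", {
  e <- effects_from_cells(30, 20, 25, 25)
  for (res in list(pool_mh(e), pool_iv_fixed(e))) {
    expect_equal(res$or, e$or, tolerance = 1e-10)
    expect_equal(res$k, 1)
  }
  expect_equal(select_and_pool(e)$or, e$or, tolerance = 1e-10)
  expect_null(select_and_pool(e)$het)
})

test_that("Mantel-Haenszel matches an exact rational-arithmetic oracle on small strata", {
  # OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i); with integer cells this
  # equals (sum a_i d_i prod_{j!=i} n_j) / (sum b_i c_i prod_{j!=i} n_j)
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    a <- sample(1:6, k, TRUE); b <- sample(1:6, k, TRUE)
    c <- sample(1:6, k, TRUE); d <- sample(1:6, k, TRUE)
    n <- a + b + c + d
    other <- vapply(seq_len(k), function(i) prod(n[-i]), numeric(1))
    oracle <- sum(a * d * other) / sum(b * c * other)
    got <- pool_mh(effects_from_cells(a, b, c, d))$or
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("the MH pooled OR is bounded by the study ORs", {
  set.seed(23)
  for (rep in 1:200) {
    k <- sample(2:6, 1)
    e <- effects_from_cells(sample(1:50, k, TRUE), sample(1:50, k, TRUE),
                            sample(1:50, k, TRUE), sample(1:50, k, TRUE))
    or <- pool_mh(e)$or
    expect_gte(or, min(e$or) - 1e-12)
    expect_lte(or, max(e$or) + 1e-12)
  }
})

test_that("inverse-variance pooling has the closed form for identical studies", {
  e <- effects_from_cells(c(30, 30), c(20, 20), c(25, 25), c(25, 25))
  res <- pool_iv_fixed(e)
  expect_equal(res$or, e$or[1], tolerance = 1e-12)
  expect_equal(res$se, e$se[1] / sqrt(2), tolerance = 1e-12)
  het <- cochran_q(e)
  expect_equal(het$q, 0)
  expect_equal(het$i2, 0)
  expect_equal(het$tau2, 0)
  # with no dispersion, random effects degenerate to fixed
  dl <- pool_dl(e)
  expect_equal(dl$or, res$or, tolerance = 1e-12)
  expect_equal(dl$se, res$se, tolerance = 1e-12)
})

test_that("MH pooling agrees with metafor's rma.mh on the digestive recessive stratum", {
  skip_if_not_installed("metafor")
  e <- fixture_effects(function(s) cancer_group(s) == "digestive", "recessive")
  got <- pool_mh(e)
  ref <- metafor::rma.mh(ai = e$a, bi = e$b, ci = e$c, di = e$d,
                         measure = "OR", correct = FALSE)
  expect_equal(got$ln_or, as.numeric(coef(ref)), tolerance = 1e-10)
  expect_equal(got$ci_low, exp(ref$ci.lb), tolerance = 1e-8)
  expect_equal(got$ci_high, exp(ref$ci.ub), tolerance = 1e-8)
})

test_that("DL pooling agrees with metafor's DerSimonian-Laird on the European homozygous stratum", {
  skip_if_not_installed("metafor")
  e <- fixture_effects(function(s) s$ethnicity == "European", "homozygous")
  got <- pool_dl(e)
  ref <- metafor::rma(ai = e$a, bi = e$b, ci = e$c, di = e$d,
                      measure = "OR", method = "DL")
  expect_equal(got$ln_or, as.numeric(coef(ref)), tolerance = 1e-10)
  expect_equal(got$het$tau2, ref$tau2, tolerance = 1e-10)
  expect_equal(got$p, ref$pval, tolerance = 1e-10)
})

test_that("the selection rule picks fixed or random effects from the IV-centered Q", {
  breast <- fixture_effects(function(s) cancer_group(s) == "breast",
                            "homozygous")
  res <- select_and_pool(breast)
  expect_equal(res$method, "mh_fixed")
  expect_equal(res$het$center, "chosen")

  euro <- fixture_effects(function(s) s$ethnicity == "European", "homozygous")
  expect_lt(cochran_q(euro)$p_het, 0.05)  # q about 15.2 on 5 df
  res2 <- select_and_pool(euro)
  expect_equal(res2$method, "dl_random")
  expect_equal(res2$het$center, "iv")
  # threshold is honoured: an extreme alpha forces the fixed route
  expect_equal(select_and_pool(euro, alpha_het = 1e-6)$method, "mh_fixed")
})

test_that("random-effects intervals are never narrower than fixed-effect ones", {
  set.seed(41)
  for (rep in 1:60) {
    k <- sample(3:8, 1)
    e <- effects_from_cells(sample(5:60, k, TRUE), sample(5:60, k, TRUE),
                            sample(5:60, k, TRUE), sample(5:60, k, TRUE))
    dl <- pool_dl(e); iv <- pool_iv_fixed(e)
    expect_gte(dl$se, iv$se - 1e-12)
    if (dl$het$tau2 == 0) expect_equal(dl$se, iv$se, tolerance = 1e-12)
  }
})

test_that("tau2 recovery: DL estimates the injected between-study variance", {
  tau <- 0.3
  tau2_hat <- vapply(1:300, function(r) {
    spec <- simulation_spec(k = 30, n_case = 2000, n_control = 2000,
                            p_t = 0.45, or_hom = 1.5, or_het = 1.2,
                            tau = tau, seed = 3000 + r)
    e <- study_effects(build_model_table(simulate_meta(spec), "homozygous"))
    cochran_q(e)$tau2
  }, numeric(1))
  expect_equal(mean(tau2_hat), tau^2, tolerance = 0.2)
})

test_that("degenerate pooling inputs raise errors", {
  e <- effects_from_cells(30, 20, 25, 25)
  expect_error(cochran_q(e), "fewer than two")
  expect_error(pool_dl(e), "at least two")
  expect_error(select_and_pool(e[0, ]), "no studies")
})
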