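# shared fixtures, built once per test run

fixture_set <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- cxcr2_studies()
    cached
  }
})

# minimal valid study table for constructing edge cases
tiny_studies <- function(case = c(10, 20, 10), control = c(12, 26, 14),
                         n = 1, cancer_type = "GC") {
  df <- data.frame(author = paste0("A", seq_len(n)), year = 2000 + seq_len(n),
                   origin = "X", cancer_type = cancer_type,
                   ethnicity = "European", control_source = "PB",
                   genotyping_method = "PCR",
                   case_tt = case[1], case_tc = case[2], case_cc = case[3],
                   control_tt = control[1], control_tc = control[2],
                   control_cc = control[3], stringsAsFactors = FALSE)
  study_set(df)
}

# effects table built straight from cell counts, bypassing genotype data
effects_from_cells <- function(a, b, c, d, ...) {
  study_effects(data.frame(a = a, b = b, c = c, d = d), ...)
}

# per-study effects for a fixture subset under one genetic model
fixture_effects <- function(rows, model) {
  set <- fixture_set()
  study_effects(build_model_table(set[rows(set), , drop = FALSE], model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent exact-HWE oracle: conditional distribution of genotype
# configurations given the allele counts, from multinomial HWE
# probabilities at an arbitrary allele frequency (conditioning cancels it)
oracle_exact_p <- function(tt, tc, cc, p = 0.37) {
  n <- tt + tc + cc
  nT <- 2 * tt + tc
  cfg <- expand.grid(t = 0:n, h = 0:n)
  cfg <- cfg[cfg$t + cfg$h <= n & 2 * cfg$t + cfg$h == nT, ]
  pr <- mapply(function(t, h)
    dmultinom(c(t, h, n - t - h), prob = c(p^2, 2 * p * (1 - p), (1 - p)^2)),
    cfg$t, cfg$h)
  pr <- pr / sum(pr)
  obs <- pr[cfg$t == tt & cfg$h == tc]
  sum(pr[pr <= obs * (1 + 1e-9)])
}
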