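#' Specify a synthetic case-control genotype simulation
#'
#' Defines the data-generating model for synthetic studies: controls are
#' drawn multinomially from genotype probabilities (p^2, 2pq, q^2) for
#' control T-allele frequency p, optionally perturbed by a disequilibrium
#' shift \code{hwe_d} added to the heterozygote class and removed equally
#' from the two homozygote classes (so the allele frequency is preserved);
#' case genotype probabilities are the control probabilities times the
#' genotype odds ratios (or_hom, or_het, 1), renormalized - the
#' retrospective sampling model of a case-control design, under which the
#' target odds ratios are exact functionals of the sampling
#' probabilities. When \code{tau > 0}, a single study-level normal deviate
#' of standard deviation tau is added to both genotype log odds ratios,
#' giving correlated between-study heterogeneity across all model
#' contrasts.
#'
#' @param k Number of studies.
#' @param n_case,n_control Per-arm sizes: a single number, or a length-2
#'   range sampled uniformly per study.
#' @param p_t Control T-allele frequency in (0, 1).
#' @param or_het Genotype odds ratio TC vs CC (default 1).
#' @param or_hom Genotype odds ratio TT vs CC (default 1).
#' @param hwe_d Heterozygote disequilibrium shift (default 0 = HWE).
#' @param tau Between-study SD of the genotype log odds ratios (default 0).
#' @param censor_rule Optional small-study publication-censoring rule for
#'   bias simulations: a list with elements \code{model} (contrast tested,
#'   default \code{"allele"}), \code{alpha} (one-sided significance level
#'   for a positive association, default 0.05), \code{keep_nonsig}
#'   (probability a non-significant small study is still retained,
#'   default 0.02, i.e. strong selection) and \code{large_n} (combined
#'   case + control size at and
#'   above which a study is always retained, default 1000 - the same
#'   cutoff as \code{\link{size_class}}). Candidate studies are redrawn
#'   until k are retained.
#' @param seed Integer seed; every study derives a deterministic substream
#'   from it, keyed by study index.
#' @return A \code{simulation_spec} list.
#' @export
simulation_spec <- function(k = 10, n_case = 500, n_control = 500,
                            p_t = 0.45, or_het = 1, or_hom = 1,
                            hwe_d = 0, tau = 0, censor_rule = NULL,
                            seed = 1L) {
  stopifnot(k >= 1, p_t > 0, p_t < 1, or_het > 0, or_hom > 0, tau >= 0,
            all(n_case >= 1), all(n_control >= 1))
  pr <- .control_probs(p_t, hwe_d)
  if (any(pr < 0) || any(pr > 1))
    stop("hwe_d = ", hwe_d, " pushes a genotype probability outside [0, 1]",
         call. = FALSE)
  if (!is.null(censor_rule)) {
    censor_rule <- utils::modifyList(
      list(model = "allele", alpha = 0.05, keep_nonsig = 0.02,
           large_n = 1000), censor_rule)
  }
  structure(list(k = k, n_case = n_case, n_control = n_control, p_t = p_t,
                 or_het = or_het, or_hom = or_hom, hwe_d = hwe_d, tau = tau,
                 censor_rule = censor_rule, seed = as.integer(seed)),
            class = "simulation_spec")
}

# genotype order: (TT, TC, CC)
.control_probs <- function(p, d) {
  q <- 1 - p
  c(p^2 - d / 2, 2 * p * q + d, q^2 - d / 2)
}

.study_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) + 104729 * index + 15485863 * salt) %%
             2147483647)
}

.draw_arm <- function(n, probs) {
  as.integer(rmultinom(1, n, probs))
}

.sample_size <- function(n) {
  if (length(n) == 2) sample(seq(n[1], n[2]), 1) else n
}

.sim_labels <- function(i) {
  map <- cancer_group_map()
  data.frame(author = sprintf("Sim%02d", i), year = 1990L + i,
             origin = "synthetic",
             cancer_type = map$cancer_type[1 + (i - 1) %% nrow(map)],
             ethnicity = .ethnicities[1 + (i - 1) %% length(.ethnicities)],
             control_source = .control_sources[1 + (i - 1) %% 2],
             genotyping_method = "simulated", stringsAsFactors = FALSE)
}

#' Simulate one case-control genotype study
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @param index Study index (keys the deterministic random substream).
#' @return A one-row \code{\link{study_set}}.
#' @export
simulate_study <- function(spec, index = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(.study_seed(spec$seed, index))
  row <- .sim_study_row(spec, index)
  study_set(row, label = sprintf("simulated study %d", index))
}

.sim_study_row <- function(spec, index, nca = NULL, nco = NULL) {
  ctrl_p <- .control_probs(spec$p_t, spec$hwe_d)
  u <- if (spec$tau > 0) rnorm(1, 0, spec$tau) else 0
  w <- ctrl_p * c(spec$or_hom * exp(u), spec$or_het * exp(u), 1)
  case_p <- w / sum(w)
  if (is.null(nca)) nca <- .sample_size(spec$n_case)
  if (is.null(nco)) nco <- .sample_size(spec$n_control)
  ca <- .draw_arm(nca, case_p)
  co <- .draw_arm(nco, ctrl_p)
  cbind(.sim_labels(index),
        data.frame(case_tt = ca[1], case_tc = ca[2], case_cc = ca[3],
                   control_tt = co[1], control_tc = co[2],
                   control_cc = co[3],
                   age_case = "NA", age_control = "NA"))
}

#' Simulate a multi-study set with known truth
#'
#' Draws \code{k} independent studies under the spec's data-generating
#' model, filling metadata with synthetic labels that cycle through the
#' stratification vocabularies so subgroup machinery can be exercised.
#' When a \code{censor_rule} is active, each candidate study is retained
#' only if its chosen contrast is one-sided significant for a positive
#' association (or with probability \code{keep_nonsig} otherwise),
#' emulating small-study publication bias; candidates are drawn until k
#' are retained.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @return A \code{\link{study_set}} of k studies.
#' @export
simulate_meta <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  rows <- vector("list", spec$k)
  if (is.null(spec$censor_rule)) {
    # uncensored studies share substreams with simulate_study(spec, i)
    for (i in seq_len(spec$k)) {
      set.seed(.study_seed(spec$seed, i))
      rows[[i]] <- .sim_study_row(spec, i)
    }
  } else {
    # each study slot keeps its drawn size; only the outcome is redrawn
    # until the censoring rule retains it, emulating a literature whose
    # small studies surface only when significant
    for (i in seq_len(spec$k)) {
      set.seed(.study_seed(spec$seed, i, salt = 1L))
      nca <- .sample_size(spec$n_case)
      nco <- .sample_size(spec$n_control)
      for (try in seq_len(1000L)) {
        row <- .sim_study_row(spec, i, nca = nca, nco = nco)
        if (.retain(row, spec$censor_rule)) break
        if (try == 1000L)
          stop("censor_rule retained no draw for a study slot; relax the rule",
               call. = FALSE)
      }
      rows[[i]] <- row
    }
  }
  study_set(do.call(rbind, rows),
            label = sprintf("simulated meta-set (k = %d, seed = %d)",
                            spec$k, spec$seed))
}

.retain <- function(row, rule) {
  n_total <- row$case_tt + row$case_tc + row$case_cc +
    row$control_tt + row$control_tc + row$control_cc
  if (n_total >= rule$large_n) return(TRUE)
  cells <- .model_cells(row, rule$model)
  cells <- cells + 0.5 * any(cells == 0)
  z <- (log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])) /
    sqrt(sum(1 / cells))
  if (pnorm(z, lower.tail = FALSE) < rule$alpha) TRUE
  else stats::runif(1) < rule$keep_nonsig
}

.model_cells <- function(row, model) {
  with(row, switch(model,
    allele = c(2 * case_tt + case_tc, 2 * case_cc + case_tc,
               2 * control_tt + control_tc, 2 * control_cc + control_tc),
    heterozygous = c(case_tc, case_cc, control_tc, control_cc),
    homozygous = c(case_tt, case_cc, control_tt, control_cc),
    dominant = c(case_tt + case_tc, case_cc, control_tt + control_tc,
                 control_cc),
    recessive = c(case_tt, case_tc + case_cc, control_tt,
                  control_tc + control_cc)))
}

#' True model-contrast odds ratios implied by a simulation spec
#'
#' The population odds ratio of each genetic-model contrast under the
#' spec's sampling probabilities (tau = 0, no censoring), computed in
#' closed form from the case and control genotype probabilities.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @return Named numeric vector over \code{\link{genetic_models}}.
#' @export
true_model_or <- function(spec) {
  co <- .control_probs(spec$p_t, spec$hwe_d)
  w <- co * c(spec$or_hom, spec$or_het, 1)
  ca <- w / sum(w)
  odds <- function(p) p / (1 - p)
  c(allele = odds((2 * ca[1] + ca[2]) / 2) / odds((2 * co[1] + co[2]) / 2),
    heterozygous = (ca[2] / ca[3]) / (co[2] / co[3]),
    homozygous = (ca[1] / ca[3]) / (co[1] / co[3]),
    dominant = ((ca[1] + ca[2]) / ca[3]) / ((co[1] + co[2]) / co[3]),
    recessive = odds(ca[1]) / odds(co[1]))
}
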