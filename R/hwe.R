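#' Hardy-Weinberg chi-squared goodness-of-fit test
#'
#' Tests genotype counts (tt, tc, cc) against the Hardy-Weinberg
#' proportions p^2, 2pq, q^2 implied by the observed T-allele frequency,
#' with a 1-df chi-squared statistic and no continuity correction. A
#' monomorphic sample (allele frequency 0 or 1) is reported as chi2 = 0,
#' p = 1 and flagged.
#'
#' @param tt,tc,cc Genotype counts (vectors are accepted and recycled
#'   element-wise).
#' @return A data frame with columns \code{chi2}, \code{p},
#'   \code{allele_freq} (T-allele frequency) and \code{monomorphic}.
#' @examples
#' hwe_chisq(66, 108, 34)  # p = 0.359
#' @export
hwe_chisq <- function(tt, tc, cc) {
  n <- tt + tc + cc
  stopifnot(all(n > 0))
  p <- (2 * tt + tc) / (2 * n)
  mono <- p == 0 | p == 1
  e_tt <- n * p^2
  e_tc <- 2 * n * p * (1 - p)
  e_cc <- n * (1 - p)^2
  chi2 <- ifelse(mono, 0,
                 (tt - e_tt)^2 / e_tt + (tc - e_tc)^2 / e_tc +
                 (cc - e_cc)^2 / e_cc)
  pval <- ifelse(mono, 1, pchisq(chi2, df = 1, lower.tail = FALSE))
  data.frame(chi2 = chi2, p = pval, allele_freq = p, monomorphic = mono)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, sums the
#' probabilities of all heterozygote counts (of matching parity) whose
#' conditional probability does not exceed that of the observed
#' configuration. Provided alongside \code{\link{hwe_chisq}}; the
#' chi-squared test is the package default.
#'
#' @inheritParams hwe_chisq
#' @return As \code{\link{hwe_chisq}} (single observation only).
#' @export
hwe_exact <- function(tt, tc, cc) {
  stopifnot(length(tt) == 1, length(tc) == 1, length(cc) == 1)
  n <- tt + tc + cc
  stopifnot(n > 0)
  nT <- 2 * tt + tc
  nC <- 2 * cc + tc
  p <- nT / (2 * n)
  if (nT == 0 || nC == 0)
    return(data.frame(chi2 = 0, p = 1, allele_freq = p, monomorphic = TRUE))
  # P(h heterozygotes | allele counts) proportional to
  #   2^h * n! / ((nT-h)/2)! h! ((nC-h)/2)!
  h <- seq(nT %% 2, min(nT, nC), by = 2)
  logp <- h * log(2) - lfactorial((nT - h) / 2) - lfactorial(h) -
    lfactorial((nC - h) / 2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[h == tc]
  pval <- min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
  data.frame(chi2 = NA_real_, p = pval, allele_freq = p, monomorphic = FALSE)
}

#' Hardy-Weinberg QC report for a study set
#'
#' Runs the HWE test on both arms of every study.
#'
#' @param set A \code{\link{study_set}}.
#' @param test \code{"chisq"} (default) or \code{"exact"}.
#' @return Data frame: study_id, arm, chi2, p, allele_freq, monomorphic.
#' @export
hwe_report <- function(set, test = c("chisq", "exact")) {
  test <- match.arg(test)
  one_arm <- function(tt, tc, cc) {
    if (test == "chisq") hwe_chisq(tt, tc, cc)
    else do.call(rbind, Map(hwe_exact, tt, tc, cc))
  }
  ca <- one_arm(set$case_tt, set$case_tc, set$case_cc)
  co <- one_arm(set$control_tt, set$control_tc, set$control_cc)
  rbind(cbind(study_id = set$study_id, arm = "cases", ca),
        cbind(study_id = set$study_id, arm = "controls", co))
}

#' Hardy-Weinberg inclusion filter
#'
#' Applies the standard meta-analytic QC rule: a study is excluded when its
#' CONTROL arm deviates from Hardy-Weinberg equilibrium at the given
#' threshold. Case-arm deviation is flagged in the report but never
#' excludes a study (cases are not expected to be in equilibrium when the
#' variant is associated with disease).
#'
#' @param set A \code{\link{study_set}}.
#' @param alpha Exclusion threshold on the control-arm HWE p-value
#'   (default 0.05).
#' @param test \code{"chisq"} (default) or \code{"exact"}.
#' @return A list: \code{retained} (study_set), \code{excluded}
#'   (data frame of dropped studies with their control p), and
#'   \code{case_flags} (study_ids whose case arm deviates).
#' @export
hwe_filter <- function(set, alpha = 0.05, test = c("chisq", "exact")) {
  test <- match.arg(test)
  rep <- hwe_report(set, test)
  ctrl <- rep[rep$arm == "controls", ]
  case <- rep[rep$arm == "cases", ]
  drop <- ctrl$p < alpha
  excluded <- data.frame(study_id = ctrl$study_id[drop],
                         control_p = ctrl$p[drop])
  retained <- set[!drop, , drop = FALSE]
  if (nrow(retained) == 0)
    stop("all studies excluded by the HWE filter", call. = FALSE)
  list(retained = retained, excluded = excluded,
       case_flags = case$study_id[case$p < alpha])
}

#' Pooled allele frequency across studies
#'
#' Count-weighted T-allele frequency over an arm of a study set:
#' (sum of 2*tt + tc) / (2 * sum of totals). This is the "MAF" figure
#' conventionally quoted for the pooled sample, expressed as the T-allele
#' frequency regardless of whether T is the minor allele.
#'
#' @param set A \code{\link{study_set}}.
#' @param arm \code{"cases"} or \code{"controls"}.
#' @return A single frequency in [0, 1].
#' @examples
#' round(pooled_allele_freq(cxcr2_studies(), "controls"), 3)  # 0.479
#' @export
pooled_allele_freq <- function(set, arm = c("cases", "controls")) {
  arm <- match.arg(arm)
  if (arm == "cases")
    sum(2 * set$case_tt + set$case_tc) / (2 * sum(set$n_case))
  else
    sum(2 * set$control_tt + set$control_tc) / (2 * sum(set$n_control))
}

#' Reference population allele frequencies for CXCR2 C1208T
#'
#' Published HapMap population frequencies of the T allele, shipped as
#' reference metadata only (never computed by this package).
#'
#' @return Named numeric vector of allele frequencies.
#' @export
hapmap_maf <- function() {
  c(African = 0.078, American = 0.461, European = 0.455,
    global = 0.346, Asian = 0.650)
}
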