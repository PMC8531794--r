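z975 <- function() qnorm(0.975)

new_pooled <- function(est, se, method, k, weights, het = NULL) {
  z <- z975()
  structure(list(
    or = exp(est), ln_or = est, se = se,
    ci_low = exp(est - z * se), ci_high = exp(est + z * se),
    p = 2 * pnorm(-abs(est / se)),
    method = method, k = k, weights = weights, het = het),
    class = "pooled_result")
}

iv_parts <- function(effects) {
  w <- 1 / effects$se^2
  list(w = w, est = sum(w * effects$ln_or) / sum(w), se = 1 / sqrt(sum(w)))
}

#' Mantel-Haenszel fixed-effect pooled odds ratio
#'
#' Stratified cross-product estimator OR = sum(a_i d_i / n_i) /
#' sum(b_i c_i / n_i) on the uncorrected cells, with the
#' Robins-Breslow-Greenland variance for its log and a Wald 95\% CI and
#' z-test. Zero cells are tolerated without correction (the estimator is
#' defined whenever some stratum contributes to each sum).
#'
#' @param effects A \code{\link{study_effects}} data frame.
#' @return A \code{pooled_result} with method \code{"mh_fixed"}. Weights
#'   are the per-stratum cross products b_i c_i / n_i (the MH denominator
#'   contributions).
#' @export
pool_mh <- function(effects) {
  a <- effects$a; b <- effects$b; c <- effects$c; d <- effects$d
  n <- a + b + c + d
  R <- a * d / n; S <- b * c / n
  if (sum(R) == 0 || sum(S) == 0)
    stop("Mantel-Haenszel estimator undefined: a cross-product sum is zero",
         call. = FALSE)
  P <- (a + d) / n; Q <- (b + c) / n
  est <- log(sum(R) / sum(S))
  v <- sum(P * R) / (2 * sum(R)^2) +
       sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
       sum(Q * S) / (2 * sum(S)^2)
  new_pooled(est, sqrt(v), "mh_fixed", nrow(effects), S)
}

#' Inverse-variance fixed-effect pooling
#'
#' Weighted mean of study log odds ratios with Woolf weights 1/se^2. This
#' is the weighting basis for Cochran's Q and the DerSimonian-Laird
#' between-study variance; the Mantel-Haenszel estimator is the package's
#' reporting fixed-effect method.
#'
#' @inheritParams pool_mh
#' @return A \code{pooled_result} with method \code{"iv_fixed"}.
#' @export
pool_iv_fixed <- function(effects) {
  f <- iv_parts(effects)
  new_pooled(f$est, f$se, "iv_fixed", nrow(effects), f$w)
}

#' Cochran's Q, I-squared and the DerSimonian-Laird tau-squared
#'
#' Q is the inverse-variance weighted sum of squared deviations of study
#' log odds ratios about a pooled estimate. By default Q is centered at
#' the inverse-variance fixed estimate (the classical definition, used for
#' fixed/random model selection and for tau^2); a different center may be
#' supplied, e.g. the Mantel-Haenszel estimate when reporting
#' heterogeneity alongside an MH result. tau^2 is always the
#' DerSimonian-Laird moment estimator from the IV-centered Q, whatever
#' center is used for the reported Q.
#'
#' @inheritParams pool_mh
#' @param center_ln_or Optional log-OR about which Q is computed; default
#'   the inverse-variance fixed estimate.
#' @return A \code{heterogeneity} object: \code{q}, \code{df},
#'   \code{p_het}, \code{i2} (percent), \code{tau2}, \code{center}
#'   (\code{"iv"} or \code{"chosen"}).
#' @export
cochran_q <- function(effects, center_ln_or = NULL) {
  k <- nrow(effects)
  if (k < 2)
    stop("heterogeneity is undefined for fewer than two studies",
         call. = FALSE)
  f <- iv_parts(effects)
  q_iv <- sum(f$w * (effects$ln_or - f$est)^2)
  C <- sum(f$w) - sum(f$w^2) / sum(f$w)
  tau2 <- max(0, (q_iv - (k - 1)) / C)
  if (is.null(center_ln_or)) {
    q <- q_iv; center <- "iv"
  } else {
    q <- sum(f$w * (effects$ln_or - center_ln_or)^2); center <- "chosen"
  }
  structure(list(q = q, df = k - 1,
                 p_het = pchisq(q, k - 1, lower.tail = FALSE),
                 i2 = 100 * max(0, (q - (k - 1)) / q),
                 tau2 = tau2, center = center),
            class = "heterogeneity")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Adds the moment-based between-study variance tau^2 (from the
#' IV-centered Q) to each study's Woolf variance, then pools by inverse
#' variance.
#'
#' @inheritParams pool_mh
#' @return A \code{pooled_result} with method \code{"dl_random"} and the
#'   IV-centered \code{heterogeneity} attached.
#' @export
pool_dl <- function(effects) {
  if (nrow(effects) < 2)
    stop("random-effects pooling requires at least two studies",
         call. = FALSE)
  het <- cochran_q(effects)
  w <- 1 / (effects$se^2 + het$tau2)
  est <- sum(w * effects$ln_or) / sum(w)
  new_pooled(est, 1 / sqrt(sum(w)), "dl_random", nrow(effects), w, het)
}

#' Pool with the heterogeneity-driven model-selection rule
#'
#' Computes Cochran's Q about the inverse-variance fixed estimate; if its
#' p-value falls below \code{alpha_het} the DerSimonian-Laird
#' random-effects model is used, otherwise Mantel-Haenszel fixed effects.
#' A single study bypasses selection (its own effect is returned as a
#' fixed-effect result with no heterogeneity). The attached heterogeneity
#' follows the reporting convention of the classic meta-analysis software:
#' Q about the MH estimate when MH is chosen, the IV-centered Q when
#' random effects are chosen (tau^2 always derives from the IV-centered
#' Q).
#'
#' @inheritParams pool_mh
#' @param alpha_het Heterogeneity p-value threshold below which random
#'   effects are selected (default 0.05).
#' @return A \code{pooled_result}.
#' @examples
#' set <- cxcr2_studies()
#' eff <- study_effects(build_model_table(set[cancer_group(set) == "breast", ],
#'                                        "homozygous"))
#' select_and_pool(eff)  # fixed effects, OR 1.56
#' @export
select_and_pool <- function(effects, alpha_het = 0.05) {
  k <- nrow(effects)
  if (k < 1) stop("no studies to pool", call. = FALSE)
  if (k == 1) return(pool_mh(effects))
  sel <- cochran_q(effects)  # IV-centered
  if (sel$p_het < alpha_het) {
    pool_dl(effects)
  } else {
    res <- pool_mh(effects)
    res$het <- cochran_q(effects, center_ln_or = res$ln_or)
    res
  }
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("pooled OR [%s, k = %d]: %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$method, x$k, x$or, x$ci_low, x$ci_high, x$p))
  if (!is.null(x$het)) print(x$het)
  invisible(x)
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf(
    "heterogeneity: Q = %.3f (df = %d, p = %.4g), I2 = %.1f%%, tau2 = %.4f [%s-centered]\n",
    x$q, x$df, x$p_het, x$i2, x$tau2, x$center))
  invisible(x)
}
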