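#' Leave-one-out sensitivity analysis
#'
#' Re-runs \code{\link{select_and_pool}} from scratch on every subset that
#' omits one study, re-selecting the fixed/random model per subset.
#'
#' @inheritParams pool_mh
#' @param alpha_het Heterogeneity threshold passed through to
#'   \code{\link{select_and_pool}}.
#' @return Data frame with one row per omitted study: \code{omitted_study},
#'   \code{method}, \code{or}, \code{ci_low}, \code{ci_high}, \code{p},
#'   \code{p_het}.
#' @export
leave_one_out <- function(effects, alpha_het = 0.05) {
  k <- nrow(effects)
  if (k < 3)
    stop("leave-one-out sensitivity needs at least three studies",
         call. = FALSE)
  rows <- lapply(seq_len(k), function(i) {
    r <- select_and_pool(effects[-i, , drop = FALSE], alpha_het)
    data.frame(omitted_study = effects$study_id[i], method = r$method,
               or = r$or, ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
               p_het = if (is.null(r$het)) NA_real_ else r$het$p_het,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect (ln OR / se) on
#' precision (1 / se); the intercept is tested against zero with a t-test
#' on k - 2 degrees of freedom. A significantly non-zero intercept
#' indicates small-study asymmetry. When all standard errors are equal the
#' precision predictor is constant: the slope is undefined, the intercept
#' is reported as the mean standardized effect and the result is flagged
#' degenerate with p = NA.
#'
#' @inheritParams pool_mh
#' @return A \code{bias_result} with \code{egger_intercept},
#'   \code{egger_se}, \code{egger_p}, \code{k}, \code{degenerate}.
#' @export
egger_test <- function(effects) {
  k <- nrow(effects)
  if (k < 3) stop("Egger's test needs at least three studies", call. = FALSE)
  zstd <- effects$ln_or / effects$se
  prec <- 1 / effects$se
  if (max(prec) - min(prec) < 1e-12) {
    return(structure(list(egger_intercept = mean(zstd), egger_se = NA_real_,
                          egger_p = NA_real_, k = k, degenerate = TRUE),
                     class = "bias_result"))
  }
  fit <- lm(zstd ~ prec)
  sm <- summary(fit)$coefficients
  structure(list(egger_intercept = sm["(Intercept)", "Estimate"],
                 egger_se = sm["(Intercept)", "Std. Error"],
                 egger_p = sm["(Intercept)", "Pr(>|t|)"],
                 k = k, degenerate = FALSE),
            class = "bias_result")
}

kendall_S <- function(x, y) {
  k <- length(x)
  s <- 0
  for (i in seq_len(k - 1))
    for (j in (i + 1):k)
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  s
}

#' Begg rank-correlation test for publication bias
#'
#' Kendall rank correlation between the variance-stabilized effect
#' deviates (ln OR_i - IV-fixed pooled) / sqrt(se_i^2 - 1/sum w) and the
#' study variances se_i^2, with the tie-corrected normal approximation and
#' a +/-1 continuity correction. For small k an exact permutation p-value
#' over all orderings is available.
#'
#' @inheritParams pool_mh
#' @param exact Compute the exact permutation p-value (only allowed for
#'   k <= 8; default \code{FALSE}).
#' @return A \code{bias_result} with \code{begg_tau} (tie-corrected
#'   tau-b), \code{begg_p}, \code{k}, and \code{begg_p_exact} when
#'   requested.
#' @export
begg_test <- function(effects, exact = FALSE) {
  k <- nrow(effects)
  if (k < 3) stop("Begg's test needs at least three studies", call. = FALSE)
  f <- iv_parts(effects)
  vstar <- effects$se^2 - 1 / sum(f$w)
  vstar <- pmax(vstar, .Machine$double.eps)
  dev <- (effects$ln_or - f$est) / sqrt(vstar)
  v <- effects$se^2
  S <- kendall_S(dev, v)
  tie_terms <- function(x) {
    t <- table(x); t <- t[t > 1]
    c(sum(t * (t - 1) * (2 * t + 5)), sum(t * (t - 1)), sum(t * (t - 1) * (t - 2)))
  }
  tx <- tie_terms(dev); ty <- tie_terms(v)
  n0 <- k * (k - 1) / 2
  varS <- (k * (k - 1) * (2 * k + 5) - tx[1] - ty[1]) / 18 +
    tx[3] * ty[3] / (9 * k * (k - 1) * (k - 2)) +
    tx[2] * ty[2] / (2 * k * (k - 1))
  tau <- S / sqrt((n0 - tx[2] / 2) * (n0 - ty[2] / 2))
  z <- if (S == 0) 0 else (abs(S) - 1) / sqrt(varS)
  res <- list(begg_tau = tau, begg_p = min(1, 2 * pnorm(-abs(z))), k = k)
  if (exact) {
    if (k > 8) stop("exact permutation p only supported for k <= 8",
                    call. = FALSE)
    perms <- .permutations(k)
    rv <- rank(v)
    Sdist <- apply(perms, 1, function(p) kendall_S(dev[p], rv))
    res$begg_p_exact <- mean(abs(Sdist) >= abs(S))
  }
  structure(res, class = "bias_result")
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Funnel-plot coordinates
#'
#' Per-study (ln OR, se) points plus pseudo-confidence guide lines
#' (pooled estimate +/- z * se over the observed se range, evaluated at
#' se = 0 they meet the pooled estimate). The center is the
#' inverse-variance fixed pooled estimate.
#'
#' @inheritParams pool_mh
#' @param conf_level Guide-line confidence level (default 0.95).
#' @return A list: \code{points} (study_id, ln_or, se), \code{center}
#'   (pooled ln OR) and \code{guides} (se grid with lower/upper lines).
#' @export
funnel_data <- function(effects, conf_level = 0.95) {
  est <- if (nrow(effects) == 1) effects$ln_or else iv_parts(effects)$est
  z <- qnorm(1 - (1 - conf_level) / 2)
  se_grid <- seq(0, max(effects$se) * 1.05, length.out = 50)
  list(points = data.frame(study_id = effects$study_id,
                           ln_or = effects$ln_or, se = effects$se,
                           stringsAsFactors = FALSE),
       center = est,
       guides = data.frame(se = se_grid, lower = est - z * se_grid,
                           upper = est + z * se_grid))
}

#' @export
print.bias_result <- function(x, ...) {
  if (!is.null(x$egger_intercept))
    cat(sprintf("Egger: intercept = %.3f (se %.3f), p = %.4g, k = %d%s\n",
                x$egger_intercept, x$egger_se, x$egger_p, x$k,
                if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  if (!is.null(x$begg_tau))
    cat(sprintf("Begg: tau = %.3f, p = %.4g, k = %d\n",
                x$begg_tau, x$begg_p, x$k))
  invisible(x)
}
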