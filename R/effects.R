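#' Per-study odds ratios with Woolf standard errors
#'
#' Computes each study's odds ratio (a*d)/(b*c), its log, the Woolf
#' standard error sqrt(1/a + 1/b + 1/c + 1/d) and a 95\% Wald confidence
#' interval. When any cell of a table is zero, 0.5 is added to all four
#' cells of that table (Woolf-Haldane continuity correction) before both
#' the estimate and the variance; the uncorrected cells are retained for
#' Mantel-Haenszel pooling, which does not require the correction.
#'
#' @param tables A \code{model_tables} data frame from
#'   \code{\link{build_model_table}}, or any data frame with integer
#'   columns \code{a}, \code{b}, \code{c}, \code{d} (and optionally
#'   \code{study_id}, \code{model}).
#' @param correction Continuity constant added to all cells of a table
#'   containing a zero (default 0.5).
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return A data frame (class \code{study_effects}) with the uncorrected
#'   cells plus \code{or}, \code{ln_or}, \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{corrected}.
#' @examples
#' tabs <- build_model_table(cxcr2_studies(), "homozygous")
#' study_effects(tabs)
#' @export
study_effects <- function(tables, correction = 0.5, conf_level = 0.95) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  if (any((a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0))
    stop("degenerate 2x2 table: an entire row or column is empty",
         call. = FALSE)
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  k <- ifelse(corrected, correction, 0)
  aa <- a + k; bb <- b + k; cc <- c + k; dd <- d + k
  ln_or <- log(aa) + log(dd) - log(bb) - log(cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    study_id = if ("study_id" %in% names(tables)) tables$study_id
               else paste0("study_", seq_along(a)),
    model = if ("model" %in% names(tables)) tables$model else NA_character_,
    a = a, b = b, c = c, d = d,
    or = exp(ln_or), ln_or = ln_or, se = se,
    ci_low = exp(ln_or - z * se), ci_high = exp(ln_or + z * se),
    corrected = corrected, stringsAsFactors = FALSE)
  class(out) <- c("study_effects", "data.frame")
  out
}

#' @rdname study_effects
#' @export
study_effect <- study_effects
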