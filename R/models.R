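#' The five genetic-model contrasts
#'
#' Closed set of the contrasts used at a biallelic locus with risk allele T:
#' allelic (T vs C allele), heterozygous (TC vs CC), homozygous (TT vs CC),
#' dominant (TT+TC vs CC) and recessive (TT vs TC+CC).
#'
#' @export
genetic_models <- c("allele", "heterozygous", "homozygous",
                    "dominant", "recessive")

#' Build 2x2 exposure tables under a genetic model
#'
#' Collapses each study's three genotype counts into the 2x2 table of the
#' requested contrast, with the risk category ("exposed") as the first
#' column: cell \code{a} = exposed cases, \code{b} = unexposed cases,
#' \code{c} = exposed controls, \code{d} = unexposed controls. The allelic
#' contrast counts alleles (2 per subject); homozygous and heterozygous
#' contrasts drop the excluded genotype class. The risk allele is fixed as
#' T; there is no automatic minor-allele flipping.
#'
#' @param set A \code{\link{study_set}}.
#' @param model One of \code{\link{genetic_models}}.
#' @return A data frame (class \code{model_tables}) with one row per study:
#'   \code{study_id}, \code{model}, \code{a}, \code{b}, \code{c}, \code{d},
#'   \code{n}.
#' @examples
#' tabs <- build_model_table(cxcr2_studies(), "recessive")
#' tabs[tabs$study_id == "Kamangar 2006 GC", ]
#' @export
build_model_table <- function(set, model = genetic_models) {
  model <- match.arg(model)
  ct <- set$case_tt; ch <- set$case_tc; cc <- set$case_cc
  kt <- set$control_tt; kh <- set$control_tc; kc <- set$control_cc
  cells <- switch(model,
    allele       = list(a = 2 * ct + ch, b = 2 * cc + ch,
                        c = 2 * kt + kh, d = 2 * kc + kh),
    heterozygous = list(a = ch, b = cc, c = kh, d = kc),
    homozygous   = list(a = ct, b = cc, c = kt, d = kc),
    dominant     = list(a = ct + ch, b = cc, c = kt + kh, d = kc),
    recessive    = list(a = ct, b = ch + cc, c = kt, d = kh + kc))
  out <- data.frame(study_id = set$study_id, model = model,
                    a = cells$a, b = cells$b, c = cells$c, d = cells$d,
                    stringsAsFactors = FALSE)
  out$n <- out$a + out$b + out$c + out$d
  class(out) <- c("model_tables", "data.frame")
  out
}

#' Export model tables for all five contrasts in long format
#'
#' @param set A \code{\link{study_set}}.
#' @param models Subset of \code{\link{genetic_models}}.
#' @return Long-format data frame: study_id, model, a, b, c, d, n.
#' @export
model_tables <- function(set, models = genetic_models) {
  out <- do.call(rbind, lapply(models, function(m) build_model_table(set, m)))
  class(out) <- c("model_tables", "data.frame")
  out
}
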