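# Evidence-strength scale shared by the PS4 (odds-ratio) and PP4 (OddsPath)
# engines. Strengths are ordered; banding is half-open on the left.

.strengths <- c("not_met", "supporting", "moderate", "strong", "very_strong")

.strength_rank <- function(x) {
  r <- match(x, .strengths)
  if (anyNA(r)) stop("unknown evidence strength: ", paste(x[is.na(r)], collapse = ", "))
  r
}

#' Tavtigian evidence-strength thresholds
#'
#' Thresholds on a likelihood-ratio scale (odds of pathogenicity) that map a
#' positive statistic to ACMG/AMP evidence strength: supporting (>= 2.08),
#' moderate (>= 4.33), strong (>= 18.7), very strong (>= 350). The same bands
#' are applied to the lower confidence bound of a case-enrichment odds ratio
#' (PS4) and to the OddsPath likelihood ratio (PP4).
#'
#' @param supporting,moderate,strong,very_strong Band lower bounds; must be
#'   strictly increasing.
#' @return A named numeric vector of class `evidence_thresholds`.
#' @examples
#' evidence_thresholds()
#' @export
evidence_thresholds <- function(supporting = 2.08, moderate = 4.33,
                                strong = 18.7, very_strong = 350) {
  th <- c(supporting = supporting, moderate = moderate,
          strong = strong, very_strong = very_strong)
  if (any(!is.finite(th)) || any(diff(th) <= 0))
    stop("evidence thresholds must be finite and strictly increasing")
  structure(th, class = "evidence_thresholds")
}

#' Map a positive statistic to an evidence-strength band
#'
#' Half-open bands: `[supporting, moderate)` -> supporting,
#' `[moderate, strong)` -> moderate, `[strong, very_strong)` -> strong,
#' `>= very_strong` -> very_strong, below supporting -> not_met.
#'
#' @param x Positive numeric vector (an OddsPath or a CI lower bound).
#' @param thresholds An [evidence_thresholds()] vector.
#' @return Character vector of strengths.
#' @examples
#' evidence_band(c(1, 2.08, 252, 350))
#' @export
evidence_band <- function(x, thresholds = evidence_thresholds()) {
  stopifnot(is.numeric(x))
  out <- rep("not_met", length(x))
  out[x >= thresholds[["supporting"]]]  <- "supporting"
  out[x >= thresholds[["moderate"]]]    <- "moderate"
  out[x >= thresholds[["strong"]]]      <- "strong"
  out[x >= thresholds[["very_strong"]]] <- "very_strong"
  out
}
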