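# OddsPath: multinomial likelihood-ratio model over somatic-hit patterns.
#
# For a germline variant observed in N somatic-evaluable carriers with
# pattern counts (n1, n2, n3, n0), the odds of pathogenicity is the
# likelihood ratio of the counts under two multinomial hypotheses:
# category probabilities p_path (carrier of a deleterious germline variant)
# versus p_null (no deleterious germline variant). The multinomial
# coefficient is identical under both hypotheses and cancels, so
#   OddsPath = prod_k (p_path[k] / p_null[k])^(n_k).
# The posterior probability of pathogenicity follows from the prior via
# Tavtigian's formula, and evidence strength from the Tavtigian bands.

#' Multinomial somatic-pattern model
#'
#' Category probability vectors over the four somatic-pattern categories
#' (single recurrent hotspot, single non-recurrent, multiple, none) under the
#' two hypotheses, plus the prior probability of pathogenicity.
#'
#' The defaults are the pattern frequencies observed in aggregated MDS/AML
#' case series: carriers of established deleterious germline variants show
#' single recurrent, single non-recurrent, and multiple somatic DDX41
#' variants in 58%, 10% and 0.7% of cases, whereas cases without a germline
#' DDX41 variant show them in 0.23%, 0.20% and 0.14% of cases; the "none"
#' entries are the complements. The default prior of 0.10 reproduces the
#' reference conversion of an OddsPath of 252 to a posterior of 97%.
#'
#' @param p_path Probability 4-vector under a deleterious germline variant.
#' @param p_null Probability 4-vector under no deleterious germline variant.
#' @param prior Prior probability of pathogenicity, in (0, 1).
#' @return A `multinomial_model` object.
#' @examples
#' multinomial_model()
#' @export
multinomial_model <- function(p_path = c(single_recurrent = 0.58,
                                         single_nonrecurrent = 0.10,
                                         multiple = 0.007,
                                         none = 0.313),
                              p_null = c(single_recurrent = 0.0023,
                                         single_nonrecurrent = 0.0020,
                                         multiple = 0.0014,
                                         none = 0.9943),
                              prior = 0.10) {
  p_path <- unname(as.numeric(p_path)); p_null <- unname(as.numeric(p_null))
  for (p in list(p_path, p_null)) {
    if (length(p) != 4 || any(p < 0) || any(p > 1))
      stop("category probabilities must be four values in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9)
      stop("category probabilities must sum to 1 (within 1e-9)")
  }
  if (!is.numeric(prior) || length(prior) != 1 || prior <= 0 || prior >= 1)
    stop("prior must be a single probability in (0, 1)")
  structure(list(p_path = setNames(p_path, .patterns),
                 p_null = setNames(p_null, .patterns),
                 prior = prior),
            class = "multinomial_model")
}

#' @export
print.multinomial_model <- function(x, ...) {
  cat("multinomial somatic-pattern model\n")
  m <- rbind(p_path = x$p_path, p_null = x$p_null)
  print(m)
  cat(sprintf("prior probability of pathogenicity: %.3g\n", x$prior))
  invisible(x)
}

# vectorized uncapped log likelihood-ratio core; zero counts contribute
# nothing even when a category probability is zero
.log_lr <- function(n1, n2, n3, n0, model) {
  lr <- log(model$p_path) - log(model$p_null)
  term <- function(n, l) ifelse(n == 0, 0, n * l)
  term(n1, lr[[1]]) + term(n2, lr[[2]]) + term(n3, lr[[3]]) + term(n0, lr[[4]])
}

#' OddsPath likelihood ratio for observed somatic-pattern counts
#'
#' Computes the multinomial likelihood ratio (odds of pathogenicity) for the
#' counts under the model's two hypotheses. Returns 1 for an empty tally
#' (N = 0). Because the null category probabilities are small empirical
#' frequencies, the ratio is capped (default 1e6) with a warning rather than
#' allowed to claim effectively infinite evidence.
#'
#' @param counts A [pattern_counts()] object or numeric `(n1, n2, n3, n0)`.
#' @param model A [multinomial_model()].
#' @param cap Maximum returned ratio; `Inf` disables the guard.
#' @return A positive scalar.
#' @examples
#' likelihood_ratio(pattern_counts(1, 0, 0, 0))  # ~252
#' likelihood_ratio(pattern_counts(1, 0, 0, 3))  # ~7.9, moderate band
#' @export
likelihood_ratio <- function(counts, model = multinomial_model(), cap = 1e6) {
  counts <- .as_pattern_counts(counts)
  if (attr(counts, "N") == 0) return(1)
  zero_null <- model$p_null == 0 & unclass(counts)[1:4] > 0
  if (any(zero_null))
    stop("null category probability is zero for an observed category; ",
         "OddsPath would be infinite")
  op <- exp(.log_lr(counts[[1]], counts[[2]], counts[[3]], counts[[4]], model))
  if (op > cap) {
    warning(sprintf("OddsPath %.3g capped at %.3g", op, cap))
    op <- cap
  }
  op
}

#' Posterior probability of pathogenicity from an OddsPath
#'
#' Tavtigian's conversion: `Post = (OP * prior) / ((OP - 1) * prior + 1)`.
#' Equals the prior when `OP = 1` and increases monotonically in `OP`.
#'
#' @param oddspath Positive likelihood ratio(s).
#' @param prior Prior probability of pathogenicity in (0, 1).
#' @return Posterior probability in (0, 1).
#' @examples
#' posterior_from_oddspath(252, 0.10)  # ~0.966, prints as 97%
#' @export
posterior_from_oddspath <- function(oddspath, prior = 0.10) {
  stopifnot(all(oddspath > 0), prior > 0, prior < 1)
  (oddspath * prior) / ((oddspath - 1) * prior + 1)
}

#' Invert the posterior conversion back to an OddsPath
#'
#' @param posterior Posterior probability in (0, 1).
#' @param prior Prior probability in (0, 1).
#' @return The likelihood ratio whose posterior equals `posterior`.
#' @export
oddspath_from_posterior <- function(posterior, prior = 0.10) {
  stopifnot(all(posterior > 0), all(posterior < 1), prior > 0, prior < 1)
  posterior * (1 - prior) / (prior * (1 - posterior))
}

#' Evidence band for an OddsPath
#'
#' Applies the Tavtigian bands to the likelihood ratio; see
#' [evidence_band()].
#'
#' @param oddspath Positive likelihood ratio(s).
#' @param thresholds [evidence_thresholds()].
#' @return Character vector of strengths.
#' @examples
#' band_from_oddspath(c(252, 350, 1))
#' @export
band_from_oddspath <- function(oddspath, thresholds = evidence_thresholds()) {
  stopifnot(all(oddspath > 0))
  evidence_band(oddspath, thresholds)
}

#' Full OddsPath evaluation of a somatic-pattern tally
#'
#' Convenience wrapper combining [likelihood_ratio()],
#' [posterior_from_oddspath()] and [band_from_oddspath()].
#'
#' @inheritParams likelihood_ratio
#' @param thresholds [evidence_thresholds()].
#' @return An `oddspath_result` list: `oddspath`, `posterior`, `band`,
#'   `counts`.
#' @export
oddspath <- function(counts, model = multinomial_model(),
                     thresholds = evidence_thresholds(), cap = 1e6) {
  counts <- .as_pattern_counts(counts)
  op <- likelihood_ratio(counts, model, cap = cap)
  structure(list(oddspath = op,
                 posterior = posterior_from_oddspath(op, model$prior),
                 band = band_from_oddspath(op, thresholds),
                 counts = counts),
            class = "oddspath_result")
}

#' @export
print.oddspath_result <- function(x, ...) {
  n <- unclass(x$counts)[1:4]
  cat(sprintf("OddsPath %.4g (posterior %.3f, PP4 %s) from (n1,n2,n3,n0) = (%d,%d,%d,%d)\n",
              x$oddspath, x$posterior, x$band, n[1], n[2], n[3], n[4]))
  invisible(x)
}

#' Enumerate OddsPath over all somatic-pattern count combinations
#'
#' Builds the simulation grid of OddsPath, posterior and evidence band for
#' every combination of hit counts `(n1, n2, n3)` with
#' `n1 + n2 + n3 <= N <= max_n` (the remainder being carriers without a
#' somatic hit), including the empty `N = 0` baseline. The row count equals
#' `choose(max_n + 4, 4)`.
#'
#' @param max_n Largest number of evaluable carriers to enumerate (>= 1).
#' @param model [multinomial_model()].
#' @param thresholds [evidence_thresholds()].
#' @param cap Cap applied to the ratio (no warning; see [likelihood_ratio()]).
#' @return data.frame with columns `N`, `n1`, `n2`, `n3`, `n0`, `oddspath`,
#'   `posterior`, `band`.
#' @export
oddspath_grid <- function(max_n = 25, model = multinomial_model(),
                          thresholds = evidence_thresholds(), cap = 1e6) {
  stopifnot(max_n >= 1)
  combos <- expand.grid(n1 = 0:max_n, n2 = 0:max_n, n3 = 0:max_n)
  combos <- combos[combos$n1 + combos$n2 + combos$n3 <= max_n, , drop = FALSE]
  rows <- lapply(0:max_n, function(N) {
    cc <- combos[combos$n1 + combos$n2 + combos$n3 <= N, , drop = FALSE]
    cc$N <- N
    cc$n0 <- N - (cc$n1 + cc$n2 + cc$n3)
    cc
  })
  g <- do.call(rbind, rows)
  g <- g[, c("N", "n1", "n2", "n3", "n0")]
  op <- exp(.log_lr(g$n1, g$n2, g$n3, g$n0, model))
  g$oddspath <- pmin(op, cap)
  g$posterior <- posterior_from_oddspath(g$oddspath, model$prior)
  g$band <- band_from_oddspath(g$oddspath, thresholds)
  rownames(g) <- NULL
  g
}

#' Presence-based PP4 comparator rule
#'
#' The simpler presence/absence rule used before the multinomial model: any
#' single recurrent hotspot hit gives strong evidence; otherwise any somatic
#' hit (non-recurrent single or multiple) gives moderate; no hits, not met.
#' The rule table is configurable since published variants of it differ.
#'
#' @param counts [pattern_counts()] or numeric `(n1, n2, n3, n0)`.
#' @param rule Named list with strengths for `recurrent` and `other`.
#' @return Evidence strength string.
#' @examples
#' original_pp4(pattern_counts(1, 0, 0, 3))  # "strong"
#' @export
original_pp4 <- function(counts, rule = list(recurrent = "strong",
                                             other = "moderate")) {
  counts <- .as_pattern_counts(counts)
  stopifnot(all(c("recurrent", "other") %in% names(rule)))
  if (counts[["single_recurrent"]] >= 1) return(rule$recurrent)
  if (counts[["single_nonrecurrent"]] >= 1 || counts[["multiple"]] >= 1)
    return(rule$other)
  "not_met"
}

#' Estimate the multinomial model from a cohort
#'
#' Re-derives the category probability vectors empirically: `p_path` from the
#' somatic patterns of evaluable carriers of the anchor variants (established
#' deleterious variants, by default the three most common pathogenic ones),
#' and `p_null` from evaluable cases carrying no germline variant. Optional
#' additive smoothing adds a pseudo-count to every category before
#' normalizing; the default of 0 reports raw frequencies (which may contain
#' zeros — [likelihood_ratio()] then refuses observed categories with a zero
#' null probability).
#'
#' @param cases Cohort data.frame.
#' @param anchor_variants Character vector of aggregation keys of the anchor
#'   (known-deleterious) germline variants.
#' @param registry Hotspot registry.
#' @param prior Prior carried into the returned model.
#' @param pseudocount Additive smoothing constant (default 0).
#' @return A [multinomial_model()]; attributes `n_path` and `n_null` give the
#'   carrier / non-carrier denominators, `smoothing` the pseudo-count.
#' @export
estimate_model_from_cohort <- function(cases, anchor_variants,
                                       registry = ddx41_hotspots(),
                                       prior = 0.10, pseudocount = 0) {
  anchor_variants <- unique(anchor_variants)
  if (length(anchor_variants) == 0) stop("at least one anchor variant is required")
  is_anchor <- vapply(cases$germline_keys,
                      function(k) any(anchor_variants %in% k), logical(1))
  anchors <- cases[is_anchor & cases$somatic_evaluable, , drop = FALSE]
  if (nrow(anchors) == 0) stop("no evaluable carriers of the anchor variants")
  noncar <- cases[lengths(cases$germline_keys) == 0 & cases$somatic_evaluable, ,
                  drop = FALSE]
  if (nrow(noncar) == 0) stop("no evaluable non-carrier cases")
  freq <- function(df) {
    pats <- vapply(df$somatic_hits, classify_somatic_pattern, character(1),
                   registry = registry)
    tab <- table(factor(pats, levels = .patterns)) + pseudocount
    as.numeric(tab / sum(tab))
  }
  m <- multinomial_model(p_path = freq(anchors), p_null = freq(noncar),
                         prior = prior)
  attr(m, "n_path") <- nrow(anchors)
  attr(m, "n_null") <- nrow(noncar)
  attr(m, "smoothing") <- pseudocount
  m
}
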