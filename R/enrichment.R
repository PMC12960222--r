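# PS4 case-enrichment engine: Haldane-corrected odds ratios against
# population allele counts, prevalence CIs, pairwise Fisher tests, and the
# ancestry-matching policy that guards against founder-variant inflation.

#' Haldane-corrected odds ratio for a 2x2 table
#'
#' Computes the odds ratio for the table (a = exposed cases, b = unexposed
#' cases, c = exposed controls, d = unexposed controls) with the Haldane
#' continuity correction (0.5 added to each cell), and a confidence interval
#' from the normal approximation on the log odds ratio with standard error
#' `sqrt(sum(1 / corrected cells))`. The correction is applied
#' unconditionally by default; `"on_zero"` applies it only when a cell is
#' zero, `"none"` never (zero cells then error).
#'
#' @param a,b,c,d Non-negative cell counts; `a` may also be a length-4 vector
#'   or 2x2 matrix.
#' @param conf.level Confidence level (default 0.95).
#' @param correction `"always"`, `"on_zero"` or `"none"`.
#' @return An `or_result` list: `or`, `ci_low`, `ci_high`, `conf.level`,
#'   `table`.
#' @examples
#' haldane_or(800, 538, 139, 32499)  # OR ~346, a hallmark second-hit signal
#' @export
haldane_or <- function(a, b = NULL, c = NULL, d = NULL, conf.level = 0.95,
                       correction = c("always", "on_zero", "none")) {
  correction <- match.arg(correction)
  if (is.matrix(a)) a <- as.numeric(t(a))
  if (length(a) == 4 && is.null(b)) { d <- a[4]; c <- a[3]; b <- a[2]; a <- a[1] }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) stop("cell counts must be non-negative")
  if (all(cells == 0)) stop("odds ratio undefined for an all-zero table")
  if (a + b <= 0 || c + d <= 0) stop("each row of the 2x2 table must have positive total")
  add <- switch(correction,
    always = 0.5,
    on_zero = if (any(cells == 0)) 0.5 else 0,
    none = 0
  )
  if (add == 0 && any(cells == 0))
    stop("zero cell with no continuity correction; odds ratio undefined")
  cc <- cells + add
  or <- (cc[["a"]] * cc[["d"]]) / (cc[["b"]] * cc[["c"]])
  se <- sqrt(sum(1 / cc))
  z <- qnorm(1 - (1 - conf.level) / 2)
  structure(list(or = unname(or),
                 ci_low = unname(or * exp(-z * se)),
                 ci_high = unname(or * exp(z * se)),
                 conf.level = conf.level,
                 correction = correction,
                 table = cells),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR = %.4g (%.0f%% CI: %.4g-%.4g)  [a=%g b=%g c=%g d=%g]\n",
              x$or, 100 * x$conf.level, x$ci_low, x$ci_high,
              x$table[["a"]], x$table[["b"]], x$table[["c"]], x$table[["d"]]))
  invisible(x)
}

#' PS4 strength from the lower confidence bound of an odds ratio
#'
#' Evidence strength is determined solely by the lower bound of the CI, so a
#' wide interval around a large point estimate yields weak evidence. Bands as
#' in [evidence_band()].
#'
#' @param x An `or_result` from [haldane_or()], or a numeric lower bound.
#' @param thresholds [evidence_thresholds()].
#' @return Evidence strength string.
#' @examples
#' strength_from_lower_ci(haldane_or(800, 538, 139, 32499))
#' @export
strength_from_lower_ci <- function(x, thresholds = evidence_thresholds()) {
  lo <- if (inherits(x, "or_result")) x$ci_low else as.numeric(x)
  evidence_band(lo, thresholds)
}

#' Prevalence point estimate with Wilson score confidence interval
#'
#' @param k Number of positives (0 <= k <= n).
#' @param n Denominator (> 0).
#' @param conf.level Confidence level.
#' @return Named numeric: `point`, `ci_low`, `ci_high` (fractions).
#' @examples
#' prevalence_ci(1083, 34051)  # 3.2% (3.0-3.4%)
#' @export
prevalence_ci <- function(k, n, conf.level = 0.95) {
  if (n <= 0) stop("denominator must be positive")
  if (k < 0 || k > n) stop("k must be between 0 and n")
  ci <- prop.test(k, n, conf.level = conf.level, correct = FALSE)$conf.int
  c(point = k / n, ci_low = ci[1], ci_high = ci[2])
}

#' Pairwise Fisher exact tests with Benjamini-Hochberg adjustment
#'
#' Two-sided Fisher exact test (probability-mass rule) for every pair of
#' groups given as (positives, total) counts, with BH step-up adjustment over
#' all pairs. Returns the symmetric matrix of adjusted p-values with unit
#' diagonal.
#'
#' @param k Integer vector of positives per group.
#' @param n Integer vector of totals per group.
#' @param labels Optional group names for dimnames.
#' @return Symmetric numeric matrix of BH-adjusted p-values.
#' @export
pairwise_fisher_bh <- function(k, n, labels = NULL) {
  stopifnot(length(k) == length(n), length(k) >= 2, all(k >= 0), all(k <= n))
  m <- length(k)
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  raw <- apply(pairs, 1, function(ij) {
    i <- ij[1]; j <- ij[2]
    fisher.test(matrix(c(k[i], n[i] - k[i], k[j], n[j] - k[j]), nrow = 2))$p.value
  })
  adj <- p.adjust(raw, method = "BH")
  out <- matrix(1, m, m)
  out[pairs] <- adj
  out[pairs[, c(2, 1), drop = FALSE]] <- adj
  if (!is.null(labels)) dimnames(out) <- list(labels, labels)
  out
}

#' Ancestry-matching policy for PS4
#'
#' @param min_carriers Minimum carriers in an ancestry group for an
#'   ancestry-restricted table to be built.
#' @param dominant_fraction Carrier fraction above which one non-reference
#'   ancestry group triggers the matched downgrade (default 2/3).
#' @param reference_ancestries Groups treated as the well-represented
#'   reference (no downgrade trigger).
#' @param unmatched Labels that can never be matched to a control stratum.
#' @return A `ps4_policy` list.
#' @export
ps4_policy <- function(min_carriers = 3, dominant_fraction = 2 / 3,
                       reference_ancestries = "NFE",
                       unmatched = "unknown") {
  structure(list(min_carriers = min_carriers,
                 dominant_fraction = dominant_fraction,
                 reference_ancestries = reference_ancestries,
                 unmatched = unmatched),
            class = "ps4_policy")
}

#' PS4 case-enrichment evidence for one germline variant
#'
#' Builds a quasi-case-control table of variant carriers among the affected
#' case pool (default: MDS/AML diagnoses) against population allele counts,
#' overall and restricted to each ancestry group with enough carriers.
#' Control carriers are taken as allele counts under an all-heterozygote
#' assumption (exposed = AC, unexposed = AN/2 - AC). When a configured
#' fraction of carriers (default two-thirds) belongs to a single
#' non-reference ancestry group — the founder-variant situation — the final
#' strength is the minimum of the overall strength and that group's matched
#' strength, preventing ancestry-mismatched controls from inflating the
#' evidence.
#'
#' @param key Variant aggregation key.
#' @param cases Cohort data.frame containing the full case series (carriers
#'   and non-carriers).
#' @param controls Control allele-count data.frame with columns
#'   `variant_key`, `ancestry`, `AC`, `AN`.
#' @param diagnoses Diagnoses forming the case pool.
#' @param policy [ps4_policy()].
#' @param thresholds [evidence_thresholds()].
#' @param conf.level Confidence level for the odds-ratio CIs.
#' @param correction Continuity-correction mode, see [haldane_or()].
#' @return A `ps4_result` list: `overall` (or_result + strength),
#'   `by_ancestry` (named list of the same), `dominant_ancestry`,
#'   `dominant_fraction`, `n_carriers`, `strength`.
#' @export
variant_ps4 <- function(key, cases, controls, diagnoses = "mds_aml",
                        policy = ps4_policy(),
                        thresholds = evidence_thresholds(),
                        conf.level = 0.95, correction = "always") {
  pool <- cases[cases$diagnosis %in% diagnoses, , drop = FALSE]
  if (nrow(pool) == 0) stop("no cases in the requested diagnosis pool")
  carrier <- .carrier_index(pool, key)
  a <- sum(carrier); b <- nrow(pool) - a
  ctrl <- controls[controls$variant_key == key, , drop = FALSE]
  bad_an <- ctrl$AN <= 0
  if (any(bad_an)) {
    warning("skipping control ancestry group(s) with zero allele number: ",
            paste(ctrl$ancestry[bad_an], collapse = ", "))
    ctrl <- ctrl[!bad_an, , drop = FALSE]
  }
  if (nrow(ctrl) == 0) stop("no usable control allele counts for variant '", key, "'")
  c_all <- sum(ctrl$AC); d_all <- sum(ctrl$AN) / 2 - c_all
  overall <- haldane_or(a, b, c_all, d_all, conf.level = conf.level,
                        correction = correction)
  overall$strength <- strength_from_lower_ci(overall, thresholds)

  anc_counts <- table(pool$ancestry[carrier])
  by_ancestry <- list()
  for (anc in names(anc_counts)) {
    if (anc %in% policy$unmatched) next
    if (anc_counts[[anc]] < policy$min_carriers) next
    cr <- ctrl[ctrl$ancestry == anc, , drop = FALSE]
    if (nrow(cr) == 0) next
    sub <- pool[pool$ancestry == anc, , drop = FALSE]
    a_g <- sum(.carrier_index(sub, key)); b_g <- nrow(sub) - a_g
    c_g <- sum(cr$AC); d_g <- sum(cr$AN) / 2 - c_g
    res <- haldane_or(a_g, b_g, c_g, d_g, conf.level = conf.level,
                      correction = correction)
    res$strength <- strength_from_lower_ci(res, thresholds)
    by_ancestry[[anc]] <- res
  }

  dominant <- NA_character_; dom_frac <- NA_real_
  strength <- overall$strength
  if (a > 0 && length(anc_counts) > 0) {
    dominant <- names(anc_counts)[which.max(anc_counts)]
    dom_frac <- max(anc_counts) / a
    if (!dominant %in% policy$reference_ancestries &&
        !dominant %in% policy$unmatched &&
        dom_frac >= policy$dominant_fraction &&
        dominant %in% names(by_ancestry)) {
      matched <- by_ancestry[[dominant]]$strength
      strength <- .strengths[min(.strength_rank(c(strength, matched)))]
    }
  }
  structure(list(key = key, overall = overall, by_ancestry = by_ancestry,
                 dominant_ancestry = dominant, dominant_fraction = dom_frac,
                 n_carriers = a, strength = strength),
            class = "ps4_result")
}

#' @export
print.ps4_result <- function(x, ...) {
  cat(sprintf("PS4 for %s: %d carriers, overall OR %.3g (CI low %.3g, %s)\n",
              x$key, x$n_carriers, x$overall$or, x$overall$ci_low,
              x$overall$strength))
  for (anc in names(x$by_ancestry)) {
    r <- x$by_ancestry[[anc]]
    cat(sprintf("  %s-matched: OR %.3g (CI low %.3g, %s)\n",
                anc, r$or, r$ci_low, r$strength))
  }
  cat(sprintf("  final strength: %s\n", x$strength))
  invisible(x)
}
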