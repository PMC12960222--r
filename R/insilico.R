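# PP3/BP4 in-silico evidence: truth-set construction from germline-somatic
# co-occurrence, ROC/AUC with DeLong machinery (via pROC, the standard
# implementation), Youden thresholding, and threshold-based evidence
# assignment with a splice-impact override.

#' Build pathogenic/benign truth sets for in-silico score calibration
#'
#' Pathogenicity labels are derived from orthogonal evidence, not from the
#' scores being calibrated: the pathogenic truth set contains germline
#' missense variants with at least one evaluable carrier whose somatic
#' pattern is a single recurrent hotspot (excluding variants flagged as
#' lying in splice-junction regions, whose effect may be on splicing rather
#' than protein function); the benign truth set contains population-derived
#' missense variants not observed in the aggregated case series. Variants
#' lacking a tool's score are dropped from that tool's set with a logged
#' count.
#'
#' @param cases Cohort data.frame.
#' @param annotations Annotation data.frame for the cohort variants, with
#'   columns `variant_key`, `variant_type`, score columns (`revel`,
#'   `alphamissense`), and optionally logical `splice_region`.
#' @param population_variants Annotation-format data.frame of
#'   population-database missense variants.
#' @param registry Hotspot registry.
#' @param asc_keys Keys counted as present in the case series (default: all
#'   germline keys observed in `cases`).
#' @param tools Score columns to build sets for.
#' @return Named list of `scored_set` data.frames (`variant_key`, `score`,
#'   `label`), one per tool, each with attribute `n_dropped`.
#' @export
build_truth_sets <- function(cases, annotations, population_variants,
                             registry = ddx41_hotspots(), asc_keys = NULL,
                             tools = c("revel", "alphamissense")) {
  if (is.null(asc_keys)) asc_keys <- unique(unlist(cases$germline_keys))
  splice_flag <- function(df) {
    if ("splice_region" %in% names(df)) isTRUE_vec(df$splice_region) else
      rep(FALSE, nrow(df))
  }
  ev <- cases[cases$somatic_evaluable, , drop = FALSE]
  pats <- vapply(ev$somatic_hits, classify_somatic_pattern, character(1),
                 registry = registry)
  rec_keys <- unique(unlist(ev$germline_keys[pats == "single_recurrent"]))
  path <- annotations[annotations$variant_type == "missense" &
                        annotations$variant_key %in% rec_keys &
                        !splice_flag(annotations), , drop = FALSE]
  ben <- population_variants[population_variants$variant_type == "missense" &
                               !population_variants$variant_key %in% asc_keys, ,
                             drop = FALSE]
  if (nrow(path) == 0) stop("pathogenic truth set is empty")
  if (nrow(ben) == 0) stop("benign truth set is empty")
  out <- list()
  for (tool in tools) {
    if (!tool %in% names(path) || !tool %in% names(ben))
      stop("score column '", tool, "' missing from annotations")
    df <- data.frame(
      variant_key = c(path$variant_key, ben$variant_key),
      score = c(path[[tool]], ben[[tool]]),
      label = c(rep("pathogenic_truth", nrow(path)),
                rep("benign_truth", nrow(ben))),
      stringsAsFactors = FALSE
    )
    dropped <- sum(is.na(df$score))
    df <- df[!is.na(df$score), , drop = FALSE]
    if (dropped > 0)
      message(dropped, " variant(s) lacking a ", tool, " score dropped")
    if (length(unique(df$label)) < 2)
      stop("truth set for '", tool, "' lost a label class after score filtering")
    rownames(df) <- NULL
    attr(df, "n_dropped") <- dropped
    class(df) <- c("scored_set", "data.frame")
    out[[tool]] <- df
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

.check_scored <- function(s) {
  if (!is.data.frame(s) || !all(c("score", "label") %in% names(s)))
    stop("expected a data.frame with 'score' and 'label' columns")
  if (!all(s$label %in% c("pathogenic_truth", "benign_truth")))
    stop("labels must be 'pathogenic_truth' or 'benign_truth'")
  if (length(unique(s$label)) < 2)
    stop("both label classes are required")
  s
}

.proc_roc <- function(s) {
  pROC::roc(response = s$label, predictor = s$score,
            levels = c("benign_truth", "pathogenic_truth"),
            direction = "<", quiet = TRUE)
}

#' ROC curve, AUC with DeLong confidence interval, and Youden threshold
#'
#' The AUC is the Mann-Whitney concordance statistic of the sample (with tie
#' correction); the CI uses the DeLong placement-value variance. The Youden
#' threshold maximizes sensitivity + specificity - 1 over all observed score
#' values (classification rule: score >= threshold is called pathogenic),
#' breaking ties toward the higher threshold.
#'
#' @param s A `scored_set` data.frame (`score`, `label`).
#' @param conf.level Confidence level for the AUC CI.
#' @return A `roc_result` list: `auc`, `auc_ci`, `points` (threshold,
#'   sensitivity, specificity), `youden_threshold`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(s, conf.level = 0.95) {
  s <- .check_scored(s)
  r <- .proc_roc(s)
  auc <- as.numeric(pROC::auc(r))
  ci <- tryCatch(
    suppressWarnings(
      as.numeric(pROC::ci.auc(r, method = "delong", conf.level = conf.level))),
    error = function(e) c(auc, auc, auc)
  )
  points <- data.frame(threshold = r$thresholds,
                       sensitivity = r$sensitivities,
                       specificity = r$specificities)
  pos <- s$score[s$label == "pathogenic_truth"]
  neg <- s$score[s$label == "benign_truth"]
  thr <- sort(unique(s$score))
  j <- vapply(thr, function(t) mean(pos >= t) + mean(neg < t) - 1, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  youden <- thr[max(best)]
  structure(list(auc = auc, auc_ci = c(low = ci[1], high = ci[3]),
                 points = points, youden_threshold = youden,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d pathogenic vs %d benign; Youden threshold %.3g\n",
              x$auc, x$auc_ci[["low"]], x$auc_ci[["high"]],
              x$n_pos, x$n_neg, x$youden_threshold))
  invisible(x)
}

#' DeLong variance of a single empirical AUC
#'
#' Placement-value (structural-component) variance of the empirical AUC, as
#' used in the DeLong CI and paired test.
#'
#' @param s A `scored_set` data.frame.
#' @return Variance estimate (scalar).
#' @export
auc_variance_delong <- function(s) {
  s <- .check_scored(s)
  as.numeric(pROC::var(.proc_roc(s), method = "delong"))
}

#' Paired DeLong comparison of two tools' AUCs
#'
#' Compares two score sets over the identical variant collection (e.g. REVEL
#' vs AlphaMissense on the same truth sets) with the DeLong test for paired
#' correlated AUCs. Two identical score vectors (or a zero-variance
#' difference) give z = 0, p = 1.
#'
#' @param s1,s2 `scored_set` data.frames over the same variants and labels,
#'   in the same order.
#' @return List with `z` (signed statistic, positive when `s1` has the
#'   larger AUC), `p` (two-sided), `auc1`, `auc2`.
#' @export
delong_compare <- function(s1, s2) {
  s1 <- .check_scored(s1); s2 <- .check_scored(s2)
  if (nrow(s1) != nrow(s2) || !identical(s1$label, s2$label))
    stop("inputs are not paired: same variants and labels required")
  if (all(c("variant_key") %in% names(s1)) && "variant_key" %in% names(s2) &&
      !identical(s1$variant_key, s2$variant_key))
    stop("inputs are not paired: variant_key order differs")
  r1 <- .proc_roc(s1); r2 <- .proc_roc(s2)
  auc1 <- as.numeric(pROC::auc(r1)); auc2 <- as.numeric(pROC::auc(r2))
  if (isTRUE(all.equal(s1$score, s2$score)))
    return(list(z = 0, p = 1, auc1 = auc1, auc2 = auc2))
  tt <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  z <- unname(tt$statistic)
  if (!is.finite(z)) { z <- 0; p <- 1 } else p <- tt$p.value
  list(z = z, p = unname(p), auc1 = auc1, auc2 = auc2)
}

#' Assign PP3/BP4 computational-prediction evidence for one variant
#'
#' Threshold rule on the chosen missense predictor: score at or above the
#' upper threshold gives PP3 (supporting), at or below the lower threshold
#' gives BP4 (supporting), otherwise neither. Defaults are the calibrated
#' AlphaMissense cutoffs (>= 0.792 / <= 0.169) and the conventional REVEL
#' pair (>= 0.7 / <= 0.3). When the splice policy is enabled and the
#' variant's SpliceAI score reaches its cutoff (default 0.2), predicted
#' splice impact takes precedence: PP3 applies regardless of the missense
#' score and BP4 is suppressed.
#'
#' @param revel,alphamissense,spliceai Scores in `[0, 1]`, `NA` when absent.
#' @param tool `"alphamissense"` or `"revel"`.
#' @param thresholds Named list of `c(low, high)` per tool.
#' @param splice_policy Enable the SpliceAI override.
#' @param spliceai_cutoff SpliceAI max delta score triggering the override.
#' @return An [evidence_code()] (PP3, BP4, or PP3 at `not_met` when neither
#'   fires or no usable score exists).
#' @examples
#' assign_pp3_bp4(alphamissense = 0.95)
#' assign_pp3_bp4(revel = 0.1, spliceai = 0.8, tool = "revel")
#' @export
assign_pp3_bp4 <- function(revel = NA_real_, alphamissense = NA_real_,
                           spliceai = NA_real_,
                           tool = c("alphamissense", "revel"),
                           thresholds = list(revel = c(low = 0.3, high = 0.7),
                                             alphamissense = c(low = 0.169, high = 0.792)),
                           splice_policy = TRUE, spliceai_cutoff = 0.2) {
  tool <- match.arg(tool)
  if (splice_policy && !is.na(spliceai) && spliceai >= spliceai_cutoff) {
    return(evidence_code("PP3", "supporting",
                         rationale = sprintf("SpliceAI %.3g >= %.3g: predicted splice impact overrides missense score",
                                             spliceai, spliceai_cutoff)))
  }
  score <- switch(tool, revel = revel, alphamissense = alphamissense)
  th <- thresholds[[tool]]
  if (is.na(score)) {
    warning("no usable ", tool, " score; PP3/BP4 not met")
    return(evidence_code("PP3", "not_met", rationale = "no usable score"))
  }
  if (score >= th[["high"]])
    return(evidence_code("PP3", "supporting",
                         rationale = sprintf("%s %.3g >= %.3g", tool, score, th[["high"]])))
  if (score <= th[["low"]])
    return(evidence_code("BP4", "supporting", direction = "benign",
                         rationale = sprintf("%s %.3g <= %.3g", tool, score, th[["low"]])))
  evidence_code("PP3", "not_met",
                rationale = sprintf("%s %.3g between thresholds", tool, score))
}
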