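# ACMG/AMP evidence integration: individual codes (PVS1, PM2, PS4, PP4,
# PP3/BP4), the Bayesian point-based combiner, and single/bulk variant
# curation with full provenance.

.code_names <- c("PVS1", "PS4", "PM2", "PP3", "PP4", "BP4")
.points_path <- c(not_met = 0, supporting = 1, moderate = 2, strong = 4,
                  very_strong = 8)

#' Construct an ACMG/AMP evidence code
#'
#' Pathogenic-direction points follow the Bayesian point scale:
#' supporting = 1, moderate = 2, strong = 4, very strong = 8; benign
#' supporting = -1; `not_met` = 0.
#'
#' @param code One of PVS1, PS4, PM2, PP3, PP4, BP4.
#' @param strength Evidence strength.
#' @param direction `"pathogenic"` or `"benign"` (BP4 defaults to benign).
#' @param rationale Free-text provenance for the assignment.
#' @return An `evidence_code` list with a `points` field.
#' @examples
#' evidence_code("PVS1", "very_strong")
#' @export
evidence_code <- function(code, strength = "not_met",
                          direction = if (code == "BP4") "benign" else "pathogenic",
                          rationale = "") {
  code <- match.arg(code, .code_names)
  strength <- match.arg(strength, .strengths)
  direction <- match.arg(direction, c("pathogenic", "benign"))
  pts <- unname(.points_path[[strength]])
  if (direction == "benign") pts <- -pts
  structure(list(code = code, direction = direction, strength = strength,
                 points = pts, rationale = rationale),
            class = "evidence_code")
}

#' @export
print.evidence_code <- function(x, ...) {
  cat(sprintf("%s [%s, %s, %+d pt]%s\n", x$code, x$direction, x$strength,
              x$points,
              if (nzchar(x$rationale)) paste0(": ", x$rationale) else ""))
  invisible(x)
}

#' Assign PVS1 (predicted loss of function)
#'
#' Null-variant types carry PVS1 at a policy strength: very strong for
#' nonsense, frameshift and canonical splice variants, strong for start-loss
#' (start-loss may be rescued by downstream initiation). All other types do
#' not meet the criterion. The full exon-level NMD decision tree is out of
#' scope; the policy table is configurable.
#'
#' @param variant_type Variant type string (e.g. `"frameshift"`).
#' @param policy Named strengths per qualifying type.
#' @return An [evidence_code()].
#' @examples
#' assign_pvs1("frameshift")
#' @export
assign_pvs1 <- function(variant_type,
                        policy = c(nonsense = "very_strong",
                                   frameshift = "very_strong",
                                   canonical_splice = "very_strong",
                                   start_loss = "strong")) {
  if (variant_type %in% names(policy))
    evidence_code("PVS1", policy[[variant_type]],
                  rationale = paste0("predicted loss of function (", variant_type, ")"))
  else
    evidence_code("PVS1", "not_met", rationale = paste0(variant_type, " is not a null variant type"))
}

#' Assign PM2 (absence or rarity in population controls)
#'
#' Applied at supporting strength, as recommended for this criterion:
#' supporting when the variant is absent from all control ancestry groups
#' (every AC = 0) or its maximum per-group allele frequency is at or below
#' the threshold (default 2e-5); otherwise not met.
#'
#' @param ac,an Per-ancestry allele counts and numbers (equal-length
#'   vectors; groups with `AN = 0` are ignored).
#' @param af_threshold Maximum group allele frequency (fraction).
#' @return An [evidence_code()].
#' @examples
#' assign_pm2(c(NFE = 0, EAS = 0), c(NFE = 1e6, EAS = 5e4))
#' @export
assign_pm2 <- function(ac, an, af_threshold = 2e-5) {
  stopifnot(length(ac) == length(an))
  ok <- !is.na(ac) & !is.na(an) & an > 0
  if (!any(ok)) {
    return(evidence_code("PM2", "not_met", rationale = "no population data"))
  }
  if (any(ac[ok] > an[ok])) stop("allele count exceeds allele number")
  if (all(ac[ok] == 0))
    return(evidence_code("PM2", "supporting",
                         rationale = "absent from population controls"))
  grpmax <- max(ac[ok] / an[ok])
  if (grpmax <= af_threshold)
    evidence_code("PM2", "supporting",
                  rationale = sprintf("max group AF %.3g <= %.3g", grpmax, af_threshold))
  else
    evidence_code("PM2", "not_met",
                  rationale = sprintf("max group AF %.3g > %.3g", grpmax, af_threshold))
}

.tiers <- c("B", "LB", "VUS", "LP", "P")

#' Combine evidence codes into a five-tier classification
#'
#' Sums the codes' points and maps the total to a tier:
#' `>= 10` pathogenic (P), `6..9` likely pathogenic (LP), `0..5` uncertain
#' (VUS), `-6..-1` likely benign (LB), `<= -7` benign (B).
#'
#' @param codes List of [evidence_code()] objects, at most one per code name.
#' @return A `classification` list: `tier`, `total_points`, `codes`.
#' @examples
#' combine_codes(list(evidence_code("PVS1", "very_strong"),
#'                    evidence_code("PM2", "supporting")))
#' @export
combine_codes <- function(codes) {
  stopifnot(all(vapply(codes, inherits, logical(1), "evidence_code")))
  nm <- vapply(codes, `[[`, character(1), "code")
  if (anyDuplicated(nm))
    stop("duplicate evidence code(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  total <- sum(vapply(codes, `[[`, numeric(1), "points"))
  tier <- if (total >= 10) "P" else if (total >= 6) "LP" else if (total >= 0) "VUS"
          else if (total >= -6) "LB" else "B"
  structure(list(tier = tier, total_points = total, codes = codes),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("classification: %s (%+d points)\n", x$tier, x$total_points))
  for (cd in x$codes) if (cd$points != 0 || cd$strength != "not_met") print(cd)
  invisible(x)
}

#' Curation configuration
#'
#' Collects every tunable of the curation pipeline: the hotspot registry,
#' the somatic-pattern model and prior, evidence thresholds, the missense
#' predictor and its PP3/BP4 cutoffs, the SpliceAI override, the PM2 allele
#' frequency cutoff, the PVS1 policy, the PS4 ancestry policy and case pool,
#' the OddsPath cap, and manual per-variant overrides.
#'
#' @param registry Hotspot registry.
#' @param model [multinomial_model()].
#' @param thresholds [evidence_thresholds()].
#' @param tool Missense predictor: `"alphamissense"` or `"revel"`.
#' @param pp3_thresholds Per-tool `c(low, high)` cutoffs.
#' @param splice_policy,spliceai_cutoff SpliceAI override settings.
#' @param af_threshold PM2 maximum group allele frequency.
#' @param pvs1_policy PVS1 strength per variant type.
#' @param ps4 [ps4_policy()].
#' @param diagnoses PS4 case pool diagnoses.
#' @param conf.level Confidence level for odds-ratio CIs.
#' @param cap OddsPath cap.
#' @param overrides Named list: `overrides[[variant_key]][[code]] = strength`,
#'   optionally with a `note` entry, replacing the computed strength with an
#'   audit trail.
#' @return A `curation_config` list.
#' @export
curation_config <- function(registry = ddx41_hotspots(),
                            model = multinomial_model(),
                            thresholds = evidence_thresholds(),
                            tool = c("alphamissense", "revel"),
                            pp3_thresholds = list(revel = c(low = 0.3, high = 0.7),
                                                  alphamissense = c(low = 0.169, high = 0.792)),
                            splice_policy = TRUE, spliceai_cutoff = 0.2,
                            af_threshold = 2e-5,
                            pvs1_policy = c(nonsense = "very_strong",
                                            frameshift = "very_strong",
                                            canonical_splice = "very_strong",
                                            start_loss = "strong"),
                            ps4 = ps4_policy(), diagnoses = "mds_aml",
                            conf.level = 0.95, cap = 1e6,
                            overrides = list()) {
  tool <- match.arg(tool)
  structure(list(registry = registry, model = model, thresholds = thresholds,
                 tool = tool, pp3_thresholds = pp3_thresholds,
                 splice_policy = splice_policy,
                 spliceai_cutoff = spliceai_cutoff,
                 af_threshold = af_threshold, pvs1_policy = pvs1_policy,
                 ps4 = ps4, diagnoses = diagnoses, conf.level = conf.level,
                 cap = cap, overrides = overrides),
            class = "curation_config")
}

#' Read a curation configuration from YAML
#'
#' Reads the scalar/vector tunables (registry, model probabilities and
#' prior, thresholds, tool and cutoffs, PM2/PS4 settings) from a YAML file;
#' anything absent keeps its default.
#'
#' @param path YAML file path.
#' @return A [curation_config()].
#' @export
read_curation_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$registry)) args$registry <- ddx41_hotspots(y$registry)
  if (!is.null(y$model))
    args$model <- multinomial_model(
      p_path = as.numeric(y$model$p_path),
      p_null = as.numeric(y$model$p_null),
      prior = if (is.null(y$model$prior)) 0.10 else y$model$prior)
  if (!is.null(y$thresholds)) args$thresholds <- do.call(evidence_thresholds, y$thresholds)
  for (f in c("tool", "splice_policy", "spliceai_cutoff", "af_threshold",
              "diagnoses", "conf.level", "cap"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$pp3_thresholds))
    args$pp3_thresholds <- lapply(y$pp3_thresholds, function(v)
      c(low = v$low, high = v$high))
  if (!is.null(y$pvs1_policy)) args$pvs1_policy <- unlist(y$pvs1_policy)
  if (!is.null(y$ps4)) args$ps4 <- do.call(ps4_policy, y$ps4)
  do.call(curation_config, args)
}

.annotation_row <- function(annotations, key) {
  hit <- which(annotations$variant_key == key)
  if (length(hit) == 0) stop("variant '", key, "' not found in the annotation table")
  annotations[hit[1], , drop = FALSE]
}

.ann_ac_an <- function(ann) {
  ac_cols <- grep("^AC_", names(ann), value = TRUE)
  groups <- sub("^AC_", "", ac_cols)
  an_cols <- paste0("AN_", groups)
  ok <- an_cols %in% names(ann)
  list(ac = setNames(as.numeric(ann[1, ac_cols[ok]]), groups[ok]),
       an = setNames(as.numeric(ann[1, an_cols[ok]]), groups[ok]))
}

.apply_override <- function(code_obj, overrides, key) {
  ov <- overrides[[key]]
  if (is.null(ov) || is.null(ov[[code_obj$code]])) return(code_obj)
  note <- if (is.null(ov$note)) "manual override" else ov$note
  new <- evidence_code(code_obj$code, ov[[code_obj$code]],
                       direction = code_obj$direction,
                       rationale = paste0("MANUAL OVERRIDE (was ", code_obj$strength,
                                          "): ", note))
  new
}

#' Curate one germline variant end to end
#'
#' Runs the full evidence pipeline for a variant: PS4 case enrichment with
#' ancestry matching ([variant_ps4()]), somatic-pattern tally and OddsPath
#' PP4 ([tally_patterns()], [likelihood_ratio()]), in-silico PP3/BP4
#' ([assign_pp3_bp4()]), PVS1 and PM2, then combines the codes into a
#' five-tier classification. Every intermediate value, the carrier list and
#' the configuration snapshot are kept in the report. Manual overrides in
#' the configuration replace individual code strengths with an audit note.
#'
#' @param key Variant aggregation key (must exist in `annotations`).
#' @param cases Cohort data.frame (the full case series).
#' @param controls Control allele-count table (`variant_key`, `ancestry`,
#'   `AC`, `AN`).
#' @param annotations Annotation data.frame (`variant_key`, `variant_type`,
#'   scores, `AC_*`/`AN_*` columns).
#' @param config [curation_config()].
#' @return A `curation_report` list.
#' @export
curate_variant <- function(key, cases, controls, annotations,
                           config = curation_config()) {
  ann <- .annotation_row(annotations, key)

  ps4_detail <- tryCatch(
    variant_ps4(key, cases, controls, diagnoses = config$diagnoses,
                policy = config$ps4, thresholds = config$thresholds,
                conf.level = config$conf.level),
    error = function(e) e)
  ps4_code <- if (inherits(ps4_detail, "error"))
    evidence_code("PS4", "not_met",
                  rationale = paste0("enrichment not assessable: ",
                                     conditionMessage(ps4_detail)))
  else
    evidence_code("PS4", ps4_detail$strength,
                  rationale = sprintf("overall OR %.3g (CI low %.3g); dominant ancestry %s",
                                      ps4_detail$overall$or,
                                      ps4_detail$overall$ci_low,
                                      ps4_detail$dominant_ancestry))

  counts <- tally_patterns(key, cases, registry = config$registry)
  capped <- FALSE
  op <- withCallingHandlers(
    likelihood_ratio(counts, config$model, cap = config$cap),
    warning = function(w) {
      capped <<- TRUE
      invokeRestart("muffleWarning")
    })
  post <- posterior_from_oddspath(op, config$model$prior)
  pp4_code <- evidence_code("PP4", band_from_oddspath(op, config$thresholds),
                            rationale = sprintf("OddsPath %.4g%s (posterior %.3f) from N = %d evaluable carriers",
                                                op, if (capped) " (capped)" else "",
                                                post, attr(counts, "N")))

  spl <- if ("spliceai" %in% names(ann)) ann$spliceai else NA_real_
  pp3_code <- if (ann$variant_type %in% c("missense", "inframe") ||
                  (!is.na(spl) && config$splice_policy)) {
    suppressWarnings(assign_pp3_bp4(
      revel = if ("revel" %in% names(ann)) ann$revel else NA_real_,
      alphamissense = if ("alphamissense" %in% names(ann)) ann$alphamissense else NA_real_,
      spliceai = spl, tool = config$tool,
      thresholds = config$pp3_thresholds,
      splice_policy = config$splice_policy,
      spliceai_cutoff = config$spliceai_cutoff))
  } else evidence_code("PP3", "not_met",
                       rationale = "predictor not applicable to variant type")

  pvs1_code <- assign_pvs1(ann$variant_type, policy = config$pvs1_policy)
  acan <- .ann_ac_an(ann)
  pm2_code <- if (length(acan$ac))
    assign_pm2(acan$ac, acan$an, af_threshold = config$af_threshold)
  else evidence_code("PM2", "not_met", rationale = "no population data")

  codes <- list(pvs1_code, ps4_code, pm2_code, pp3_code, pp4_code)
  codes <- lapply(codes, .apply_override, overrides = config$overrides, key = key)
  classification <- combine_codes(codes)

  carriers <- cases$case_id[.carrier_index(cases, key)]
  structure(list(
    variant_key = key,
    variant_type = ann$variant_type,
    classification = classification,
    codes = setNames(codes, vapply(codes, `[[`, character(1), "code")),
    oddspath = op, posterior = post, oddspath_capped = capped,
    pattern_counts = counts,
    ps4 = ps4_detail,
    carriers = carriers,
    annotation = ann,
    config = config
  ), class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("== %s (%s) ==\n", x$variant_key, x$variant_type))
  cat(sprintf("carriers: %d; OddsPath %.4g (posterior %.3f)\n",
              length(x$carriers), x$oddspath, x$posterior))
  print(x$classification)
  invisible(x)
}

#' Curate many variants with one configuration
#'
#' Applies [curate_variant()] to each key in input order. Per-variant errors
#' are collected in the summary table rather than aborting the batch.
#'
#' @inheritParams curate_variant
#' @param keys Character vector of variant keys.
#' @return data.frame with one row per key (`variant_key`, `tier`,
#'   `total_points`, per-code strengths, `oddspath`, `n_carriers`, `error`);
#'   full reports in `attr(, "reports")`.
#' @export
bulk_curate <- function(keys, cases, controls, annotations,
                        config = curation_config()) {
  if (length(keys) == 0) {
    out <- data.frame(variant_key = character(), tier = character(),
                      total_points = integer(), PVS1 = character(),
                      PS4 = character(), PM2 = character(),
                      PP3_BP4 = character(), PP4 = character(),
                      oddspath = numeric(), n_carriers = integer(),
                      error = character(), stringsAsFactors = FALSE)
    attr(out, "reports") <- list()
    return(out)
  }
  reports <- vector("list", length(keys))
  rows <- lapply(seq_along(keys), function(i) {
    rep <- tryCatch(curate_variant(keys[i], cases, controls, annotations, config),
                    error = function(e) e)
    reports[[i]] <<- rep
    if (inherits(rep, "error")) {
      data.frame(variant_key = keys[i], tier = NA_character_,
                 total_points = NA_integer_, PVS1 = NA, PS4 = NA, PM2 = NA,
                 PP3_BP4 = NA, PP4 = NA, oddspath = NA_real_,
                 n_carriers = NA_integer_,
                 error = conditionMessage(rep), stringsAsFactors = FALSE)
    } else {
      str_of <- function(code) {
        cd <- rep$codes[[code]]
        if (is.null(cd)) "not_met" else cd$strength
      }
      pp3 <- rep$codes[["PP3"]]; bp4 <- rep$codes[["BP4"]]
      pp3_bp4 <- if (!is.null(bp4)) paste0("BP4:", bp4$strength)
                 else paste0("PP3:", pp3$strength)
      data.frame(variant_key = keys[i],
                 tier = rep$classification$tier,
                 total_points = rep$classification$total_points,
                 PVS1 = str_of("PVS1"), PS4 = str_of("PS4"),
                 PM2 = str_of("PM2"), PP3_BP4 = pp3_bp4,
                 PP4 = str_of("PP4"),
                 oddspath = rep$oddspath,
                 n_carriers = length(rep$carriers),
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- setNames(reports, keys)
  out
}
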