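# Cohort model: case records, somatic-pattern classification, tallies and
# cohort/non-cohort merging.
#
# A cohort is a plain data.frame with one row per case and list-columns for
# the (0-2, occasionally more) germline variants and somatic hits:
#   case_id            chr
#   source             chr: "cohort", "non_cohort", "center"
#   diagnosis          chr: "mds_aml", "other_myeloid", "cytopenia",
#                           "lymphoid", "excluded"
#   ancestry           chr  (e.g. "NFE", "EAS", "other", "unknown")
#   germline_hgvsc     list of chr
#   germline_protein   list of chr (normalized, "p." stripped, uppercase)
#   germline_keys      list of chr (aggregation keys, see variant_key())
#   germline_confirmed lgl
#   somatic_hits       list of chr (normalized protein changes)
#   somatic_vaf        list of num (fractions in (0, 1], NA when unreported)
#   somatic_evaluable  lgl

.diagnoses <- c("mds_aml", "other_myeloid", "cytopenia", "lymphoid", "excluded")
.sources <- c("cohort", "non_cohort", "center")
.patterns <- c("single_recurrent", "single_nonrecurrent", "multiple", "none")

#' Normalize a protein-change string
#'
#' Uppercases and strips a leading "p." so that e.g. `"p.R525H"`, `"R525H"`
#' and `"r525h"` compare equal. Matching of somatic hits and hotspots is
#' exact string comparison after this normalization; no HGVS grammar is
#' assumed.
#'
#' @param x Character vector of protein changes.
#' @return Normalized character vector.
#' @export
normalize_protein <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^[Pp]\\.", "", x)
  x <- sub("^\\(", "", x)
  x <- sub("\\)$", "", x)
  toupper(x)
}

#' Default registry of recurrent somatic DDX41 hotspots
#'
#' The recurrent somatic missense variants observed across aggregated MDS/AML
#' case series: R525H (by far the most common), G530D, P321L, T227M, E345D,
#' G530S and D344E. Membership in this registry defines the
#' "single recurrent" somatic pattern category.
#'
#' @param extra Additional protein changes to include.
#' @return Character vector of normalized protein changes.
#' @examples
#' ddx41_hotspots()
#' @export
ddx41_hotspots <- function(extra = character()) {
  unique(normalize_protein(c(
    "R525H", "G530D", "P321L", "T227M", "E345D", "G530S", "D344E", extra
  )))
}

#' Aggregation key for a germline variant
#'
#' Variants are aggregated by normalized protein change when one is reported,
#' falling back to the HGVSc string otherwise. This collapses distinct coding
#' descriptions of the same protein change (e.g. E345D arising from c.1035G>C
#' or c.1035G>T, or frameshifts reported with different indel notations) the
#' way aggregated case series count them. Set `by = "hgvsc"` to key strictly
#' on the coding description.
#'
#' @param hgvsc Character vector of coding HGVS strings (may be `""`/`NA`).
#' @param protein Character vector of protein changes (may be `""`/`NA`).
#' @param by `"auto"` (protein when present, else hgvsc), `"protein"` or
#'   `"hgvsc"`.
#' @return Character vector of keys.
#' @export
variant_key <- function(hgvsc, protein, by = c("auto", "protein", "hgvsc")) {
  by <- match.arg(by)
  hgvsc <- trimws(ifelse(is.na(hgvsc), "", as.character(hgvsc)))
  protein <- normalize_protein(ifelse(is.na(protein), "", protein))
  key <- switch(by,
    auto = ifelse(nzchar(protein), protein, hgvsc),
    protein = protein,
    hgvsc = hgvsc
  )
  ifelse(nzchar(key), key, NA_character_)
}

#' Classify a case's somatic-hit pattern
#'
#' Deterministic four-way classification of the somatic DDX41 hits observed
#' in one case: no hit, a single hit that is a registry hotspot
#' ("single recurrent"), a single non-hotspot hit, or two or more hits
#' (regardless of identity).
#'
#' @param hits Character vector of somatic protein changes for one case
#'   (empty vector or `NA`s for none).
#' @param registry Hotspot registry, a character vector as from
#'   [ddx41_hotspots()].
#' @return One of `"single_recurrent"`, `"single_nonrecurrent"`,
#'   `"multiple"`, `"none"`.
#' @examples
#' classify_somatic_pattern("R525H")
#' classify_somatic_pattern(c("R525H", "L87V"))
#' classify_somatic_pattern(character())
#' @export
classify_somatic_pattern <- function(hits, registry = ddx41_hotspots()) {
  if (length(registry) == 0) stop("hotspot registry must be non-empty")
  hits <- normalize_protein(hits)
  hits <- hits[!is.na(hits) & nzchar(hits)]
  n <- length(hits)
  if (n == 0) return("none")
  if (n >= 2) return("multiple")
  if (hits %in% registry) "single_recurrent" else "single_nonrecurrent"
}

#' Somatic-pattern counts for a germline variant
#'
#' Container for the per-variant tally over evaluable carriers: `n1` single
#' recurrent (hotspot) hits, `n2` single non-recurrent hits, `n3` multiple
#' hits, `n0` no hit; `N = n1 + n2 + n3 + n0`.
#'
#' @param n1,n2,n3,n0 Non-negative counts.
#' @return A `pattern_counts` object (named numeric vector with an `N`
#'   attribute).
#' @examples
#' pattern_counts(1, 0, 0, 3)
#' @export
pattern_counts <- function(n1 = 0, n2 = 0, n3 = 0, n0 = 0) {
  x <- c(single_recurrent = n1, single_nonrecurrent = n2,
         multiple = n3, none = n0)
  if (any(x < 0) || any(x != round(x))) stop("pattern counts must be non-negative integers")
  structure(x, N = sum(x), class = "pattern_counts")
}

.as_pattern_counts <- function(x) {
  if (inherits(x, "pattern_counts")) return(x)
  if (is.numeric(x) && length(x) == 4) return(pattern_counts(x[[1]], x[[2]], x[[3]], x[[4]]))
  stop("expected pattern_counts or a numeric vector (n1, n2, n3, n0)")
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat(sprintf("somatic-pattern counts over N = %d evaluable carriers\n", attr(x, "N")))
  print(unclass(x)[1:4])
  invisible(x)
}

.carrier_index <- function(cases, key) {
  vapply(cases$germline_keys, function(k) key %in% k, logical(1))
}

#' Tally somatic patterns among carriers of a germline variant
#'
#' Counts the somatic-pattern categories over all somatic-evaluable carriers
#' of `key`, across all diagnoses. A case carrying two germline variants
#' contributes its pattern to each variant's tally. Cases flagged as not
#' somatic-evaluable contribute nothing.
#'
#' @param key Aggregation key of the germline variant (see [variant_key()]).
#' @param cases Cohort data.frame (see [read_cohort()]).
#' @param registry Hotspot registry.
#' @return A [pattern_counts()] object (all zero when there are no carriers).
#' @export
tally_patterns <- function(key, cases, registry = ddx41_hotspots()) {
  idx <- .carrier_index(cases, key) & cases$somatic_evaluable
  carriers <- cases[idx, , drop = FALSE]
  pats <- vapply(carriers$somatic_hits, classify_somatic_pattern,
                 character(1), registry = registry)
  tab <- table(factor(pats, levels = .patterns))
  pattern_counts(tab[["single_recurrent"]], tab[["single_nonrecurrent"]],
                 tab[["multiple"]], tab[["none"]])
}

.parse_diagnosis <- function(x) {
  x0 <- tolower(trimws(x))
  map <- c(
    mds_aml = "mds_aml", mds = "mds_aml", aml = "mds_aml",
    "mds/aml" = "mds_aml",
    other_myeloid = "other_myeloid", mpn = "other_myeloid",
    "mds/mpn" = "other_myeloid", "other myeloid" = "other_myeloid",
    cmml = "other_myeloid",
    cytopenia = "cytopenia", cytopenias = "cytopenia",
    "unexplained cytopenia" = "cytopenia", "ccus" = "cytopenia",
    lymphoid = "lymphoid", lymphoma = "lymphoid", all = "lymphoid",
    cll = "lymphoid",
    excluded = "excluded", "aplastic anemia" = "excluded",
    "aplastic anaemia" = "excluded", unspecified = "excluded",
    "healthy" = "excluded"
  )
  out <- unname(map[x0])
  out
}

.parse_vaf <- function(x) {
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  x <- sub("%$", "", x)
  v <- suppressWarnings(as.numeric(x))
  v[pct & !is.na(v)] <- v[pct & !is.na(v)] / 100
  # bare values > 1 are percentages reported without the sign
  v[!is.na(v) & v > 1] <- v[!is.na(v) & v > 1] / 100
  v
}

.split_multi <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(p) {
    p <- trimws(p)
    p[nzchar(p)]
  })
}

#' Cohort file schema
#'
#' Maps the canonical cohort columns to the column names used in a file.
#' Required columns: `case_id`, `diagnosis`. Optional columns default to
#' sensible values when absent: `source` to `"cohort"`, `ancestry` to
#' `"unknown"`, `somatic_evaluable` to `TRUE`, `germline_confirmed` to `NA`.
#' `somatic_protein` and `somatic_vaf` hold semicolon-separated values;
#' likewise `germline_hgvsc`/`germline_protein` for cases with two germline
#' variants on one row.
#'
#' @param ... Overrides of the form `canonical = "file column"`.
#' @return Named character vector.
#' @export
cohort_schema <- function(...) {
  base <- c(case_id = "case_id", source = "source", diagnosis = "diagnosis",
            ancestry = "ancestry", germline_hgvsc = "germline_hgvsc",
            germline_protein = "germline_protein",
            germline_confirmed = "germline_confirmed",
            somatic_protein = "somatic_protein", somatic_vaf = "somatic_vaf",
            somatic_evaluable = "somatic_evaluable")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) stop("unknown schema fields: ", paste(bad, collapse = ", "))
    base[names(over)] <- over
  }
  base
}

.parse_logical <- function(x, default = NA) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(default, length(x))
  out[x0 %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x0 %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' Read a cohort table into case records
#'
#' Reads a delimited cohort table (TSV by default, CSV by extension) and
#' builds one case record per `case_id`, merging multi-row cases (e.g. a case
#' listed once per germline variant). VAFs given as percentages ("23%") are
#' normalized to fractions; unrecognized ancestry labels map to `"unknown"`;
#' diagnoses such as aplastic anemia or unspecified malignancy map to
#' `"excluded"`. Rows that cannot be interpreted are collected into an error
#' report attached as `attr(, "errors")` rather than silently dropped.
#'
#' @param file Path or connection to the table.
#' @param schema Column mapping from [cohort_schema()].
#' @param aggregate_by Variant aggregation key policy, see [variant_key()].
#' @param sep Field separator; guessed from the file extension when `NULL`.
#' @return A cohort data.frame (see package overview) with attribute
#'   `"errors"` (data.frame of skipped rows and reasons).
#' @export
read_cohort <- function(file, schema = cohort_schema(),
                        aggregate_by = c("auto", "protein", "hgvsc"),
                        sep = NULL) {
  aggregate_by <- match.arg(aggregate_by)
  if (is.null(sep)) {
    sep <- if (is.character(file) && grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  }
  raw <- read.delim(file, sep = sep, header = TRUE, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (req in c("case_id", "diagnosis")) {
    if (!schema[[req]] %in% names(raw))
      stop("cohort table is missing required column '", schema[[req]], "'")
  }
  get_col <- function(canon, default) {
    nm <- schema[[canon]]
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }

  case_id <- trimws(get_col("case_id", ""))
  diagnosis <- .parse_diagnosis(get_col("diagnosis", ""))
  source <- tolower(trimws(get_col("source", "cohort")))
  source[!nzchar(source)] <- "cohort"
  ancestry <- trimws(get_col("ancestry", "unknown"))
  ancestry[!nzchar(ancestry) | tolower(ancestry) %in% c("na", "unknown", "none")] <- "unknown"
  g_hgvsc <- .split_multi(get_col("germline_hgvsc", ""))
  g_prot <- lapply(.split_multi(get_col("germline_protein", "")), normalize_protein)
  confirmed <- .parse_logical(get_col("germline_confirmed", NA), NA)
  s_prot <- lapply(.split_multi(get_col("somatic_protein", "")), normalize_protein)
  s_vaf <- lapply(.split_multi(get_col("somatic_vaf", "")), .parse_vaf)
  evaluable <- .parse_logical(get_col("somatic_evaluable", "TRUE"), TRUE)

  errors <- data.frame(row = integer(), case_id = character(),
                       problem = character(), stringsAsFactors = FALSE)
  add_error <- function(i, why) {
    errors <<- rbind(errors, data.frame(row = i, case_id = case_id[i],
                                        problem = why, stringsAsFactors = FALSE))
  }
  keep <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (!nzchar(case_id[i])) { add_error(i, "missing case_id"); keep[i] <- FALSE; next }
    if (is.na(diagnosis[i])) { add_error(i, "unrecognized diagnosis"); keep[i] <- FALSE; next }
    if (!source[i] %in% .sources) { add_error(i, "unrecognized source"); keep[i] <- FALSE; next }
    nh <- length(g_hgvsc[[i]]); np <- length(g_prot[[i]])
    if (nh > 0 && np > 0 && nh != np) {
      add_error(i, "germline hgvsc/protein length mismatch"); keep[i] <- FALSE; next
    }
    v <- s_vaf[[i]]
    if (any(!is.na(v) & (v <= 0 | v > 1))) {
      add_error(i, "VAF outside (0, 1]"); keep[i] <- FALSE; next
    }
  }

  rows <- which(keep)
  ids <- unique(case_id[rows])
  rec <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    ii <- rows[case_id[rows] == ids[j]]
    dg <- unique(diagnosis[ii])
    if (length(dg) > 1)
      stop("case '", ids[j], "' has conflicting diagnoses: ", paste(dg, collapse = ", "))
    hg <- unlist(g_hgvsc[ii]); pr <- unlist(g_prot[ii])
    n <- max(length(hg), length(pr))
    length(hg) <- n; length(pr) <- n
    hg[is.na(hg)] <- ""; pr[is.na(pr)] <- ""
    dup <- duplicated(paste(hg, pr))
    hg <- hg[!dup]; pr <- pr[!dup]
    sp <- unlist(s_prot[ii]); sv <- unlist(s_vaf[ii])
    length(sv) <- length(sp)
    sdup <- duplicated(sp)
    sp <- sp[!sdup]; sv <- sv[!sdup]
    rec[[j]] <- list(
      case_id = ids[j],
      source = source[ii[1]],
      diagnosis = dg,
      ancestry = ancestry[ii[1]],
      germline_hgvsc = hg,
      germline_protein = pr,
      germline_keys = unname(variant_key(hg, pr, by = aggregate_by)),
      germline_confirmed = any(confirmed[ii] %in% TRUE),
      somatic_hits = sp,
      somatic_vaf = sv,
      somatic_evaluable = all(evaluable[ii])
    )
  }
  out <- data.frame(
    case_id = vapply(rec, `[[`, character(1), "case_id"),
    source = vapply(rec, `[[`, character(1), "source"),
    diagnosis = vapply(rec, `[[`, character(1), "diagnosis"),
    ancestry = vapply(rec, `[[`, character(1), "ancestry"),
    germline_confirmed = vapply(rec, `[[`, logical(1), "germline_confirmed"),
    somatic_evaluable = vapply(rec, `[[`, logical(1), "somatic_evaluable"),
    stringsAsFactors = FALSE
  )
  out$germline_hgvsc <- lapply(rec, `[[`, "germline_hgvsc")
  out$germline_protein <- lapply(rec, `[[`, "germline_protein")
  out$germline_keys <- lapply(rec, function(r) {
    k <- r$germline_keys
    k[!is.na(k)]
  })
  out$somatic_hits <- lapply(rec, `[[`, "somatic_hits")
  out$somatic_vaf <- lapply(rec, `[[`, "somatic_vaf")
  attr(out, "errors") <- errors
  out
}

#' Merge non-cohort cases into a cohort without double-counting somatic hits
#'
#' Case reports outside consecutive cohorts may re-describe patients already
#' counted. The merge keeps every non-cohort case without somatic hits, and
#' keeps a non-cohort case with somatic hits only when no base-cohort case
#' carrying the same germline variant reports the identical somatic
#' protein-change set. Non-cohort cases whose `case_id` already exists in the
#' base list are skipped, which makes the merge idempotent.
#'
#' @param cohort_cases,noncohort_cases Cohort data.frames ([read_cohort()]).
#' @param registry Hotspot registry (kept for interface symmetry; the dedup
#'   rule compares raw protein-change sets, not pattern categories).
#' @return Combined cohort data.frame with attribute `"merge_log"`, a
#'   data.frame of (case_id, action, reason).
#' @export
merge_noncohort <- function(cohort_cases, noncohort_cases,
                            registry = ddx41_hotspots()) {
  hit_sig <- function(h) paste(sort(normalize_protein(h)), collapse = "|")
  base_sig <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cohort_cases))) {
    sig <- hit_sig(cohort_cases$somatic_hits[[i]])
    if (!nzchar(sig)) next
    for (k in cohort_cases$germline_keys[[i]]) {
      kk <- paste0(k, "::", sig)
      assign(kk, TRUE, envir = base_sig)
    }
  }
  log <- data.frame(case_id = character(), action = character(),
                    reason = character(), stringsAsFactors = FALSE)
  keep <- logical(nrow(noncohort_cases))
  for (i in seq_len(nrow(noncohort_cases))) {
    id <- noncohort_cases$case_id[i]
    if (id %in% cohort_cases$case_id) {
      log <- rbind(log, data.frame(case_id = id, action = "dropped",
                                   reason = "case_id already present",
                                   stringsAsFactors = FALSE))
      next
    }
    sig <- hit_sig(noncohort_cases$somatic_hits[[i]])
    if (!nzchar(sig)) {
      keep[i] <- TRUE
      log <- rbind(log, data.frame(case_id = id, action = "retained",
                                   reason = "no somatic hit",
                                   stringsAsFactors = FALSE))
      next
    }
    dup <- any(vapply(noncohort_cases$germline_keys[[i]], function(k) {
      exists(paste0(k, "::", sig), envir = base_sig)
    }, logical(1)))
    keep[i] <- !dup
    log <- rbind(log, data.frame(
      case_id = id,
      action = if (dup) "dropped" else "retained",
      reason = if (dup) "somatic hit set already reported in cohorts"
               else "unique somatic hit set",
      stringsAsFactors = FALSE))
  }
  out <- rbind(cohort_cases, noncohort_cases[keep, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "errors") <- attr(cohort_cases, "errors")
  attr(out, "merge_log") <- log
  out
}
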