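# Synthetic cohort generator. Emulates the statistical structure of an
# aggregated DDX41 case series: a patient pool with a realistic diagnosis
# and ancestry mix; a catalog of germline variants (pathogenic and benign,
# including an East-Asian founder-style entry) with case carrier
# frequencies and population allele frequencies; somatic second-hit
# patterns drawn from the multinomial model (pathogenic vector for
# deleterious-variant carriers, null vector otherwise, including
# somatic-only hits in non-carriers); binomial control allele counts; and
# class-separated predictor score distributions. Each logical component
# (cases, controls, scores) draws from its own stream derived from the
# master seed so components do not perturb one another.

.sub_seed <- function(seed, component) {
  offs <- c(cases = 11L, controls = 29L, scores = 47L, truth = 83L)
  ((as.integer(seed) %% 100000L) * 10007L + offs[[component]]) %% 2147483647L
}

# single-hit somatic variants outside the hotspot registry, used to realize
# "single non-recurrent" pattern draws
.nonrecurrent_pool <- c("L87V", "Y451C", "G586R", "Q52P", "R164W", "A225T",
                        "S21F", "E247K", "V303M", "R479Q", "T392I", "K494N")

# relative frequencies of the recurrent hotspots among single recurrent hits
.hotspot_weights <- c(R525H = 0.780, G530D = 0.075, P321L = 0.048,
                      T227M = 0.030, E345D = 0.021, G530S = 0.023,
                      D344E = 0.023)

#' Default synthetic variant catalog
#'
#' A small catalog spanning the situations the framework must handle:
#' common truncating and start-loss pathogenic variants, a pathogenic
#' missense variant, an East-Asian founder-style frameshift (carrier
#' frequency concentrated in EAS to exercise the ancestry-matching
#' downgrade), and benign missense polymorphisms present in population
#' controls. `carrier_freq_*` is the per-ancestry probability that an
#' MDS/AML case carries the variant (scaled by `other_dx_rr` in other
#' diagnosis groups); `af_*` is the population allele frequency feeding the
#' control table.
#'
#' @return data.frame with columns `variant_key`, `hgvsc`, `protein`,
#'   `variant_type`, `true_class`, `carrier_freq_NFE`, `carrier_freq_EAS`,
#'   `carrier_freq_other`, `af_NFE`, `af_EAS`, `af_other`.
#' @export
default_variant_catalog <- function() {
  data.frame(
    variant_key = c("M1?", "D140FS", "A500FS", "Y340N", "M155I", "G218S"),
    hgvsc = c("c.3G>A", "c.419dup", "c.1496dup", "c.1018T>A", "c.465G>C",
              "c.652G>A"),
    protein = c("M1?", "D140FS", "A500FS", "Y340N", "M155I", "G218S"),
    variant_type = c("start_loss", "frameshift", "frameshift", "missense",
                     "missense", "missense"),
    true_class = c("pathogenic", "pathogenic", "pathogenic", "pathogenic",
                   "benign", "benign"),
    carrier_freq_NFE = c(0.006, 0.006, 0.0005, 0.004, 0.008, 0.004),
    carrier_freq_EAS = c(0.002, 0.002, 0.015, 0.001, 0.002, 0.002),
    carrier_freq_other = c(0.004, 0.004, 0.0005, 0.002, 0.005, 0.003),
    af_NFE = c(0, 1e-6, 0, 0, 4e-4, 2e-4),
    af_EAS = c(0, 0, 1e-4, 0, 1e-4, 1e-4),
    af_other = c(0, 0, 0, 0, 3e-4, 1.5e-4),
    stringsAsFactors = FALSE
  )
}

#' Default predictor score model
#'
#' Beta-distribution parameters (shape1, shape2) on `[0, 1]` per predictor
#' and generating class. These are test fixtures expressing the qualitative
#' behavior seen empirically — pathogenic-class scores stochastically larger
#' than benign-class scores, with AlphaMissense more concentrated near the
#' extremes than REVEL — not claims about the tools' true distributions.
#'
#' A single value instead of a shape pair is taken as a point mass (useful
#' for degenerate calibration checks).
#'
#' @return Nested list `score_model$<tool>$<class> = c(shape1, shape2)`.
#' @export
default_score_model <- function() {
  list(
    revel = list(pathogenic = c(6, 3), benign = c(2.5, 5)),
    alphamissense = list(pathogenic = c(8, 1.5), benign = c(1.2, 6))
  )
}

#' Generator configuration for synthetic cohorts
#'
#' @param seed Master seed (integer); component streams are derived from it.
#' @param n_cases Number of patients in the series.
#' @param diagnosis_mix Probability vector over diagnosis groups (sums to 1).
#' @param ancestry_mix Probability vector over ancestry labels (sums to 1).
#' @param variant_catalog See [default_variant_catalog()].
#' @param pattern_model [multinomial_model()] driving somatic patterns.
#' @param score_model See [default_score_model()].
#' @param control_an Named vector of control allele numbers per ancestry.
#' @param other_dx_rr Carrier-frequency multiplier outside MDS/AML (relative
#'   ascertainment of carriers in non-MDS/AML diagnoses).
#' @param vaf_shape Beta parameters for somatic VAFs.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_cases = 2000L,
                             diagnosis_mix = c(mds_aml = 0.63,
                                               other_myeloid = 0.15,
                                               cytopenia = 0.10,
                                               lymphoid = 0.02,
                                               excluded = 0.10),
                             ancestry_mix = c(NFE = 0.55, EAS = 0.30,
                                              other = 0.10, unknown = 0.05),
                             variant_catalog = default_variant_catalog(),
                             pattern_model = multinomial_model(),
                             score_model = default_score_model(),
                             control_an = c(NFE = 1152000, EAS = 44000,
                                            other = 110000),
                             other_dx_rr = 0.25,
                             vaf_shape = c(2, 18)) {
  if (!is.data.frame(variant_catalog) || nrow(variant_catalog) == 0)
    stop("variant catalog must be a non-empty data.frame")
  for (mix in list(diagnosis_mix, ancestry_mix)) {
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
      stop("mix probabilities must be non-negative and sum to 1 (within 1e-9)")
  }
  freq_cols <- grep("^(carrier_freq|af)_", names(variant_catalog), value = TRUE)
  fr <- unlist(variant_catalog[freq_cols])
  if (any(fr < 0 | fr > 1)) stop("catalog frequencies must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 diagnosis_mix = diagnosis_mix, ancestry_mix = ancestry_mix,
                 variant_catalog = variant_catalog,
                 pattern_model = pattern_model, score_model = score_model,
                 control_an = control_an, other_dx_rr = other_dx_rr,
                 vaf_shape = vaf_shape),
            class = "generator_config")
}

.draw_hits <- function(pattern, vaf_shape) {
  hits <- switch(pattern,
    none = character(),
    single_recurrent = sample(names(.hotspot_weights), 1,
                              prob = .hotspot_weights),
    single_nonrecurrent = sample(.nonrecurrent_pool, 1),
    multiple = c(sample(names(.hotspot_weights), 1, prob = .hotspot_weights),
                 sample(.nonrecurrent_pool, 1))
  )
  list(hits = hits, vaf = rbeta(length(hits), vaf_shape[1], vaf_shape[2]))
}

#' Generate a synthetic DDX41 cohort with controls, annotations and truth
#'
#' Reproducible given the seed. Carriers of catalog variants are drawn
#' per-ancestry, with each case carrying at most one catalog variant; each
#' case's somatic pattern is drawn from the pathogenic
#' category vector if it carries any generating-class pathogenic variant and
#' from the null vector otherwise (so non-carriers exhibit rare somatic-only
#' hits). Control allele counts are binomial draws at the configured
#' population frequencies; annotations carry class-separated predictor
#' scores and per-ancestry AC/AN.
#'
#' @param config A [generator_config()].
#' @return List: `cases` (cohort data.frame), `controls` (`variant_key`,
#'   `ancestry`, `AC`, `AN`), `annotations`, `truth` (generating class and
#'   realized carrier counts), `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cat_ <- config$variant_catalog
  n <- config$n_cases
  ancestries <- names(config$ancestry_mix)

  set.seed(.sub_seed(config$seed, "cases"))
  diagnosis <- sample(names(config$diagnosis_mix), n, replace = TRUE,
                      prob = config$diagnosis_mix)
  ancestry <- sample(ancestries, n, replace = TRUE, prob = config$ancestry_mix)

  cf_col <- function(anc) {
    col <- paste0("carrier_freq_", anc)
    if (col %in% names(cat_)) cat_[[col]] else cat_[["carrier_freq_other"]]
  }
  # each case carries at most one catalog variant (dual-variant carriers are
  # rare enough in real series to neglect); carriage is a single categorical
  # draw over the catalog plus "none"
  pr <- vapply(seq_len(nrow(cat_)), function(v) {
    p <- vapply(ancestry, function(a) cf_col(a)[v], numeric(1))
    p[diagnosis != "mds_aml"] <- p[diagnosis != "mds_aml"] * config$other_dx_rr
    p
  }, numeric(n))
  pr <- matrix(pr, nrow = n)
  tot <- rowSums(pr)
  pr[tot > 1, ] <- pr[tot > 1, , drop = FALSE] / tot[tot > 1]
  cum <- pr
  for (v in seq_len(ncol(pr))[-1]) cum[, v] <- cum[, v - 1] + pr[, v]
  u <- runif(n)
  pick <- rowSums(u > cum) + 1L          # catalog index, or nv + 1 for none
  carrier <- matrix(FALSE, n, nrow(cat_),
                    dimnames = list(NULL, cat_$variant_key))
  has <- pick <= nrow(cat_)
  carrier[cbind(which(has), pick[has])] <- TRUE
  is_path_carrier <- carrier[, cat_$true_class == "pathogenic", drop = FALSE]
  is_path_carrier <- rowSums(is_path_carrier) > 0
  pattern <- vapply(is_path_carrier, function(z) {
    p <- if (z) config$pattern_model$p_path else config$pattern_model$p_null
    sample(.patterns, 1, prob = p)
  }, character(1))
  hits <- lapply(pattern, .draw_hits, vaf_shape = config$vaf_shape)

  germ_keys <- apply(carrier, 1, function(cc) cat_$variant_key[cc],
                     simplify = FALSE)
  germ_hg <- apply(carrier, 1, function(cc) cat_$hgvsc[cc], simplify = FALSE)
  cases <- data.frame(
    case_id = sprintf("SYN%05d", seq_len(n)),
    source = "cohort",
    diagnosis = diagnosis,
    ancestry = ancestry,
    germline_confirmed = runif(n) < 0.25,
    somatic_evaluable = TRUE,
    stringsAsFactors = FALSE
  )
  cases$germline_hgvsc <- germ_hg
  cases$germline_protein <- germ_keys
  cases$germline_keys <- germ_keys
  cases$somatic_hits <- lapply(hits, `[[`, "hits")
  cases$somatic_vaf <- lapply(hits, `[[`, "vaf")

  set.seed(.sub_seed(config$seed, "controls"))
  controls <- do.call(rbind, lapply(seq_len(nrow(cat_)), function(v) {
    do.call(rbind, lapply(names(config$control_an), function(anc) {
      an <- config$control_an[[anc]]
      af_col <- paste0("af_", anc)
      af <- if (af_col %in% names(cat_)) cat_[[af_col]][v] else 0
      data.frame(variant_key = cat_$variant_key[v], ancestry = anc,
                 AC = rbinom(1, an, af), AN = an, stringsAsFactors = FALSE)
    }))
  }))

  set.seed(.sub_seed(config$seed, "scores"))
  sm <- config$score_model
  draw_score <- function(tool, cls) {
    sh <- sm[[tool]][[cls]]
    if (length(sh) == 1) sh else rbeta(1, sh[1], sh[2])
  }
  ann <- cat_[, c("variant_key", "hgvsc", "protein", "variant_type")]
  ann$revel <- NA_real_; ann$alphamissense <- NA_real_
  for (v in seq_len(nrow(cat_))) {
    if (cat_$variant_type[v] %in% c("missense", "inframe")) {
      ann$revel[v] <- draw_score("revel", cat_$true_class[v])
      ann$alphamissense[v] <- draw_score("alphamissense", cat_$true_class[v])
    }
  }
  ann$spliceai <- ifelse(cat_$variant_type == "canonical_splice",
                         runif(nrow(cat_), 0.8, 1),
                         runif(nrow(cat_), 0, 0.05))
  ann$splice_region <- cat_$variant_type == "canonical_splice"
  for (anc in names(config$control_an)) {
    acs <- controls$AC[controls$ancestry == anc]
    ans <- controls$AN[controls$ancestry == anc]
    ann[[paste0("AC_", anc)]] <- acs[match(ann$variant_key,
                                           controls$variant_key[controls$ancestry == anc])]
    ann[[paste0("AN_", anc)]] <- ans[match(ann$variant_key,
                                           controls$variant_key[controls$ancestry == anc])]
  }

  truth <- cat_
  truth$n_carriers <- colSums(carrier)
  rownames(controls) <- rownames(truth) <- rownames(ann) <- NULL

  list(cases = cases, controls = controls, annotations = ann, truth = truth,
       config = config)
}

#' Generate a labeled predictor-score table
#'
#' Draws per-class predictor scores from the configured score model, for
#' testing the ROC/AUC machinery against known class separation. The default
#' class sizes mirror the scale of a missense truth-set calibration (61
#' pathogenic, 503 benign).
#'
#' @param config A [generator_config()] (its seed and `score_model` are
#'   used).
#' @param n_pathogenic,n_benign Class sizes.
#' @return data.frame: `variant_key`, `label`, `revel`, `alphamissense`.
#' @export
generate_truth_scores <- function(config = generator_config(),
                                  n_pathogenic = 61, n_benign = 503) {
  stopifnot(inherits(config, "generator_config"))
  sm <- config$score_model
  set.seed(.sub_seed(config$seed, "truth"))
  lab <- c(rep("pathogenic_truth", n_pathogenic),
           rep("benign_truth", n_benign))
  draw1 <- function(sh, n) if (length(sh) == 1) rep(sh, n) else rbeta(n, sh[1], sh[2])
  draw <- function(tool) {
    c(draw1(sm[[tool]]$pathogenic, n_pathogenic),
      draw1(sm[[tool]]$benign, n_benign))
  }
  data.frame(
    variant_key = sprintf("TS%04d", seq_along(lab)),
    label = lab,
    revel = draw("revel"),
    alphamissense = draw("alphamissense"),
    stringsAsFactors = FALSE
  )
}
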