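# Builders for cohort-format data.frames used across the tests. All fixtures
# are constructed in code; nothing is read from disk except temp files the
# reader tests write themselves.

empty_cohort <- function() {
  out <- data.frame(case_id = character(), source = character(),
                    diagnosis = character(), ancestry = character(),
                    germline_confirmed = logical(),
                    somatic_evaluable = logical(), stringsAsFactors = FALSE)
  out$germline_hgvsc <- list()
  out$germline_protein <- list()
  out$germline_keys <- list()
  out$somatic_hits <- list()
  out$somatic_vaf <- list()
  out
}

# one row per case; germline/hits given as lists of character vectors
make_cases <- function(case_id, germline = list(), hits = list(),
                       diagnosis = "mds_aml", ancestry = "NFE",
                       source = "cohort", evaluable = TRUE,
                       confirmed = FALSE) {
  n <- length(case_id)
  recycle <- function(x) if (length(x) == 1) rep(x, n) else x
  if (length(germline) == 0) germline <- rep(list(character()), n)
  if (length(hits) == 0) hits <- rep(list(character()), n)
  out <- data.frame(case_id = case_id, source = recycle(source),
                    diagnosis = recycle(diagnosis),
                    ancestry = recycle(ancestry),
                    germline_confirmed = recycle(confirmed),
                    somatic_evaluable = recycle(evaluable),
                    stringsAsFactors = FALSE)
  out$germline_hgvsc <- rep(list(character()), n)
  out$germline_protein <- germline
  out$germline_keys <- germline
  out$somatic_hits <- hits
  out$somatic_vaf <- lapply(hits, function(h) rep(NA_real_, length(h)))
  out
}

# carriers of `key` realizing the four somatic-pattern categories, plus
# optional non-carrier cases with the same pattern layout
pattern_cohort <- function(key, n1 = 0, n2 = 0, n3 = 0, n0 = 0,
                           id_prefix = key, diagnosis = "mds_aml",
                           ancestry = "NFE", germline = TRUE) {
  n <- n1 + n2 + n3 + n0
  if (n == 0) return(empty_cohort())
  hits <- c(rep(list("R525H"), n1),
            rep(list("Q52P"), n2),
            rep(list(c("R525H", "L87V")), n3),
            rep(list(character()), n0))
  germ <- if (germline) rep(list(key), n) else rep(list(character()), n)
  make_cases(sprintf("%s_%04d", id_prefix, seq_len(n)), germline = germ,
             hits = hits, diagnosis = diagnosis, ancestry = ancestry)
}

# non-carrier background realizing given pattern counts, split of the single
# hits into hotspot vs non-hotspot
noncarrier_cohort <- function(n_hotspot, n_nonrec, n_multi, n_none,
                              id_prefix = "NC") {
  n <- n_hotspot + n_nonrec + n_multi + n_none
  hits <- c(rep(list("R525H"), n_hotspot),
            rep(list("Q52P"), n_nonrec),
            rep(list(c("L87V", "Y451C")), n_multi),
            rep(list(character()), n_none))
  make_cases(sprintf("%s_%05d", id_prefix, seq_len(n)),
             germline = rep(list(character()), n), hits = hits)
}

make_controls <- function(key, ac, an,
                          ancestry = names(ac)) {
  data.frame(variant_key = key, ancestry = ancestry,
             AC = unname(ac), AN = unname(an), stringsAsFactors = FALSE)
}

make_annotation <- function(key, variant_type = "missense",
                            revel = NA_real_, alphamissense = NA_real_,
                            spliceai = 0.01, splice_region = FALSE,
                            ac = c(NFE = 0, EAS = 0),
                            an = c(NFE = 1e6, EAS = 5e4)) {
  ann <- data.frame(variant_key = key, hgvsc = "", protein = key,
                    variant_type = variant_type, revel = revel,
                    alphamissense = alphamissense, spliceai = spliceai,
                    splice_region = splice_region, stringsAsFactors = FALSE)
  for (g in names(ac)) {
    ann[[paste0("AC_", g)]] <- unname(ac[[g]])
    ann[[paste0("AN_", g)]] <- unname(an[[g]])
  }
  ann
}

# rank-based empirical AUC (Mann-Whitney with tie correction); independent
# of the package's ROC path
auc_oracle <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# two-sided Fisher exact p by full hypergeometric enumeration
# (probability-mass rule)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(m, k)
  px <- dhyper(xs, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(px[px <= p_obs * (1 + 1e-7)])
}
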