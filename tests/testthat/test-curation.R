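test_that("evidence codes carry the Bayesian point scale", {
  expect_equal(evidence_code("PVS1", "very_strong")$points, 8)
  expect_equal(evidence_code("PS4", "strong")$points, 4)
  expect_equal(evidence_code("PS4", "moderate")$points, 2)
  expect_equal(evidence_code("PM2", "supporting")$points, 1)
  expect_equal(evidence_code("BP4", "supporting")$points, -1)
  expect_equal(evidence_code("PP4", "not_met")$points, 0)
  expect_equal(evidence_code("BP4", "supporting")$direction, "benign")
})

test_that("combine_codes maps point totals to the five tiers", {
  lp <- combine_codes(list(evidence_code("PVS1", "very_strong"),
                           evidence_code("PM2", "supporting")))
  expect_equal(lp$total_points, 9)
  expect_equal(lp$tier, "LP")

  expect_equal(combine_codes(list())$tier, "VUS")
  expect_equal(combine_codes(list(evidence_code("PP3", "not_met")))$total_points, 0)

  mix <- combine_codes(list(evidence_code("PS4", "moderate"),
                            evidence_code("PP4", "strong"),
                            evidence_code("PP3", "supporting")))
  expect_equal(mix$total_points, 7)
  expect_equal(mix$tier, "LP")

  expect_equal(combine_codes(list(evidence_code("PVS1", "very_strong"),
                                  evidence_code("PS4", "strong")))$tier, "P")
  expect_equal(combine_codes(list(evidence_code("BP4", "supporting")))$tier, "LB")

  expect_error(combine_codes(list(evidence_code("PM2", "supporting"),
                                  evidence_code("PM2", "supporting"))),
               "duplicate")
})

test_that("adding pathogenic evidence never lowers the tier, benign never raises", {
  tier_rank <- function(t) match(t, c("B", "LB", "VUS", "LP", "P"))
  set.seed(71)
  strengths <- c("supporting", "moderate", "strong", "very_strong")
  for (i in 1:30) {
    base_codes <- list(evidence_code("PS4", sample(c("not_met", strengths), 1)),
                       evidence_code("PP4", sample(c("not_met", strengths), 1)))
    base <- combine_codes(base_codes)
    plus <- combine_codes(c(base_codes, list(evidence_code("PVS1", sample(strengths, 1)))))
    minus <- combine_codes(c(base_codes, list(evidence_code("BP4", "supporting"))))
    expect_gte(tier_rank(plus$tier), tier_rank(base$tier))
    expect_lte(tier_rank(minus$tier), tier_rank(base$tier))
  }
})

test_that("PVS1 and PM2 follow their policy tables", {
  expect_equal(assign_pvs1("frameshift")$strength, "very_strong")
  expect_equal(assign_pvs1("nonsense")$strength, "very_strong")
  expect_equal(assign_pvs1("canonical_splice")$strength, "very_strong")
  expect_equal(assign_pvs1("start_loss")$strength, "strong")
  expect_equal(assign_pvs1("missense")$strength, "not_met")

  expect_equal(assign_pm2(c(NFE = 0, EAS = 0), c(NFE = 1e6, EAS = 5e4))$strength,
               "supporting")
  # M155I-like population frequency 0.04%
  expect_equal(assign_pm2(c(NFE = 460), c(NFE = 1.15e6))$strength, "not_met")
  # boundary: at the threshold still supporting
  expect_equal(assign_pm2(c(NFE = 2), c(NFE = 1e5))$strength, "supporting")
  expect_equal(assign_pm2(numeric(), numeric())$strength, "not_met")
  expect_error(assign_pm2(c(NFE = 10), c(NFE = 5)), "exceeds")
})

curation_fixture <- function() {
  cases <- rbind(
    pattern_cohort("T1FS", n1 = 3),                      # truncating, 3 hotspot hits
    pattern_cohort("M155I", n2 = 3, n0 = 36),            # VUS-like polymorphism
    make_cases(sprintf("bg%04d", 1:3400))                # non-carrier pool
  )
  controls <- rbind(
    make_controls("T1FS", ac = c(NFE = 0, EAS = 0), an = c(NFE = 1.15e6, EAS = 4e4)),
    make_controls("M155I", ac = c(NFE = 460, EAS = 4), an = c(NFE = 1.15e6, EAS = 4e4)),
    make_controls("NOCARR", ac = c(NFE = 12, EAS = 1), an = c(NFE = 1.15e6, EAS = 4e4))
  )
  annotations <- rbind(
    make_annotation("T1FS", "frameshift", ac = c(NFE = 0, EAS = 0),
                    an = c(NFE = 1.15e6, EAS = 4e4)),
    make_annotation("M155I", "missense", revel = 0.25, alphamissense = 0.31,
                    ac = c(NFE = 460, EAS = 4), an = c(NFE = 1.15e6, EAS = 4e4)),
    make_annotation("NOCARR", "missense", revel = 0.5, alphamissense = 0.5,
                    ac = c(NFE = 12, EAS = 1), an = c(NFE = 1.15e6, EAS = 4e4))
  )
  list(cases = cases, controls = controls, annotations = annotations)
}

test_that("curate_variant composes the evidence pipeline transparently", {
  fx <- curation_fixture()

  # pathogenic truncating variant: PVS1 + PM2 + saturated PP4 -> P
  rep1 <- curate_variant("T1FS", fx$cases, fx$controls, fx$annotations)
  expect_equal(rep1$classification$tier, "P")
  expect_equal(rep1$codes$PVS1$strength, "very_strong")
  expect_equal(rep1$codes$PM2$strength, "supporting")
  expect_equal(rep1$codes$PP4$strength, "very_strong")
  expect_true(rep1$oddspath_capped)
  expect_equal(rep1$oddspath, 1e6)
  expect_length(rep1$carriers, 3)

  # report equals the manual composition of its sub-operations
  tal <- tally_patterns("T1FS", fx$cases)
  expect_equal(rep1$pattern_counts, tal)
  expect_equal(rep1$codes$PS4$strength,
               variant_ps4("T1FS", fx$cases, fx$controls)$strength)

  # common-polymorphism pattern: nothing decisive fires -> VUS
  rep2 <- curate_variant("M155I", fx$cases, fx$controls, fx$annotations)
  expect_equal(rep2$codes$PP4$strength, "not_met")
  expect_lt(rep2$oddspath, 2.08)
  expect_equal(rep2$codes$PM2$strength, "not_met")
  expect_equal(rep2$classification$tier, "VUS")

  # no carriers, mid-range scores, not rare enough for PM2 -> VUS
  rep3 <- curate_variant("NOCARR", fx$cases, fx$controls, fx$annotations)
  expect_equal(rep3$classification$tier, "VUS")
  expect_equal(rep3$oddspath, 1)
  expect_length(rep3$carriers, 0)

  expect_error(curate_variant("MISSING", fx$cases, fx$controls, fx$annotations),
               "not found")
})

test_that("manual overrides replace a code with an audit note", {
  fx <- curation_fixture()
  cfg <- curation_config(overrides = list(
    M155I = list(PP4 = "strong", note = "functional assay evidence")))
  rep <- curate_variant("M155I", fx$cases, fx$controls, fx$annotations, cfg)
  expect_equal(rep$codes$PP4$strength, "strong")
  expect_match(rep$codes$PP4$rationale, "MANUAL OVERRIDE")
  expect_match(rep$codes$PP4$rationale, "functional assay")
})

test_that("bulk curation is consistent, ordered, deterministic and fault-tolerant", {
  fx <- curation_fixture()
  keys <- c("T1FS", "M155I", "NOCARR")
  tab <- bulk_curate(keys, fx$cases, fx$controls, fx$annotations)
  expect_equal(tab$variant_key, keys)
  for (k in keys) {
    solo <- curate_variant(k, fx$cases, fx$controls, fx$annotations)
    expect_equal(tab$tier[tab$variant_key == k], solo$classification$tier)
    expect_equal(tab$total_points[tab$variant_key == k],
                 solo$classification$total_points)
  }

  expect_equal(nrow(bulk_curate(character(), fx$cases, fx$controls,
                                fx$annotations)), 0)

  tab2 <- bulk_curate(keys, fx$cases, fx$controls, fx$annotations)
  expect_identical(tab, tab2)

  tab3 <- bulk_curate(c("T1FS", "MISSING"), fx$cases, fx$controls,
                      fx$annotations)
  expect_equal(tab3$tier, c("P", NA))
  expect_match(tab3$error[2], "not found")
})

test_that("YAML round-trips the curation configuration", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    tool = "revel",
    spliceai_cutoff = 0.5,
    af_threshold = 1e-4,
    registry = c("Q99X"),
    model = list(p_path = c(0.5, 0.2, 0.01, 0.29),
                 p_null = c(0.01, 0.01, 0.01, 0.97), prior = 0.2),
    thresholds = list(supporting = 2, moderate = 4, strong = 18, very_strong = 300),
    ps4 = list(min_carriers = 5)
  ), f)
  cfg <- read_curation_config(f)
  expect_equal(cfg$tool, "revel")
  expect_equal(cfg$spliceai_cutoff, 0.5)
  expect_equal(cfg$af_threshold, 1e-4)
  expect_true("Q99X" %in% cfg$registry)
  expect_true("R525H" %in% cfg$registry)
  expect_equal(cfg$model$prior, 0.2)
  expect_equal(unname(cfg$thresholds["strong"]), 18)
  expect_equal(cfg$ps4$min_carriers, 5)
})
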