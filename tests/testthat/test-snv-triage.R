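th <- triage_thresholds()

test_that("quality filter implements both mode rule sets", {
  # depth below 10 fails everywhere
  expect_false(quality_filter(9, 1.0, FALSE, th, "primary")$pass)
  expect_false(quality_filter(9, 1.0, TRUE, th, "reanalysis")$pass)
  # primary: VAF below 30% fails; reanalysis mosaic band keeps it
  expect_false(quality_filter(100, 0.29, FALSE, th, "primary")$pass)
  expect_true(quality_filter(100, 0.29, FALSE, th, "reanalysis")$pass)
  # low-depth band: LoF 20% vs non-LoF 25%
  expect_true(quality_filter(30, 0.20, TRUE, th, "reanalysis")$pass)
  expect_false(quality_filter(30, 0.24, FALSE, th, "reanalysis")$pass)
  expect_true(quality_filter(30, 0.25, FALSE, th, "reanalysis")$pass)
  # depth exactly 50 is in the mosaic band
  expect_true(quality_filter(50, 0.10, FALSE, th, "reanalysis")$pass)
  expect_false(quality_filter(49, 0.10, FALSE, th, "reanalysis")$pass)
  # homozygous passes both modes
  expect_true(quality_filter(100, 1.0, FALSE, th, "primary")$pass)
  expect_true(quality_filter(100, 1.0, FALSE, th, "reanalysis")$pass)
  # depth zero yields a dedicated reason
  q <- quality_filter(0, NA, FALSE, th, "primary")
  expect_false(q$pass)
  expect_identical(q$reason, "no_coverage")
})

test_that("frequency filter discards gnomAD AC strictly above 4", {
  expect_false(frequency_filter(5L, th))
  expect_true(frequency_filter(4L, th))
  expect_true(frequency_filter(NA_integer_, th))
  expect_true(frequency_filter(0L, th))
})

test_that("splice ensemble takes the max over available scores", {
  expect_true(splice_ensemble(NA, 0.6, NA, NA))
  expect_false(splice_ensemble(0.49, 0.49, 0.49, 0.49))
  expect_true(splice_ensemble(0.5, NA, NA, NA))   # boundary inclusive
  expect_false(splice_ensemble(NA, NA, NA, NA))   # no evidence
})

test_that("consequence filter keeps protein-affecting or splice hits", {
  expect_true(consequence_filter("synonymous", TRUE))
  expect_false(consequence_filter("intronic", FALSE))
  expect_true(consequence_filter("missense", FALSE))
  expect_true(consequence_filter("stop_loss", FALSE))
  expect_true(consequence_filter("inframe_indel", FALSE))
  expect_false(consequence_filter("other", FALSE))
})

test_that("missense majority vote uses available predictors only", {
  expect_true(missense_majority_vote(5L, 10L, th))
  expect_false(missense_majority_vote(4L, 10L, th))
  expect_false(missense_majority_vote(0L, 0L, th))  # no evidence
  expect_true(missense_majority_vote(1L, 1L, th))
})

test_that("strong effect combines the four routes with printed cutoffs", {
  se <- function(...) strong_effect(...)
  expect_true(se("frameshift", NA, 0L, 0L, FALSE, th))
  expect_true(se("inframe_indel", -2.5, 0L, 0L, FALSE, th))
  expect_false(se("inframe_indel", -2.4, 0L, 0L, FALSE, th))
  expect_warning(
    expect_false(se("inframe_indel", NA, 0L, 0L, FALSE, th)),
    "missing PROVEAN")
  expect_true(se("missense", NA, 6L, 10L, FALSE, th))
  expect_false(se("missense", NA, 4L, 10L, FALSE, th))
  expect_true(se("synonymous", NA, 0L, 0L, TRUE, th))
})

test_that("prioritization routes behave in both modes", {
  any_th <- th
  con_th <- triage_thresholds(priority_mode = "conjunction")
  # ClinVar route alone suffices in 'any'
  expect_true(prioritize("pathogenic", 2L, FALSE, any_th)$candidate)
  # absent + strong but no ClinVar: any yes, conjunction no
  expect_true(prioritize("absent", NA_integer_, TRUE, any_th)$candidate)
  expect_false(prioritize("absent", NA_integer_, TRUE, con_th)$candidate)
  expect_true(prioritize("pathogenic", 0L, TRUE, con_th)$candidate)
  # nothing satisfied
  expect_false(prioritize("absent", 3L, FALSE, any_th)$candidate)
  p <- prioritize("likely_pathogenic", NA_integer_, TRUE, any_th)
  expect_identical(p$routes, "clinvar_plp;gnomad_absent;strong_effect")
})

test_that("recurrent artifacts are flagged at >3 distinct carriers", {
  mk <- function(sample, ac = NA_integer_, status = "candidate")
    data.table::data.table(sample_id = sample, chrom = "chr1", pos = 500L,
                           ref = "A", alt = "T", gnomad_ac = ac,
                           status = status)
  four <- data.table::rbindlist(lapply(sprintf("S%d", 1:4), mk))
  out <- flag_recurrent_artifacts(four, th)
  expect_true(all(out$artifact_flag))
  three <- data.table::rbindlist(lapply(sprintf("S%d", 1:3), mk))
  expect_false(any(flag_recurrent_artifacts(three, th)$artifact_flag))
  # present in gnomAD: never flagged no matter how many carriers
  five_ac <- data.table::rbindlist(lapply(sprintf("S%d", 1:5), mk, ac = 2L))
  expect_false(any(flag_recurrent_artifacts(five_ac, th)$artifact_flag))
  # flag only set on surviving records
  mixed <- data.table::rbindlist(c(lapply(sprintf("S%d", 1:4), mk),
                                   list(mk("S5", status = "discarded_quality"))))
  out <- flag_recurrent_artifacts(mixed, th)
  expect_identical(out$artifact_flag, c(rep(TRUE, 4), FALSE))
})

test_that("recessive filter applies AF/homozygote cutoffs and pairs hets", {
  v <- rbind(
    make_variant(pos = 1L, gene = "GA", zygosity = "hom", gnomad_af = 0.001),
    make_variant(pos = 2L, gene = "GA", zygosity = "hom",
                 gnomad_ac = 12L, gnomad_af = 4.8e-5, gnomad_hom = 5L),
    make_variant(pos = 3L, gene = "GB", zygosity = "hom",
                 gnomad_af = 5e-4),
    make_variant(pos = 4L, gene = "GC", zygosity = "het",
                 gnomad_af = 5e-4),
    make_variant(pos = 5L, gene = "GC", zygosity = "het"),
    make_variant(pos = 6L, gene = "GD", zygosity = "het"))
  out <- recessive_filter(validate_variants(v))
  expect_equal(out$homozygous$pos, 3L)           # af/hom cutoffs applied
  expect_setequal(out$compound_het$pos, c(4L, 5L))
  expect_true(all(out$compound_het$phase == "unphased"))
})

test_that("run_triage reproduces a hand-enumerated toy decision table", {
  v <- rbind(
    make_variant(pos = 20000L),                               # off panel
    make_variant(pos = 101L, depth = 5L, alt_reads = 2L),     # low depth
    make_variant(pos = 102L, depth = 100L, alt_reads = 20L),  # low vaf (primary)
    make_variant(pos = 103L, gnomad_ac = 9L),                 # common
    make_variant(pos = 104L, consequence = "intronic"),       # consequence
    make_variant(pos = 105L, consequence = "synonymous",
                 spliceai = 0.9),                             # splice rescue
    make_variant(pos = 106L, gnomad_ac = 3L, n_pred_avail = 10L,
                 n_pred_del = 2L),                            # retained
    make_variant(pos = 107L, consequence = "frameshift"))     # candidate
  res <- run_triage(validate_variants(v), toy_panel(), th, "primary")
  expect_identical(
    res$decisions$status,
    c("off_panel", "discarded_quality", "discarded_quality",
      "discarded_frequency", "discarded_consequence", "candidate",
      "retained", "candidate"))
  expect_equal(res$summary$kept_total, 3)
  expect_equal(res$summary$candidate_total, 2)
  # the same input in reanalysis keeps the mosaic-band variant too
  res_r <- run_triage(validate_variants(v), toy_panel(), th, "reanalysis")
  expect_identical(res_r$decisions$status[3], "candidate")
})

test_that("all variants below min depth are fully eliminated", {
  v <- do.call(rbind, lapply(1:6, function(i)
    make_variant(pos = 100L + i, depth = 5L, alt_reads = 2L)))
  res <- run_triage(validate_variants(v), toy_panel(), th, "primary")
  expect_equal(res$summary$eliminated_fraction, 1.0)
})

test_that("reanalysis retains a superset of primary on random cohorts", {
  for (seed in c(5, 17)) {
    co <- simulate_cohort(sim_config(n_patients = 25, background_mean = 50,
                                     seed = seed))
    p <- run_triage(co$variants, co$panel, th, "primary")
    r <- run_triage(co$variants, co$panel, th, "reanalysis")
    kept_p <- p$decisions$status %in% c("retained", "candidate")
    kept_r <- r$decisions$status %in% c("retained", "candidate")
    expect_true(all(kept_r[kept_p]))
  }
})

test_that("tightening thresholds never grows the retained set", {
  co <- simulate_cohort(sim_config(n_patients = 20, background_mean = 60,
                                   seed = 23))
  kept <- function(t) {
    d <- run_triage(co$variants, co$panel, t, "primary")$decisions
    which(d$status %in% c("retained", "candidate"))
  }
  base <- kept(th)
  deeper <- kept(triage_thresholds(min_depth = 40L))
  stricter_vaf <- kept(triage_thresholds(min_vaf_primary = 0.45))
  rarer <- kept(triage_thresholds(max_gnomad_ac = 0L))
  expect_true(all(deeper %in% base))
  expect_true(all(stricter_vaf %in% base))
  expect_true(all(rarer %in% base))
})
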