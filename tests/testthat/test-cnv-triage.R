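cth <- cnv_thresholds()

mk_call <- function(sample = "S1", chrom = "chr1", start = 1000L,
                    end = 101000L, type = "DEL", caller = "A", phred = 50) {
  data.table::data.table(sample_id = sample, chrom = chrom, start = start,
                         end = end, type = type, caller = caller,
                         phred = phred)
}

test_that("reciprocal overlap matches base counting and is symmetric", {
  expect_equal(reciprocal_overlap(100, 200, 150, 250), 0.5)
  expect_equal(reciprocal_overlap(100, 200, 100, 200), 1.0)
  expect_equal(reciprocal_overlap(100, 200, 300, 400), 0.0)
  expect_equal(reciprocal_overlap(0, 10, 5, 100), 5 / 95)
  expect_error(reciprocal_overlap(10, 10, 0, 5), "zero")
  set.seed(77)
  s1 <- sample.int(1000, 1000); e1 <- s1 + sample.int(500, 1000, replace = TRUE)
  s2 <- sample.int(1000, 1000); e2 <- s2 + sample.int(500, 1000, replace = TRUE)
  got <- reciprocal_overlap(s1, e1, s2, e2)
  sym <- reciprocal_overlap(s2, e2, s1, e1)
  base_count <- vapply(seq_along(s1), function(i) {
    shared <- length(intersect(seq(s1[i], e1[i] - 1), seq(s2[i], e2[i] - 1)))
    min(shared / (e1[i] - s1[i]), shared / (e2[i] - s2[i]))
  }, numeric(1))
  expect_equal(got, base_count, tolerance = 1e-12)
  expect_equal(got, sym)
  expect_true(all(got >= 0 & got <= 1))
})

test_that("cohort recurrence filter discards at >3 matching others", {
  base <- lapply(sprintf("S%d", 1:5), function(s) mk_call(sample = s))
  five <- data.table::rbindlist(base)
  expect_false(cohort_recurrence_filter(five, cth)[1])  # 4 others
  four <- data.table::rbindlist(base[1:4])
  expect_true(all(cohort_recurrence_filter(four, cth)))  # only 3 others
  # below the 0.8 reciprocal-overlap bar nothing matches
  shifted <- data.table::rbindlist(lapply(seq_len(5), function(i)
    mk_call(sample = sprintf("S%d", i), start = 1000L + (i - 1L) * 25000L,
            end = 101000L + (i - 1L) * 25000L)))
  expect_true(all(cohort_recurrence_filter(shifted, cth)))
  # same-sample and cross-type matches never count
  same_sample <- data.table::rbindlist(
    lapply(1:5, function(i) mk_call(caller = c("A", "B")[1 + i %% 2])))
  same_sample$sample_id <- "S1"
  expect_error(cohort_recurrence_filter(same_sample, cth), NA)
})

test_that("population SV filter needs RO >= 0.9 and a common record", {
  call <- mk_call()
  sv <- function(start, end, ac = NA, af = NA, type = "DEL")
    data.table::data.table(chrom = "chr1", start = start, end = end,
                           type = type, ac = ac, af = af)
  # RO = 0.9, AC 11 -> discard
  expect_false(population_sv_filter(call, sv(1000, 91000, ac = 11), cth))
  # boundary AC = 10 with absent AF -> keep
  expect_true(population_sv_filter(call, sv(1000, 91000, ac = 10), cth))
  # RO just below 0.9 -> keep even for a very common record
  expect_true(population_sv_filter(call, sv(1000, 89900, af = 0.5), cth))
  # frequency route
  expect_false(population_sv_filter(call, sv(1000, 101000, af = 2e-4), cth))
  expect_true(population_sv_filter(call, sv(1000, 101000, af = 1e-4), cth))
  # type mismatch never matches
  expect_true(population_sv_filter(call, sv(1000, 101000, ac = 100,
                                            type = "DUP"), cth))
})

test_that("single-caller quality filter spares dual-supported calls", {
  solo_a <- mk_call(phred = 19)
  expect_false(caller_concordance_filter(solo_a, cth))
  expect_true(caller_concordance_filter(mk_call(phred = 20), cth))
  solo_b <- mk_call(caller = "B", phred = 3)
  expect_true(caller_concordance_filter(solo_b, cth))   # boundary
  expect_false(caller_concordance_filter(mk_call(caller = "B", phred = 2.9),
                                         cth))
  both <- rbind(mk_call(phred = 5), mk_call(caller = "B", phred = 1))
  expect_true(all(caller_concordance_filter(both, cth)))
})

test_that("prioritization needs a dual pair at A>=30 and B>=20", {
  pair <- function(pa, pb) rbind(mk_call(phred = pa),
                                 mk_call(caller = "B", phred = pb))
  expect_true(all(prioritize_cnv(pair(30, 20), cth)))
  expect_false(any(prioritize_cnv(pair(29, 25), cth)))
  expect_false(any(prioritize_cnv(pair(45, 19.9), cth)))
  expect_false(prioritize_cnv(mk_call(phred = 99), cth))  # no B support
})

test_that("run_cnv_triage matches hand enumeration on a toy cohort", {
  calls_a <- data.table::rbindlist(list(
    mk_call("S1", start = 1000L, end = 101000L, phred = 60),      # dual cand
    mk_call("S2", start = 5e6L, end = 5.1e6L, phred = 10),        # solo lowq
    mk_call("S3", start = 9e6L, end = 9.1e6L, phred = 80),        # popsv hit
    mk_call("S4", start = 13e6L, end = 13.1e6L, phred = 55)))     # solo ok
  calls_b <- data.table::rbindlist(list(
    mk_call("S1", start = 2000L, end = 101000L, caller = "B", phred = 30),
    mk_call("S5", start = 17e6L, end = 17.1e6L, caller = "B", phred = 12)))
  popsv <- data.table::data.table(chrom = "chr1", start = 9e6L,
                                  end = 9.1e6L, type = "DEL", ac = 50L,
                                  af = 0.01)
  res <- run_cnv_triage(calls_a, calls_b, popsv)
  dec <- res$decisions
  expect_identical(dec[dec$sample_id == "S1" & dec$caller == "A", status],
                   "candidate")
  expect_identical(dec[dec$sample_id == "S1" & dec$caller == "B", status],
                   "candidate")
  expect_identical(dec[dec$sample_id == "S2", status],
                   "discarded_single_lowq")
  expect_identical(dec[dec$sample_id == "S3", status], "discarded_popsv")
  expect_identical(dec[dec$sample_id == "S4", status], "retained")
  expect_identical(dec[dec$sample_id == "S5", status], "retained")
  # merged event: union of the dual pair
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$start, 1000L)
  expect_equal(res$events$end, 101000L)
})

test_that("duplicating the cohort makes every call recurrent", {
  co <- simulate_cohort(sim_config(n_patients = 10, background_mean = 5,
                                   seed = 31, cnv_background_mean = 1))
  a <- co$cnv_a; b <- co$cnv_b
  dup <- function(x) data.table::rbindlist(lapply(1:5, function(k) {
    y <- data.table::copy(x); y$sample_id <- paste0(y$sample_id, "_", k); y
  }))
  res <- run_cnv_triage(dup(a), dup(b), co$popsv)
  expect_true(all(res$decisions$status == "discarded_recurrent"))
})

test_that("empty inputs yield empty outputs", {
  empty <- data.table::data.table(sample_id = character(),
                                  chrom = character(), start = integer(),
                                  end = integer(), type = character(),
                                  phred = numeric())
  res <- run_cnv_triage(empty, empty, NULL)
  expect_equal(nrow(res$decisions), 0L)
  expect_equal(nrow(res$events), 0L)
})

test_that("full CNV pipeline equals the brute-force oracle", {
  co <- simulate_cohort(sim_config(n_patients = 30, background_mean = 5,
                                   seed = 13, cnv_background_mean = 3))
  res <- run_cnv_triage(co$cnv_a, co$cnv_b, co$popsv)
  combined <- rbind(co$cnv_a, co$cnv_b)
  expect_identical(res$decisions$status, oracle_cnv_all(combined, co$popsv))
})
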