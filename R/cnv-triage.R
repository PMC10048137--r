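# Dual-caller CNV consensus filtering: cohort recurrence, population SV
# overlap, single-caller quality, and dual-caller prioritization. Caller A is
# XHMM-like, caller B ExomeDepth-like; their calling models are inputs, not
# re-implemented here.

#' CNV triage thresholds
#'
#' @param ro_recurrence Reciprocal overlap at or above which two cohort calls
#'   match in the recurrence filter (0.8).
#' @param max_recurrent_others A call matching more than this many other
#'   cohort calls is discarded (3, i.e. discard at >= 4 others).
#' @param ro_popsv Reciprocal overlap with a population SV record (0.9).
#' @param popsv_max_ac,popsv_max_af A matching population record with allele
#'   count > 10 or allele frequency > 1e-4 discards the call.
#' @param ro_support Reciprocal overlap for dual-caller support (0.8).
#' @param min_phred_a,min_phred_b Minimum Phred quality for single-caller
#'   calls (20 for caller A / XHMM, 3 for caller B / ExomeDepth).
#' @param cand_phred_a,cand_phred_b Phred thresholds a dual-supported pair
#'   must reach to be a candidate (A >= 30 and B >= 20).
#' @return Named list of class `cnv_thresholds`.
#' @export
cnv_thresholds <- function(ro_recurrence = 0.8, max_recurrent_others = 3L,
                           ro_popsv = 0.9, popsv_max_ac = 10L,
                           popsv_max_af = 1e-4, ro_support = 0.8,
                           min_phred_a = 20, min_phred_b = 3,
                           cand_phred_a = 30, cand_phred_b = 20) {
  structure(list(ro_recurrence = ro_recurrence,
                 max_recurrent_others = as.integer(max_recurrent_others),
                 ro_popsv = ro_popsv, popsv_max_ac = as.integer(popsv_max_ac),
                 popsv_max_af = popsv_max_af, ro_support = ro_support,
                 min_phred_a = min_phred_a, min_phred_b = min_phred_b,
                 cand_phred_a = cand_phred_a, cand_phred_b = cand_phred_b),
            class = "cnv_thresholds")
}

#' Reciprocal overlap between two intervals
#'
#' `min(overlap/len(a), overlap/len(b))`; 0 for disjoint intervals or
#' intervals on different chromosomes. Intervals are half-open 0-based.
#' Vectorized over all arguments.
#'
#' @param a_start,a_end,b_start,b_end Numeric interval bounds.
#' @param a_chrom,b_chrom Optional chromosome vectors; mismatching pairs get
#'   overlap 0.
#' @return Numeric vector of reciprocal-overlap fractions in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end,
                               a_chrom = NULL, b_chrom = NULL) {
  la <- a_end - a_start
  lb <- b_end - b_start
  if (any(la <= 0) || any(lb <= 0))
    stop("zero- or negative-length interval in reciprocal_overlap")
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  ro <- pmin(ov / la, ov / lb)
  if (!is.null(a_chrom)) ro[a_chrom != b_chrom] <- 0
  ro
}

.validate_cnv_calls <- function(calls, caller) {
  dt <- as.data.table(calls)
  need <- c("sample_id", "chrom", "start", "end", "type", "phred")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("CNV call table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"caller" %in% names(dt)) dt[, caller := caller]
  bad <- is.na(dt$start) | is.na(dt$end) | dt$end <= dt$start |
    !(dt$type %in% c("DEL", "DUP")) | is.na(dt$phred) | dt$phred < 0
  if (any(bad)) {
    warning(sprintf("rejected %d malformed CNV call row(s)", sum(bad)))
    dt <- dt[!bad]
  }
  dt
}

# all pairs of rows of a/b (same type, same chrom, overlapping) with their
# reciprocal overlap; returns data.table(qi, si, ro)
.ro_pairs <- function(a, b, min_ro) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.table(qi = integer(), si = integer(), ro = numeric()))
  qgr <- GenomicRanges::GRanges(a$chrom,
                                IRanges::IRanges(a$start + 1L, a$end))
  sgr <- GenomicRanges::GRanges(b$chrom,
                                IRanges::IRanges(b$start + 1L, b$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(qgr, sgr, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  keep <- a$type[qi] == b$type[si]
  qi <- qi[keep]; si <- si[keep]
  ro <- reciprocal_overlap(a$start[qi], a$end[qi], b$start[si], b$end[si])
  keep <- ro >= min_ro
  data.table(qi = qi[keep], si = si[keep], ro = ro[keep])
}

#' Cohort recurrence filter for CNV calls
#'
#' A call reciprocally sharing at least 80% of its length with more than
#' three other cohort calls (other samples, same type, either caller) is
#' discarded as a putative systematic artifact.
#'
#' @param calls Combined cohort CNV call table (both callers).
#' @param thresholds A [cnv_thresholds()] object.
#' @return Logical pass vector, one per row of `calls`.
#' @export
cohort_recurrence_filter <- function(calls, thresholds = cnv_thresholds()) {
  dt <- as.data.table(calls)
  if (nrow(dt) == 0L) return(logical(0))
  pairs <- .ro_pairs(dt, dt, thresholds$ro_recurrence)
  pairs <- pairs[qi != si & dt$sample_id[qi] != dt$sample_id[si]]
  n_others <- integer(nrow(dt))
  if (nrow(pairs)) {
    cnt <- pairs[, .N, by = qi]
    n_others[cnt$qi] <- cnt$N
  }
  n_others <= thresholds$max_recurrent_others
}

#' Population SV filter
#'
#' Discards calls reciprocally sharing at least 90% of their size with a
#' same-type population SV record (DGV / gnomAD-SV) having allele count > 10
#' or allele frequency > 1e-4. Records missing a value fail that
#' sub-condition (a record with absent AF and AC <= 10 does not discard).
#'
#' @param calls CNV call table.
#' @param popsv Population SV table with columns `chrom`, `start`, `end`,
#'   `type`, `ac`, `af` (`source` optional).
#' @param thresholds A [cnv_thresholds()] object.
#' @return Logical pass vector.
#' @export
population_sv_filter <- function(calls, popsv,
                                 thresholds = cnv_thresholds()) {
  dt <- as.data.table(calls)
  if (nrow(dt) == 0L) return(logical(0))
  sv <- as.data.table(popsv)
  pass <- rep(TRUE, nrow(dt))
  if (nrow(sv) == 0L) return(pass)
  common <- (!is.na(sv$ac) & sv$ac > thresholds$popsv_max_ac) |
    (!is.na(sv$af) & sv$af > thresholds$popsv_max_af)
  sv <- sv[common]
  if (nrow(sv) == 0L) return(pass)
  pairs <- .ro_pairs(dt, sv, thresholds$ro_popsv)
  pass[unique(pairs$qi)] <- FALSE
  pass
}

# dual-caller support pairs: for each call, best-matching call from the other
# caller in the same sample (same type, RO >= ro_support)
.support_pairs <- function(dt, thresholds) {
  pairs <- .ro_pairs(dt, dt, thresholds$ro_support)
  pairs <- pairs[dt$sample_id[qi] == dt$sample_id[si] &
                   dt$caller[qi] != dt$caller[si]]
  if (nrow(pairs) == 0L) return(pairs)
  # keep, per call, the partner with the best RO then best phred
  pairs[, partner_phred := dt$phred[si]]
  setorder(pairs, qi, -ro, -partner_phred)
  pairs[!duplicated(qi)]
}

#' Single-caller quality (concordance) filter
#'
#' Calls supported by the other caller (same sample, same type, reciprocal
#' overlap >= 0.8) always pass. Single-caller calls are discarded when their
#' Phred quality is below 20 (caller A / XHMM) or 3 (caller B / ExomeDepth).
#'
#' @param calls Combined cohort CNV call table with a `caller` column
#'   (`"A"`/`"B"`).
#' @param thresholds A [cnv_thresholds()] object.
#' @return Logical pass vector.
#' @export
caller_concordance_filter <- function(calls,
                                      thresholds = cnv_thresholds()) {
  dt <- as.data.table(calls)
  if (nrow(dt) == 0L) return(logical(0))
  supported <- rep(FALSE, nrow(dt))
  sup <- .support_pairs(dt, thresholds)
  supported[unique(sup$qi)] <- TRUE
  lowq <- (dt$caller == "A" & dt$phred < thresholds$min_phred_a) |
    (dt$caller == "B" & dt$phred < thresholds$min_phred_b)
  supported | !lowq
}

#' Prioritize CNV calls
#'
#' A call is a candidate iff it is dual-supported and the matched pair
#' reaches Phred >= 30 on caller A and Phred >= 20 on caller B. Single-caller
#' calls are never candidates.
#'
#' @param calls Combined cohort CNV call table.
#' @param thresholds A [cnv_thresholds()] object.
#' @return Logical candidate vector.
#' @export
prioritize_cnv <- function(calls, thresholds = cnv_thresholds()) {
  dt <- as.data.table(calls)
  if (nrow(dt) == 0L) return(logical(0))
  cand <- rep(FALSE, nrow(dt))
  sup <- .support_pairs(dt, thresholds)
  if (nrow(sup)) {
    pa <- ifelse(dt$caller[sup$qi] == "A", dt$phred[sup$qi],
                 dt$phred[sup$si])
    pb <- ifelse(dt$caller[sup$qi] == "B", dt$phred[sup$qi],
                 dt$phred[sup$si])
    cand[sup$qi] <- pa >= thresholds$cand_phred_a &
      pb >= thresholds$cand_phred_b
  }
  cand
}

#' Run the full CNV triage on a cohort
#'
#' Applies cohort recurrence, population SV, and single-caller quality
#' filters, then prioritizes dual-supported high-quality calls. All filter
#' predicates are evaluated against the full input call set; statuses are
#' assigned in stage order (first failing stage wins). Dual-caller candidate
#' pairs are merged into one event per sample (union interval).
#'
#' @param calls_a,calls_b Call tables for caller A (XHMM-like) and caller B
#'   (ExomeDepth-like): `sample_id`, `chrom`, `start`, `end` (half-open
#'   0-based), `type` (`"DEL"`/`"DUP"`), `phred`. Either may be empty.
#' @param popsv Population SV table (see [population_sv_filter()]); may be
#'   empty.
#' @param thresholds A [cnv_thresholds()] object.
#' @return List of class `cnv_result`: `decisions` (per call: status in
#'   `discarded_recurrent`, `discarded_popsv`, `discarded_single_lowq`,
#'   `retained`, `candidate`), `events` (merged per-sample candidate events).
#' @export
run_cnv_triage <- function(calls_a, calls_b, popsv = NULL,
                           thresholds = cnv_thresholds()) {
  a <- .validate_cnv_calls(calls_a, "A")
  b <- .validate_cnv_calls(calls_b, "B")
  dt <- rbindlist(list(a, b), use.names = TRUE, fill = TRUE)
  if (is.null(popsv))
    popsv <- data.table(chrom = character(), start = integer(),
                        end = integer(), type = character(),
                        ac = integer(), af = numeric())
  if (nrow(dt) == 0L) {
    dt[, `:=`(status = character())]
    return(structure(list(decisions = dt[], events = dt[0]),
                     class = "cnv_result"))
  }
  rec <- cohort_recurrence_filter(dt, thresholds)
  pop <- population_sv_filter(dt, popsv, thresholds)
  con <- caller_concordance_filter(dt, thresholds)
  cand <- prioritize_cnv(dt, thresholds)

  status <- ifelse(cand, "candidate", "retained")
  status[!con] <- "discarded_single_lowq"
  status[!pop] <- "discarded_popsv"
  status[!rec] <- "discarded_recurrent"
  dt[, status := status]

  # merge dual-caller candidate pairs into one event per sample
  ci <- which(dt$status == "candidate")
  events <- dt[0, .(sample_id, chrom, start, end, type)]
  if (length(ci)) {
    sup <- .support_pairs(dt, thresholds)
    sup <- sup[qi %in% ci]
    ev <- data.table(sample_id = dt$sample_id[sup$qi],
                     chrom = dt$chrom[sup$qi],
                     start = pmin(dt$start[sup$qi], dt$start[sup$si]),
                     end = pmax(dt$end[sup$qi], dt$end[sup$si]),
                     type = dt$type[sup$qi])
    events <- unique(ev)
  }
  structure(list(decisions = dt[], events = events[]), class = "cnv_result")
}

#' @export
print.cnv_result <- function(x, ...) {
  tab <- table(x$decisions$status)
  cat("CNV triage:", nrow(x$decisions), "calls;",
      paste(names(tab), as.integer(tab), collapse = ", "),
      "\n  merged candidate events:", nrow(x$events), "\n")
  invisible(x)
}
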