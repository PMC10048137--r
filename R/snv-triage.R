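# SNV/indel triage cascade: quality -> frequency -> consequence ->
# prioritization, with a mosaic-aware re-analysis mode, cohort-recurrence
# artifact flagging and a recessive extension.

#' Quality filter on depth and variant allele fraction
#'
#' Primary mode discards `depth < min_depth` or `vaf < min_vaf_primary`.
#' Re-analysis mode discards `depth < min_depth`; in the band
#' `min_depth <= depth < lowdp_max` it discards VAF below
#' `min_vaf_lof_lowdp` (LoF) / `min_vaf_nonlof_lowdp` (non-LoF); at
#' `depth >= lowdp_max` it keeps VAF down to `mosaic_min_vaf` so mosaic
#' variants survive. Depth 0 always fails with reason `no_coverage`.
#'
#' @param depth,vaf Numeric vectors (VAF may be NA at depth 0).
#' @param lof Logical vector: is the variant loss-of-function?
#' @param thresholds A [triage_thresholds()] object.
#' @param mode `"primary"` or `"reanalysis"`.
#' @return List with logical `pass` and character `reason` (`NA` on pass).
#' @export
quality_filter <- function(depth, vaf, lof, thresholds = triage_thresholds(),
                           mode = c("primary", "reanalysis")) {
  mode <- match.arg(mode)
  th <- thresholds
  n <- length(depth)
  reason <- rep(NA_character_, n)
  reason[depth == 0] <- "no_coverage"
  low <- depth > 0 & depth < th$min_depth
  reason[low] <- "low_depth"
  if (mode == "primary") {
    lv <- depth >= th$min_depth & vaf < th$min_vaf_primary
    reason[lv & is.na(reason)] <- "low_vaf"
  } else {
    band <- depth >= th$min_depth & depth < th$lowdp_max
    cut_band <- ifelse(lof, th$min_vaf_lof_lowdp, th$min_vaf_nonlof_lowdp)
    lv1 <- band & vaf < cut_band
    lv2 <- depth >= th$lowdp_max & vaf < th$mosaic_min_vaf
    reason[lv1 & is.na(reason)] <- "low_vaf_lowdp"
    reason[lv2 & is.na(reason)] <- "low_vaf_mosaic_band"
  }
  list(pass = is.na(reason), reason = reason)
}

#' Population frequency filter
#'
#' Discards variants with gnomAD allele count strictly greater than
#' `max_gnomad_ac` (default 4). Variants absent from gnomAD pass.
#'
#' @param gnomad_ac Integer vector (NA = absent from gnomAD).
#' @param thresholds A [triage_thresholds()] object.
#' @return Logical pass vector.
#' @export
frequency_filter <- function(gnomad_ac, thresholds = triage_thresholds()) {
  is.na(gnomad_ac) | gnomad_ac <= thresholds$max_gnomad_ac
}

#' Is a variant absent from gnomAD?
#'
#' Absence means no matching gnomAD record (NA allele count) or an allele
#' count of zero.
#'
#' @param gnomad_ac Integer vector.
#' @return Logical vector.
#' @export
gnomad_absent <- function(gnomad_ac) {
  is.na(gnomad_ac) | gnomad_ac == 0L
}

#' Splice-effect ensemble
#'
#' A variant is predicted to affect splicing if any of the four splice
#' predictors (SQUIRLS, SpliceAI, dbscSNV ADA, dbscSNV RF) reports a score at
#' or above the cutoff. Missing scores carry no evidence; all-missing is
#' `FALSE`.
#'
#' @param squirls,spliceai,splice_ada,splice_rf Numeric score vectors in
#'   `[0, 1]`, NA where unavailable.
#' @param cutoff Score threshold (default 0.5).
#' @return Logical vector.
#' @export
splice_ensemble <- function(squirls, spliceai, splice_ada, splice_rf,
                            cutoff = 0.5) {
  m <- pmax(ifelse(is.na(squirls), -Inf, squirls),
            ifelse(is.na(spliceai), -Inf, spliceai),
            ifelse(is.na(splice_ada), -Inf, splice_ada),
            ifelse(is.na(splice_rf), -Inf, splice_rf))
  m >= cutoff
}

#' Consequence filter
#'
#' Keeps protein-affecting classes (LoF, stop loss, in-frame indel, missense)
#' and any variant the splice ensemble marks as splice-affecting — this is
#' how synonymous and intronic variants can survive.
#'
#' @param consequence Character vector of consequence classes.
#' @param splice_hit Logical vector from [splice_ensemble()].
#' @return Logical pass vector.
#' @export
consequence_filter <- function(consequence, splice_hit) {
  keep <- c(LOF_CONSEQUENCES, "stop_loss", "inframe_indel", "missense")
  consequence %in% keep | splice_hit
}

#' Missense predictor majority vote
#'
#' Deleterious iff at least `majority_fraction` of the available (non-missing)
#' predictor calls are deleterious. Zero available predictors is not evidence,
#' so the vote is `FALSE`.
#'
#' @param n_pred_del,n_pred_avail Integer vectors: deleterious and available
#'   call counts.
#' @param thresholds A [triage_thresholds()] object.
#' @return Logical vector.
#' @export
missense_majority_vote <- function(n_pred_del, n_pred_avail,
                                   thresholds = triage_thresholds()) {
  n_pred_avail > 0L &
    n_pred_del / pmax(n_pred_avail, 1L) >= thresholds$majority_fraction
}

#' Strong protein-effect predicate
#'
#' TRUE for LoF variants; in-frame indels with PROVEAN at or below the cutoff
#' (missing PROVEAN counts as not-strong, with a warning); missense variants
#' passing the predictor majority vote; and any splice-ensemble hit.
#'
#' @param consequence Character vector.
#' @param provean Numeric PROVEAN scores (NA allowed).
#' @param n_pred_del,n_pred_avail Predictor call counts.
#' @param splice_hit Logical vector from [splice_ensemble()].
#' @param thresholds A [triage_thresholds()] object.
#' @return Logical vector.
#' @export
strong_effect <- function(consequence, provean, n_pred_del, n_pred_avail,
                          splice_hit, thresholds = triage_thresholds()) {
  th <- thresholds
  inframe <- consequence == "inframe_indel"
  if (any(inframe & is.na(provean)))
    warning("in-frame indel(s) with missing PROVEAN score treated as not ",
            "strongly protein-affecting")
  is_lof(consequence) |
    (inframe & !is.na(provean) & provean <= th$provean_cutoff) |
    (consequence == "missense" &
       missense_majority_vote(n_pred_del, n_pred_avail, th)) |
    splice_hit
}

#' Prioritize filtered variants
#'
#' Among variants that passed quality, frequency and consequence filters, a
#' candidate is one that (i) is reported pathogenic/likely pathogenic in
#' ClinVar, (ii) is absent from gnomAD, or (iii) is predicted to strongly
#' affect protein function. With `priority_mode = "any"` (default) the three
#' criteria are alternative routes; with `"conjunction"` all three must hold.
#'
#' @param clinvar Character vector of ClinVar levels.
#' @param gnomad_ac Integer vector.
#' @param strong Logical vector from [strong_effect()].
#' @param thresholds A [triage_thresholds()] object.
#' @return List with logical `candidate` and character `routes`
#'   (semicolon-joined satisfied criteria, empty when none).
#' @export
prioritize <- function(clinvar, gnomad_ac, strong,
                       thresholds = triage_thresholds()) {
  plp <- clinvar %in% c("pathogenic", "likely_pathogenic")
  absent <- gnomad_absent(gnomad_ac)
  cand <- if (thresholds$priority_mode == "any")
    plp | absent | strong else plp & absent & strong
  routes <- character(length(cand))
  add <- function(routes, hit, id)
    ifelse(hit, ifelse(nzchar(routes), paste(routes, id, sep = ";"), id),
           routes)
  routes <- add(routes, plp, "clinvar_plp")
  routes <- add(routes, absent, "gnomad_absent")
  routes <- add(routes, strong, "strong_effect")
  list(candidate = cand, routes = routes)
}

#' Flag cohort-recurrent putative artifacts
#'
#' gnomAD-absent variants carried by at least `artifact_min_carriers`
#' distinct samples (the published "> 3 patients" rule) are flagged as likely
#' sequencing artifacts. The flag is advisory: statuses are unchanged, and it
#' is set only on carriers whose variant survived the cascade
#' (retained/candidate), while carrier counting uses all cohort carriers.
#'
#' @param decisions A decision table from [run_triage()] (or any data.table
#'   with `chrom`, `pos`, `ref`, `alt`, `sample_id`, `gnomad_ac`, `status`).
#' @param thresholds A [triage_thresholds()] object.
#' @return The decision table with an updated logical `artifact_flag`.
#' @export
flag_recurrent_artifacts <- function(decisions,
                                     thresholds = triage_thresholds()) {
  dt <- as.data.table(decisions)
  dt[, artifact_flag := FALSE]
  absent <- gnomad_absent(dt$gnomad_ac)
  key <- paste(dt$chrom, dt$pos, dt$ref, dt$alt, sep = ":")
  carriers <- dt[absent, .(n_carriers = uniqueN(sample_id)),
                 by = .(k = key[absent])]
  hot <- carriers[n_carriers >= thresholds$artifact_min_carriers, k]
  dt[key %in% hot & absent & status %in% c("retained", "candidate"),
     artifact_flag := TRUE]
  dt[]
}

#' Recessive compound-heterozygous / homozygous filter
#'
#' For genes with recessive inheritance: variants with gnomAD allele
#' frequency at or above `recessive_max_af` (0.1%) or more than
#' `recessive_max_hom` (4) gnomAD homozygotes are discarded. Surviving
#' homozygous variants are reported directly; genes carrying two or more
#' surviving heterozygous variants in the same sample are reported as
#' unphased compound-heterozygous candidates.
#'
#' @param variants A variant table with a `zygosity` column (`"hom"`/`"het"`).
#' @param thresholds A [triage_thresholds()] object.
#' @return List of data.tables `homozygous` and `compound_het` (the latter
#'   with a `phase = "unphased"` label).
#' @export
recessive_filter <- function(variants, thresholds = triage_thresholds()) {
  th <- thresholds
  dt <- as.data.table(variants)
  if (!"zygosity" %in% names(dt) || anyNA(dt$zygosity))
    stop("recessive_filter requires a complete 'zygosity' column")
  af <- ifelse(is.na(dt$gnomad_af), 0, dt$gnomad_af)
  hom_n <- ifelse(is.na(dt$gnomad_hom), 0L, dt$gnomad_hom)
  keep <- dt[af < th$recessive_max_af & hom_n <= th$recessive_max_hom]
  homozygous <- keep[zygosity == "hom"]
  hets <- keep[zygosity == "het"]
  ch_genes <- hets[, .N, by = .(sample_id, gene)][N >= 2L]
  compound_het <- hets[ch_genes, on = c("sample_id", "gene")]
  if (nrow(compound_het)) compound_het[, phase := "unphased"]
  list(homozygous = homozygous[], compound_het = compound_het[])
}

#' Run the full SNV triage cascade on a cohort
#'
#' Applies, in order: virtual-panel restriction, quality filter, gnomAD
#' frequency filter, consequence filter, prioritization, and (re-analysis
#' mode only) cohort-recurrence artifact flagging. Each variant receives
#' exactly one terminal status: `off_panel`, `discarded_quality`,
#' `discarded_frequency`, `discarded_consequence`, `retained` or `candidate`.
#'
#' @param variants A cohort variant table (validated with
#'   [validate_variants()] if not already).
#' @param panel A [panel_definition()], or `NULL` to skip the panel
#'   restriction (e.g. calls already restricted upstream).
#' @param thresholds A [triage_thresholds()] object.
#' @param mode `"primary"` or `"reanalysis"`.
#' @return List of class `triage_result`: `decisions` (one row per variant
#'   with `status`, `reasons`, `artifact_flag`), `per_sample` (kept and
#'   candidate counts), and `summary` (cohort totals, eliminated fraction,
#'   mode).
#' @export
run_triage <- function(variants, panel = NULL,
                       thresholds = triage_thresholds(),
                       mode = c("primary", "reanalysis")) {
  mode <- match.arg(mode)
  th <- thresholds
  if (!inherits(variants, "variant_table"))
    variants <- validate_variants(variants)
  dt <- copy(as.data.table(variants))

  if (!is.null(panel)) {
    known <- dt$gene %in% panel$genes
    inside <- in_panel(dt$chrom, dt$pos, panel)
    if (any(inside & !known))
      warning(sprintf(paste0("%d variant(s) inside panel regions carry gene ",
                             "symbols not in the panel gene list; kept"),
                      sum(inside & !known)))
  } else {
    inside <- rep(TRUE, nrow(dt))
  }
  lof <- is_lof(dt$consequence)
  qf <- quality_filter(dt$depth, dt$vaf, lof, th, mode)
  ff <- frequency_filter(dt$gnomad_ac, th)
  sp <- splice_ensemble(dt$squirls, dt$spliceai, dt$splice_ada, dt$splice_rf,
                        th$splice_cutoff)
  cf <- consequence_filter(dt$consequence, sp)
  st <- suppressWarnings(
    strong_effect(dt$consequence, dt$provean, dt$n_pred_del, dt$n_pred_avail,
                  sp, th))
  pr <- prioritize(dt$clinvar, dt$gnomad_ac, st, th)

  status <- rep("candidate", nrow(dt))
  reasons <- pr$routes
  reasons[!pr$candidate] <- "no_priority_route"
  status[!pr$candidate] <- "retained"
  status[!cf] <- "discarded_consequence"
  reasons[!cf] <- "consequence_not_considered"
  status[!ff] <- "discarded_frequency"
  reasons[!ff] <- "gnomad_ac_gt_max"
  status[!qf$pass] <- "discarded_quality"
  reasons[!qf$pass] <- qf$reason[!qf$pass]
  status[!inside] <- "off_panel"
  reasons[!inside] <- "off_panel"

  dt[, `:=`(status = status, reasons = reasons, artifact_flag = FALSE)]
  if (mode == "reanalysis")
    dt <- flag_recurrent_artifacts(dt, th)

  per_sample <- dt[, .(
    n_variants = .N,
    kept = sum(status %in% c("retained", "candidate")),
    candidates = sum(status == "candidate"),
    artifacts_flagged = sum(artifact_flag)), by = sample_id]
  summary <- list(
    mode = mode,
    n_variants = nrow(dt),
    n_samples = uniqueN(dt$sample_id),
    kept_total = sum(per_sample$kept),
    candidate_total = sum(per_sample$candidates),
    mean_kept_per_sample = mean(per_sample$kept),
    mean_candidates_per_sample = mean(per_sample$candidates),
    eliminated_fraction =
      if (nrow(dt)) 1 - sum(per_sample$kept) / nrow(dt) else 0)
  structure(list(decisions = dt[], per_sample = per_sample[],
                 summary = summary),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("SNV triage (%s mode): %d variants in %d samples\n",
           "  kept %d (%.2f/sample), candidates %d (%.2f/sample)\n",
           "  eliminated %.2f%% of detected variants\n"),
    s$mode, s$n_variants, s$n_samples, s$kept_total, s$mean_kept_per_sample,
    s$candidate_total, s$mean_candidates_per_sample,
    100 * s$eliminated_fraction))
  invisible(x)
}
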