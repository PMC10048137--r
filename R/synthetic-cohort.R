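# Synthetic cohort generator. Emulates the input structure the triage
# pipeline assumes -- per-sample small-variant calls with genotype,
# population and functional annotations; dual-caller CNV tables; a
# population SV resource; patient HPO tables -- with planted pathogenic
# variants and truth labels computed by an independent straight-line
# restatement of the filter rules (never by calling the pipeline).
#
# Defaults are the published cohort conditions: 398 patients (247 M / 151 F),
# 76/398 in the ASD subset, pathogenic plant probability 114/398 split
# 106 germline / 3 mosaic / 5 CNV, and a background load of ~2200 detected
# variants per sample (implied by ~6 kept per sample at 99.73% elimination).
# Background attribute distributions are finite categorical mixtures so that
# expected_counts() has an exact closed form.

#' Simulation configuration
#'
#' @param n_patients Number of patients.
#' @param male_frac Fraction of males.
#' @param asd_frac Fraction of patients in the ASD subset.
#' @param background_mean Poisson mean of per-sample background variants.
#' @param planted_prob Probability a patient carries a planted pathogenic
#'   variant (any type).
#' @param plant_type_probs Probabilities of germline SNV / mosaic SNV / CNV
#'   given a plant.
#' @param off_panel_prob Probability a background variant falls outside the
#'   panel target regions.
#' @param splice_hit_prob Probability a background variant carries a splice
#'   ensemble score >= 0.5.
#' @param hom_prob Probability a background variant is homozygous.
#' @param artifact_n_sites,artifact_carriers Number of planted recurrent
#'   artifact sites (gnomAD-absent, shared across samples) and carriers per
#'   site.
#' @param n_genes Panel size (genes).
#' @param depth_dist,vaf_dist,consequence_dist,clinvar_dist,provean_dist
#'   data.frames with `value`/`prob` columns (finite mixtures).
#' @param gnomad_dist data.frame with `ac`, `af`, `hom`, `prob` (NA ac =
#'   absent from gnomAD).
#' @param predictor_dist data.frame with `avail`, `frac`, `prob`: number of
#'   available predictor calls and deleterious fraction.
#' @param category_base_prob,category_boost_prob Per-category inclusion
#'   probability for undiagnosed patients and for the two causal categories
#'   in diagnosed patients.
#' @param cnv_background_mean Poisson mean of background CNV events per
#'   patient.
#' @param n_popsv Population SV records (half common, half rare).
#' @param seed RNG seed; all draws are reproducible from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 398L,
                       male_frac = 247 / 398,
                       asd_frac = 76 / 398,
                       background_mean = 2200,
                       planted_prob = 114 / 398,
                       plant_type_probs = c(germline = 106, mosaic = 3,
                                            cnv = 5) / 114,
                       off_panel_prob = 0.05,
                       splice_hit_prob = 0.03,
                       hom_prob = 0.02,
                       artifact_n_sites = 2L,
                       artifact_carriers = 6L,
                       n_genes = 460L,
                       depth_dist = data.frame(
                         value = c(0, 5, 9, 30, 60, 100, 244),
                         prob = c(.005, .015, .02, .10, .16, .30, .40)),
                       vaf_dist = data.frame(
                         value = c(0.05, 0.15, 0.22, 0.28, 0.35, 0.5, 1.0),
                         prob = c(.30, .10, .05, .05, .05, .35, .10)),
                       consequence_dist = data.frame(
                         value = c("missense", "synonymous", "intronic",
                                   "other", "stop_gain", "frameshift",
                                   "canonical_splice", "start_loss",
                                   "stop_loss", "inframe_indel"),
                         prob = c(.30, .25, .35, .04, .012, .012, .01,
                                  .006, .002, .018)),
                       gnomad_dist = data.frame(
                         ac = c(NA, 0, 1, 3, 4, 5, 12, 50, 5000),
                         af = c(NA, 0, 4e-6, 1.2e-5, 1.6e-5, 2e-5,
                                4.8e-5, 2e-4, 2e-2),
                         hom = c(NA, 0, 0, 0, 0, 0, 5, 1, 60),
                         prob = c(.004, .001, .010, .010, .005, .020,
                                  .030, .120, .800)),
                       clinvar_dist = data.frame(
                         value = c("absent", "other", "pathogenic",
                                   "likely_pathogenic"),
                         prob = c(.97, .02, .007, .003)),
                       predictor_dist = data.frame(
                         avail = c(0, 10, 20, 30, 35),
                         frac = c(0, 0.2, 0.4, 0.6, 0.9),
                         prob = c(.05, .25, .25, .25, .20)),
                       provean_dist = data.frame(
                         value = c(-4, -2.5, -2.4, -1, NA),
                         prob = c(.2, .1, .1, .3, .3)),
                       category_base_prob = 0.20,
                       category_boost_prob = 0.45,
                       cnv_background_mean = 2,
                       n_popsv = 40L,
                       seed = 1L) {
  cfg <- as.list(environment())
  for (d in list(cfg$depth_dist$prob, cfg$vaf_dist$prob,
                 cfg$consequence_dist$prob, cfg$gnomad_dist$prob,
                 cfg$clinvar_dist$prob, cfg$predictor_dist$prob,
                 cfg$provean_dist$prob))
    if (abs(sum(d) - 1) > 1e-8) stop("distribution probs must sum to 1")
  pr <- c(cfg$planted_prob, cfg$off_panel_prob, cfg$splice_hit_prob,
          cfg$hom_prob, cfg$male_frac, cfg$asd_frac)
  if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1")
  if (cfg$planted_prob > 0 && cfg$background_mean == 0 &&
      sum(cfg$plant_type_probs[c("germline", "mosaic")]) == 0)
    stop("infeasible config: plants requested but no variants generated")
  structure(cfg, class = "sim_config")
}

.draw <- function(n, values, probs) {
  values[sample.int(length(values), n, replace = TRUE, prob = probs)]
}

# synthetic panel: genes laid out on 200 kb blocks, 23 chromosomes, exons
# padded by 20 bp flanks; block spacing guarantees off-panel offsets of
# 21..1500 bp past a region never hit another region
.synth_panel_regions <- function(n_genes) {
  chroms <- paste0("chr", c(1:22, "X"))
  out <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    chrom <- chroms[1L + (g - 1L) %% length(chroms)]
    block <- (g - 1L) %/% length(chroms)
    base <- 1e6 + block * 2e5
    n_ex <- sample(5:12, 1)
    widths <- sample(120:280, n_ex, replace = TRUE)
    gaps <- sample(2000:8000, n_ex, replace = TRUE)
    starts <- base + cumsum(gaps) + cumsum(c(0, head(widths, -1)))
    out[[g]] <- data.table(chrom = chrom,
                           start = as.integer(starts - 20L),
                           end = as.integer(starts + widths + 20L),
                           gene = sprintf("GENE%04d", g))
  }
  rbindlist(out)
}

.rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Generate a synthetic cohort bundle
#'
#' Deterministic given `config$seed`. Planted pathogenic variants satisfy
#' the candidate definition by construction (gnomAD-absent, strong protein
#' effect, adequate depth); mosaic plants (VAF 0.10-0.25 at depth >= 50) are
#' recoverable only in re-analysis mode; planted recurrent-artifact sites
#' are gnomAD-absent LoF variants shared across `artifact_carriers` samples.
#'
#' @param config A [sim_config()].
#' @return List of class `ndd_cohort`: `patients` (with list-column
#'   `hpo_terms` and `diagnosed`), `variants` (validated variant table),
#'   `panel` ([panel_definition()]), `panel_regions` (raw data.table),
#'   `cnv_a`, `cnv_b`, `popsv`, `truth_snv`, `truth_cnv`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  regions <- .synth_panel_regions(cfg$n_genes)
  panel <- panel_definition(regions)

  ids <- sprintf("P%04d", seq_len(cfg$n_patients))
  sex <- ifelse(runif(cfg$n_patients) < cfg$male_frac, "M", "F")
  subset_true <- ifelse(runif(cfg$n_patients) < cfg$asd_frac,
                        "ASD", "ID_GDD")
  planted <- runif(cfg$n_patients) < cfg$planted_prob
  plant_type <- rep(NA_character_, cfg$n_patients)
  plant_type[planted] <- .draw(sum(planted), names(cfg$plant_type_probs),
                               cfg$plant_type_probs)

  # ---- background small variants ----------------------------------------
  n_bg <- rpois(cfg$n_patients, cfg$background_mean)
  tot <- sum(n_bg)
  ri <- sample.int(nrow(regions), tot, replace = TRUE)
  inp <- runif(tot) >= cfg$off_panel_prob
  pos <- integer(tot)
  w <- regions$end[ri] - regions$start[ri]
  pos[inp] <- regions$start[ri[inp]] + 1L +
    as.integer(floor(runif(sum(inp)) * w[inp]))
  pos[!inp] <- regions$end[ri[!inp]] + 21L +
    as.integer(floor(runif(sum(!inp)) * 1480))
  depth <- .draw(tot, cfg$depth_dist$value, cfg$depth_dist$prob)
  vnom <- .draw(tot, cfg$vaf_dist$value, cfg$vaf_dist$prob)
  alt_reads <- ifelse(depth > 0, round(vnom * depth), 0)
  gn <- sample.int(nrow(cfg$gnomad_dist), tot, replace = TRUE,
                   prob = cfg$gnomad_dist$prob)
  conseq <- .draw(tot, cfg$consequence_dist$value, cfg$consequence_dist$prob)
  clinvar <- .draw(tot, cfg$clinvar_dist$value, cfg$clinvar_dist$prob)
  hit <- runif(tot) < cfg$splice_hit_prob
  pred <- sample.int(nrow(cfg$predictor_dist), tot, replace = TRUE,
                     prob = cfg$predictor_dist$prob)
  n_avail <- as.integer(cfg$predictor_dist$avail[pred])
  n_del <- as.integer(round(cfg$predictor_dist$frac[pred] * n_avail))
  provean <- rep(NA_real_, tot)
  infr <- conseq == "inframe_indel"
  provean[infr] <- .draw(sum(infr), cfg$provean_dist$value,
                         cfg$provean_dist$prob)
  bg <- data.table(
    sample_id = rep(ids, n_bg),
    chrom = regions$chrom[ri], pos = pos,
    ref = .rand_bases(tot), alt = .rand_bases(tot),
    gene = regions$gene[ri],
    depth = as.integer(depth), alt_reads = as.integer(alt_reads),
    gnomad_ac = as.integer(cfg$gnomad_dist$ac[gn]),
    gnomad_af = cfg$gnomad_dist$af[gn],
    gnomad_hom = as.integer(cfg$gnomad_dist$hom[gn]),
    consequence = conseq, clinvar = clinvar, provean = provean,
    squirls = ifelse(runif(tot) < 0.5, round(runif(tot) * 0.49, 3),
                     NA_real_),
    spliceai = ifelse(hit, round(0.5 + runif(tot) * 0.5, 3),
                      round(runif(tot) * 0.49, 3)),
    splice_ada = NA_real_, splice_rf = NA_real_,
    zygosity = ifelse(runif(tot) < cfg$hom_prob, "hom", "het"),
    n_pred_avail = n_avail, n_pred_del = n_del,
    planted_class = "background")
  bg[alt == ref, alt := ifelse(ref == "A", "G", "A")]

  # ---- planted pathogenic SNVs ------------------------------------------
  mk_plant <- function(who, mosaic) {
    np <- length(who)
    if (np == 0L) return(NULL)
    ri <- sample.int(nrow(regions), np, replace = TRUE)
    w <- regions$end[ri] - regions$start[ri]
    pos <- regions$start[ri] + 1L + as.integer(floor(runif(np) * w))
    if (mosaic) {
      depth <- .draw(np, c(100, 244), c(.5, .5))
      vnom <- .draw(np, c(0.12, 0.18, 0.24), rep(1 / 3, 3))
      conseq <- .draw(np, c("stop_gain", "frameshift"), c(.5, .5))
      n_avail <- rep(0L, np); n_del <- rep(0L, np)
      provean <- rep(NA_real_, np)
      spliceai <- rep(NA_real_, np)
    } else {
      depth <- .draw(np, c(100, 150, 244), c(1, 1, 1) / 3)
      vnom <- .draw(np, c(0.45, 0.5, 0.55), c(1, 1, 1) / 3)
      conseq <- .draw(np, c("stop_gain", "frameshift", "canonical_splice",
                            "start_loss", "missense", "inframe_indel",
                            "synonymous"),
                      c(.22, .22, .10, .05, .26, .08, .07))
      n_avail <- ifelse(conseq == "missense", 30L, 0L)
      n_del <- ifelse(conseq == "missense", 27L, 0L)
      provean <- ifelse(conseq == "inframe_indel", -4, NA_real_)
      spliceai <- ifelse(conseq == "synonymous",
                         round(0.85 + runif(np) * 0.14, 3), NA_real_)
    }
    data.table(
      sample_id = ids[who],
      chrom = regions$chrom[ri], pos = pos,
      ref = .rand_bases(np), alt = "X",  # distinct alt avoids key collisions
      gene = regions$gene[ri],
      depth = as.integer(depth),
      alt_reads = as.integer(round(vnom * depth)),
      gnomad_ac = NA_integer_, gnomad_af = NA_real_,
      gnomad_hom = NA_integer_,
      consequence = conseq,
      clinvar = .draw(np, c("pathogenic", "likely_pathogenic", "absent"),
                      c(.3, .1, .6)),
      provean = provean, squirls = NA_real_, spliceai = spliceai,
      splice_ada = NA_real_, splice_rf = NA_real_,
      zygosity = "het", n_pred_avail = n_avail, n_pred_del = n_del,
      planted_class = if (mosaic) "pathogenic_mosaic" else
        "pathogenic_germline")
  }
  germ <- mk_plant(which(plant_type %in% "germline"), mosaic = FALSE)
  mosa <- mk_plant(which(plant_type %in% "mosaic"), mosaic = TRUE)

  # ---- planted recurrent artifact sites ---------------------------------
  arts <- NULL
  if (cfg$artifact_n_sites > 0L &&
      cfg$artifact_carriers <= cfg$n_patients) {
    arts <- rbindlist(lapply(seq_len(cfg$artifact_n_sites), function(s) {
      ri <- sample.int(nrow(regions), 1L)
      w <- regions$end[ri] - regions$start[ri]
      pos <- regions$start[ri] + 1L + as.integer(floor(runif(1) * w))
      carriers <- sample.int(cfg$n_patients, cfg$artifact_carriers)
      data.table(
        sample_id = ids[carriers], chrom = regions$chrom[ri], pos = pos,
        ref = "A", alt = "T", gene = regions$gene[ri],
        depth = 100L, alt_reads = 35L,
        gnomad_ac = NA_integer_, gnomad_af = NA_real_,
        gnomad_hom = NA_integer_,
        consequence = "frameshift", clinvar = "absent",
        provean = NA_real_, squirls = NA_real_, spliceai = NA_real_,
        splice_ada = NA_real_, splice_rf = NA_real_,
        zygosity = "het", n_pred_avail = 0L, n_pred_del = 0L,
        planted_class = "artifact")
    }))
  }

  variants <- rbindlist(list(bg, germ, mosa, arts), use.names = TRUE)
  variants <- variants[!duplicated(
    paste(sample_id, chrom, pos, ref, alt, sep = ":"))]
  planted_class <- variants$planted_class
  variants[, planted_class := NULL]
  variants <- validate_variants(variants)
  # generator never emits invalid rows; truth labels stay row-aligned
  stopifnot(nrow(variants) == length(planted_class))

  # ---- CNVs and population SV resource ----------------------------------
  cnv <- .synth_cnvs(cfg, ids, planted = which(plant_type %in% "cnv"))

  # ---- patients / HPO ----------------------------------------------------
  diagnosed <- planted
  patients <- .synth_patients(cfg, ids, sex, subset_true, diagnosed)

  truth_snv <- .truth_snv(variants, planted_class, regions)
  truth_cnv <- .truth_cnv(cnv$calls_a, cnv$calls_b, cnv$popsv)

  structure(list(patients = patients, variants = variants, panel = panel,
                 panel_regions = regions, cnv_a = cnv$calls_a,
                 cnv_b = cnv$calls_b, popsv = cnv$popsv,
                 truth_snv = truth_snv, truth_cnv = truth_cnv,
                 config = cfg),
            class = "ndd_cohort")
}

.synth_cnvs <- function(cfg, ids, planted) {
  chroms <- paste0("chr", c(1:22, "X"))
  rand_iv <- function(n) {
    start <- as.integer(1e6 + floor(runif(n) * 2e8))
    len <- as.integer(2e4 + floor(runif(n) * 1.8e5))
    data.table(chrom = sample(chroms, n, replace = TRUE),
               start = start, end = start + len)
  }
  n_pop <- cfg$n_popsv
  popsv <- rand_iv(n_pop)
  popsv[, type := sample(c("DEL", "DUP"), n_pop, replace = TRUE)]
  common <- seq_len(n_pop) <= n_pop / 2
  popsv[, ac := ifelse(common, 50L, 2L)]
  popsv[, af := ifelse(common, 1e-2, 2e-6)]
  popsv[, source := "gnomAD_SV"]

  # one fixed recurrent-artifact interval shared by many samples
  art_iv <- rand_iv(1)
  art_carriers <- sample(ids, min(length(ids), 6L))

  n_ev <- rpois(length(ids), cfg$cnv_background_mean)
  classes <- c("common_pop", "single_lowq", "single_highq", "dual_moderate")
  cls_prob <- c(.3, .3, .2, .2)
  a_list <- list(); b_list <- list()
  for (i in seq_along(ids)) {
    k <- n_ev[i]
    if (k == 0L) next
    cls <- .draw(k, classes, cls_prob)
    for (cl in cls) {
      if (cl == "common_pop") {
        j <- sample(which(common), 1L)
        iv <- popsv[j, .(chrom, start, end, type)]
        a_list[[length(a_list) + 1L]] <- data.table(
          sample_id = ids[i], iv, phred = round(runif(1, 30, 90), 1))
      } else if (cl == "single_lowq") {
        iv <- rand_iv(1)[, type := sample(c("DEL", "DUP"), 1)]
        if (runif(1) < 0.5)
          a_list[[length(a_list) + 1L]] <- data.table(
            sample_id = ids[i], iv, phred = round(runif(1, 0, 19.9), 1))
        else
          b_list[[length(b_list) + 1L]] <- data.table(
            sample_id = ids[i], iv, phred = round(runif(1, 0, 2.9), 1))
      } else if (cl == "single_highq") {
        iv <- rand_iv(1)[, type := sample(c("DEL", "DUP"), 1)]
        if (runif(1) < 0.5)
          a_list[[length(a_list) + 1L]] <- data.table(
            sample_id = ids[i], iv, phred = round(runif(1, 25, 90), 1))
        else
          b_list[[length(b_list) + 1L]] <- data.table(
            sample_id = ids[i], iv, phred = round(runif(1, 5, 60), 1))
      } else { # dual_moderate: both callers, below candidate thresholds
        iv <- rand_iv(1)[, type := sample(c("DEL", "DUP"), 1)]
        a_list[[length(a_list) + 1L]] <- data.table(
          sample_id = ids[i], iv, phred = round(runif(1, 5, 29), 1))
        b_list[[length(b_list) + 1L]] <- data.table(
          sample_id = ids[i], iv, phred = round(runif(1, 3, 19), 1))
      }
    }
  }
  for (s in art_carriers)
    a_list[[length(a_list) + 1L]] <- data.table(
      sample_id = s, art_iv[, .(chrom, start, end)], type = "DEL",
      phred = round(runif(1, 30, 90), 1))
  for (i in planted) {
    iv <- rand_iv(1)[, type := sample(c("DEL", "DUP"), 1)]
    a_list[[length(a_list) + 1L]] <- data.table(
      sample_id = ids[i], iv, phred = round(runif(1, 40, 90), 1))
    # slight boundary jitter keeps RO just above the support threshold
    jit <- as.integer((iv$end - iv$start) * 0.05)
    b_list[[length(b_list) + 1L]] <- data.table(
      sample_id = ids[i], chrom = iv$chrom, start = iv$start + jit,
      end = iv$end, type = iv$type, phred = round(runif(1, 25, 60), 1))
  }
  empty <- data.table(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      type = character(), phred = numeric())
  calls_a <- if (length(a_list)) rbindlist(a_list) else copy(empty)
  calls_b <- if (length(b_list)) rbindlist(b_list) else copy(empty)
  calls_a[, caller := "A"]; calls_b[, caller := "B"]
  list(calls_a = calls_a[], calls_b = calls_b[], popsv = popsv[])
}

.synth_patients <- function(cfg, ids, sex, subset_true, diagnosed) {
  map <- read_category_map()
  cats <- phenotype_categories()
  causal <- c("Abnormal nervous system morphology",
              "Abnormality of the musculoskeletal system")
  by_cat <- split(map$code, map$category)
  terms <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    t <- character()
    if (subset_true[i] == "ASD") {
      t <- sample(hpo_autism_codes(), sample(1:3, 1))
    } else {
      t <- sample(hpo_id_gdd_codes(), sample(1:2, 1))
      if (runif(1) < 0.3) t <- c(t, sample(hpo_autism_codes(), 1))
    }
    for (cat in setdiff(cats, c("Behavioral abnormality",
                                "Intellectual disability"))) {
      p <- if (diagnosed[i] && cat %in% causal) cfg$category_boost_prob
      else cfg$category_base_prob
      if (runif(1) < p)
        t <- c(t, sample(by_cat[[cat]], min(2L, length(by_cat[[cat]]))))
    }
    terms[[i]] <- unique(t)
  }
  data.table(patient_id = ids, sex = sex, hpo_terms = terms,
             subset_true = subset_true, diagnosed = diagnosed)
}

# ---- independent truth ----------------------------------------------------
# Straight-line restatement of the published rules with literal constants;
# panel membership via a data.table non-equi join (the pipeline uses
# GenomicRanges). Never calls the triage functions.

.truth_snv <- function(variants, planted_class, regions) {
  v <- as.data.table(variants)
  n <- nrow(v)
  reg <- copy(regions)
  pts <- data.table(chrom = v$chrom, pos = v$pos, idx = seq_len(n))
  hits <- reg[pts, on = .(chrom, start < pos, end >= pos), nomatch = 0L,
              .(idx = i.idx)]
  inp <- logical(n); inp[hits$idx] <- TRUE

  vaf <- ifelse(v$depth > 0, v$alt_reads / v$depth, NA_real_)
  lof <- v$consequence %in% c("stop_gain", "frameshift", "canonical_splice",
                              "start_loss")
  smax <- pmax(ifelse(is.na(v$squirls), -1, v$squirls),
               ifelse(is.na(v$spliceai), -1, v$spliceai),
               ifelse(is.na(v$splice_ada), -1, v$splice_ada),
               ifelse(is.na(v$splice_rf), -1, v$splice_rf))
  splice <- smax >= 0.5
  q_primary <- v$depth >= 10 & !is.na(vaf) & vaf >= 0.30
  q_re <- v$depth >= 10 & !is.na(vaf) &
    ((v$depth < 50 & vaf >= ifelse(lof, 0.20, 0.25)) |
       (v$depth >= 50 & vaf >= 0.10))
  freq_ok <- is.na(v$gnomad_ac) | v$gnomad_ac <= 4
  cons_ok <- v$consequence %in% c("stop_gain", "frameshift",
                                  "canonical_splice", "start_loss",
                                  "stop_loss", "inframe_indel",
                                  "missense") | splice
  strong <- lof | splice |
    (v$consequence == "inframe_indel" & !is.na(v$provean) &
       v$provean <= -2.5) |
    (v$consequence == "missense" & v$n_pred_avail > 0 &
       v$n_pred_del / pmax(v$n_pred_avail, 1) >= 0.5)
  absent <- is.na(v$gnomad_ac) | v$gnomad_ac == 0
  plp <- v$clinvar %in% c("pathogenic", "likely_pathogenic")
  cand <- plp | absent | strong

  status_for <- function(q_ok) {
    ifelse(!inp, "off_panel",
           ifelse(!q_ok, "discarded_quality",
                  ifelse(!freq_ok, "discarded_frequency",
                         ifelse(!cons_ok, "discarded_consequence",
                                ifelse(cand, "candidate", "retained")))))
  }
  st_p <- status_for(q_primary)
  st_r <- status_for(q_re)

  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  carriers <- tapply(v$sample_id[absent], key[absent],
                     function(s) length(unique(s)))
  hot <- names(carriers)[carriers >= 4]
  art <- key %in% hot & absent & st_r %in% c("retained", "candidate")

  data.table(variant_id = paste(v$sample_id, key, sep = ":"),
             sample_id = v$sample_id, planted_class = planted_class,
             status_primary = st_p, status_reanalysis = st_r,
             artifact_flag_reanalysis = art)
}

.truth_cnv <- function(calls_a, calls_b, popsv) {
  dt <- rbindlist(list(calls_a, calls_b), use.names = TRUE)
  n <- nrow(dt)
  if (n == 0L) return(data.table())
  ro <- function(s1, e1, s2, e2) {
    ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
    pmin(ov / (e1 - s1), ov / (e2 - s2))
  }
  n_rec <- integer(n); supported <- logical(n); pop_hit <- logical(n)
  pair_a <- numeric(n); pair_b <- numeric(n)
  sv <- as.data.table(popsv)
  sv_common <- sv[(!is.na(ac) & ac > 10) | (!is.na(af) & af > 1e-4)]
  for (i in seq_len(n)) {
    same_chr <- dt$chrom == dt$chrom[i] & dt$type == dt$type[i]
    r <- ro(dt$start[i], dt$end[i], dt$start, dt$end)
    m <- same_chr & r >= 0.8
    n_rec[i] <- sum(m & dt$sample_id != dt$sample_id[i] &
                      seq_len(n) != i)
    sup <- which(m & dt$sample_id == dt$sample_id[i] &
                   dt$caller != dt$caller[i])
    if (length(sup)) {
      supported[i] <- TRUE
      best <- sup[order(-r[sup], -dt$phred[sup])][1]
      pa <- if (dt$caller[i] == "A") dt$phred[i] else dt$phred[best]
      pb <- if (dt$caller[i] == "B") dt$phred[i] else dt$phred[best]
      pair_a[i] <- pa; pair_b[i] <- pb
    }
    if (nrow(sv_common)) {
      rs <- ro(dt$start[i], dt$end[i], sv_common$start, sv_common$end)
      pop_hit[i] <- any(sv_common$chrom == dt$chrom[i] &
                          sv_common$type == dt$type[i] & rs >= 0.9)
    }
  }
  lowq <- (dt$caller == "A" & dt$phred < 20) |
    (dt$caller == "B" & dt$phred < 3)
  status <- ifelse(n_rec > 3, "discarded_recurrent",
            ifelse(pop_hit, "discarded_popsv",
            ifelse(!supported & lowq, "discarded_single_lowq",
            ifelse(supported & pair_a >= 30 & pair_b >= 20,
                   "candidate", "retained"))))
  data.table(sample_id = dt$sample_id, chrom = dt$chrom, start = dt$start,
             end = dt$end, type = dt$type, caller = dt$caller,
             phred = dt$phred, status = status)
}

#' Analytic expectations for the generator's filter funnel
#'
#' Integrates the filter rules (at default thresholds) against the finite
#' generator distributions to give exact expected per-sample counts:
#' total detected variants, kept (retained + candidate), candidates, and the
#' eliminated fraction, for both triage modes.
#'
#' @param config A [sim_config()].
#' @return List with one element per mode (`primary`, `reanalysis`), each a
#'   list of `mean_total`, `mean_kept`, `mean_candidates`,
#'   `eliminated_fraction`.
#' @export
expected_counts <- function(config) {
  cfg <- config
  dd <- cfg$depth_dist; vd <- cfg$vaf_dist
  grid <- CJ(di = seq_len(nrow(dd)), vi = seq_len(nrow(vd)))
  d <- dd$value[grid$di]; vn <- vd$value[grid$vi]
  pw <- dd$prob[grid$di] * vd$prob[grid$vi]
  alt <- ifelse(d > 0, round(vn * d), 0)
  vaf <- ifelse(d > 0, alt / d, NA_real_)
  q_primary <- d >= 10 & !is.na(vaf) & vaf >= 0.30
  q_re_lof <- d >= 10 & !is.na(vaf) &
    ((d < 50 & vaf >= 0.20) | (d >= 50 & vaf >= 0.10))
  q_re_non <- d >= 10 & !is.na(vaf) &
    ((d < 50 & vaf >= 0.25) | (d >= 50 & vaf >= 0.10))
  Pq <- list(primary_lof = sum(pw[q_primary]),
             primary_non = sum(pw[q_primary]),
             reanalysis_lof = sum(pw[q_re_lof]),
             reanalysis_non = sum(pw[q_re_non]))

  gd <- cfg$gnomad_dist
  Pfreq <- sum(gd$prob[is.na(gd$ac) | gd$ac <= 4])
  Pabs <- sum(gd$prob[is.na(gd$ac) | gd$ac == 0])
  pAbsGiven <- Pabs / Pfreq
  cv <- cfg$clinvar_dist
  pCV <- sum(cv$prob[cv$value %in% c("pathogenic", "likely_pathogenic")])
  pd <- cfg$predictor_dist
  Pmaj <- sum(pd$prob[pd$avail > 0 &
                        round(pd$frac * pd$avail) / pd$avail >= 0.5])
  pv <- cfg$provean_dist
  Pprov <- sum(pv$prob[!is.na(pv$value) & pv$value <= -2.5])

  lof_set <- c("stop_gain", "frameshift", "canonical_splice", "start_loss")
  keep_set <- c(lof_set, "stop_loss", "inframe_indel", "missense")
  cd <- cfg$consequence_dist
  ps <- cfg$splice_hit_prob

  per_mode <- function(mode) {
    kept <- 0; cand <- 0
    for (ci in seq_len(nrow(cd))) {
      co <- cd$value[ci]; pc <- cd$prob[ci]
      is_l <- co %in% lof_set
      qp <- if (mode == "primary") Pq$primary_lof else
        if (is_l) Pq$reanalysis_lof else Pq$reanalysis_non
      for (s in c(0, 1)) {
        psw <- if (s == 1) ps else 1 - ps
        pass_c <- (co %in% keep_set) || s == 1
        if (!pass_c) next
        strongP <- if (is_l || s == 1) 1
        else if (co == "inframe_indel") Pprov
        else if (co == "missense") Pmaj
        else 0
        # default priority mode ("any"): three alternative routes
        route <- 1 - (1 - pCV) * (1 - pAbsGiven) * (1 - strongP)
        base <- pc * psw * qp * Pfreq
        kept <- kept + base
        cand <- cand + base * route
      }
    }
    on_panel <- 1 - cfg$off_panel_prob
    p_g <- cfg$plant_type_probs[["germline"]]
    p_m <- cfg$plant_type_probs[["mosaic"]]
    plant_snvs <- cfg$planted_prob * (p_g + p_m)
    plant_kept <- cfg$planted_prob *
      (p_g + if (mode == "reanalysis") p_m else 0)
    art_per_sample <- if (cfg$artifact_n_sites > 0 &&
                          cfg$artifact_carriers <= cfg$n_patients)
      cfg$artifact_n_sites * cfg$artifact_carriers / cfg$n_patients else 0
    mean_total <- cfg$background_mean + plant_snvs + art_per_sample
    mean_kept <- cfg$background_mean * on_panel * kept + plant_kept +
      art_per_sample
    mean_cand <- cfg$background_mean * on_panel * cand + plant_kept +
      art_per_sample
    list(mean_total = mean_total, mean_kept = mean_kept,
         mean_candidates = mean_cand,
         eliminated_fraction = 1 - mean_kept / mean_total)
  }
  list(primary = per_mode("primary"), reanalysis = per_mode("reanalysis"))
}

#' Write a cohort bundle to disk in the formats the CLIs consume
#'
#' @param cohort An `ndd_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_variants(cohort$variants, fp("variants.tsv"))
  write_patients(cohort$patients, fp("patients.tsv"))
  write_panel(cohort$panel, fp("panel.bed"))
  writeLines(cohort$panel$genes, fp("genes.txt"))
  fwrite(cohort$cnv_a, fp("cnv_a.tsv"), sep = "\t")
  fwrite(cohort$cnv_b, fp("cnv_b.tsv"), sep = "\t")
  fwrite(cohort$popsv, fp("popsv.tsv"), sep = "\t")
  fwrite(cohort$truth_snv, fp("truth_snv.tsv"), sep = "\t")
  fwrite(cohort$truth_cnv, fp("truth_cnv.tsv"), sep = "\t")
  invisible(dir)
}
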