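# Independent brute-force oracles: scalar, per-record restatements of the
# filter rules, deliberately written without reusing any package function.

# panel membership by linear scan over the raw region table
oracle_in_panel <- function(chrom, pos, regions) {
  any(regions$chrom == chrom & regions$start < pos & pos <= regions$end)
}

# terminal status of one variant row (list or one-row data.frame)
oracle_snv_status <- function(r, inside, mode) {
  if (!inside) return("off_panel")
  vaf <- if (r$depth > 0) r$alt_reads / r$depth else NA_real_
  lof <- r$consequence %in% c("stop_gain", "frameshift", "canonical_splice",
                              "start_loss")
  if (r$depth < 10) return("discarded_quality")
  if (mode == "primary") {
    if (is.na(vaf) || vaf < 0.30) return("discarded_quality")
  } else {
    if (r$depth < 50) {
      if (is.na(vaf) || vaf < (if (lof) 0.20 else 0.25))
        return("discarded_quality")
    } else if (is.na(vaf) || vaf < 0.10) return("discarded_quality")
  }
  if (!is.na(r$gnomad_ac) && r$gnomad_ac > 4) return("discarded_frequency")
  scores <- c(r$squirls, r$spliceai, r$splice_ada, r$splice_rf)
  splice <- any(!is.na(scores) & scores >= 0.5)
  protein <- r$consequence %in% c("stop_gain", "frameshift",
                                  "canonical_splice", "start_loss",
                                  "stop_loss", "inframe_indel", "missense")
  if (!protein && !splice) return("discarded_consequence")
  strong <- lof || splice ||
    (r$consequence == "inframe_indel" && !is.na(r$provean) &&
       r$provean <= -2.5) ||
    (r$consequence == "missense" && r$n_pred_avail > 0 &&
       r$n_pred_del / r$n_pred_avail >= 0.5)
  plp <- r$clinvar %in% c("pathogenic", "likely_pathogenic")
  absent <- is.na(r$gnomad_ac) || r$gnomad_ac == 0
  if (plp || absent || strong) "candidate" else "retained"
}

oracle_snv_all <- function(variants, regions, mode) {
  v <- as.data.frame(variants)
  vapply(seq_len(nrow(v)), function(i) {
    r <- as.list(v[i, ])
    oracle_snv_status(r, oracle_in_panel(r$chrom, r$pos, regions), mode)
  }, character(1))
}

oracle_ro <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}

# per-call CNV status by quadratic scan; dt must carry caller + phred
oracle_cnv_all <- function(dt, popsv) {
  dt <- as.data.frame(dt)
  sv <- as.data.frame(popsv)
  n <- nrow(dt)
  vapply(seq_len(n), function(i) {
    ro_i <- function(j) {
      if (dt$chrom[j] != dt$chrom[i] || dt$type[j] != dt$type[i]) return(0)
      oracle_ro(dt$start[i], dt$end[i], dt$start[j], dt$end[j])
    }
    others <- sum(vapply(seq_len(n), function(j)
      j != i && dt$sample_id[j] != dt$sample_id[i] && ro_i(j) >= 0.8,
      logical(1)))
    if (others > 3) return("discarded_recurrent")
    if (nrow(sv)) {
      hit <- any(vapply(seq_len(nrow(sv)), function(k) {
        if (sv$chrom[k] != dt$chrom[i] || sv$type[k] != dt$type[i])
          return(FALSE)
        freq_bad <- (!is.na(sv$ac[k]) && sv$ac[k] > 10) ||
          (!is.na(sv$af[k]) && sv$af[k] > 1e-4)
        freq_bad &&
          oracle_ro(dt$start[i], dt$end[i], sv$start[k], sv$end[k]) >= 0.9
      }, logical(1)))
      if (hit) return("discarded_popsv")
    }
    partners <- which(vapply(seq_len(n), function(j)
      j != i && dt$sample_id[j] == dt$sample_id[i] &&
        dt$caller[j] != dt$caller[i] && ro_i(j) >= 0.8, logical(1)))
    if (length(partners) == 0L) {
      lowq <- (dt$caller[i] == "A" && dt$phred[i] < 20) ||
        (dt$caller[i] == "B" && dt$phred[i] < 3)
      return(if (lowq) "discarded_single_lowq" else "retained")
    }
    ros <- vapply(partners, ro_i, numeric(1))
    best <- partners[order(-ros, -dt$phred[partners])][1]
    pa <- if (dt$caller[i] == "A") dt$phred[i] else dt$phred[best]
    pb <- if (dt$caller[i] == "B") dt$phred[i] else dt$phred[best]
    if (pa >= 30 && pb >= 20) "candidate" else "retained"
  }, character(1))
}

# tiny deterministic variant-row constructor for unit tests
make_variant <- function(sample_id = "S1", chrom = "chr1", pos = 100L,
                         ref = "A", alt = "T", gene = "G1", depth = 100L,
                         alt_reads = 50L, gnomad_ac = NA_integer_,
                         gnomad_af = NA_real_, gnomad_hom = NA_integer_,
                         consequence = "missense", clinvar = "absent",
                         provean = NA_real_, squirls = NA_real_,
                         spliceai = NA_real_, splice_ada = NA_real_,
                         splice_rf = NA_real_, zygosity = "het",
                         n_pred_avail = 0L, n_pred_del = 0L) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, depth = depth, alt_reads = alt_reads,
             gnomad_ac = gnomad_ac, gnomad_af = gnomad_af,
             gnomad_hom = gnomad_hom, consequence = consequence,
             clinvar = clinvar, provean = provean, squirls = squirls,
             spliceai = spliceai, splice_ada = splice_ada,
             splice_rf = splice_rf, zygosity = zygosity,
             n_pred_avail = n_pred_avail, n_pred_del = n_pred_del,
             stringsAsFactors = FALSE)
}

# single-region panel covering chr1:1..10000 (1-based), i.e. [0, 10000)
toy_panel <- function() {
  panel_definition(data.frame(chrom = "chr1", start = 0L, end = 10000L,
                              gene = "G1"))
}
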