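# Readers/writers: flat variant TSV, VCF 4.x with configurable INFO-key
# mapping, CNV call tables, coverage QC, and run outputs.

#' Write a cohort variant table to TSV
#'
#' One row per (sample, variant), tab-separated, NA written as `NA`; stable
#' column order. Round-trips through [read_variants()].
#'
#' @param variants A variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  dt <- as.data.table(variants)
  cols <- intersect(c(VARIANT_REQUIRED_COLS, VARIANT_OPTIONAL_COLS),
                    names(dt))
  fwrite(dt[, ..cols], path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Default VCF annotation mapping
#'
#' Names the INFO keys holding each annotation field. Override entries to
#' match the upstream annotation dialect.
#'
#' @return Named list mapping record fields to INFO keys.
#' @export
vcf_mapping <- function() {
  list(gene = "GENE", consequence = "CONSEQ", clinvar = "CLNSIG",
       gnomad_ac = "GAC", gnomad_af = "GAF", gnomad_hom = "GHOM",
       provean = "PROVEAN", squirls = "SQUIRLS", spliceai = "SPLICEAI",
       splice_ada = "ADA", splice_rf = "RF", predictor_calls = "PREDCALLS")
}

.read_variants_vcf <- function(path, mapping) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)  # one row per alt allele
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- VariantAnnotation::geno(vcf)$AD
  dp <- VariantAnnotation::geno(vcf)$DP
  samples <- colnames(vcf)
  get_info <- function(field, default = NA) {
    key <- mapping[[field]]
    if (!is.null(key) && key %in% names(info)) {
      v <- info[[key]]
      if (is(v, "List")) v <- as.numeric(unlist(lapply(v, `[`, 1)))
      v
    } else rep(default, nrow(info))
  }
  rows <- lapply(seq_along(samples), function(j) {
    called <- !(gt[, j] %in% c("0/0", "0|0", "./.", ".", ".|."))
    if (!any(called)) return(NULL)
    i <- which(called)
    # AD after expand(): array variants x samples x (ref, alt), or a
    # matrix of integer vectors in unexpanded corner cases
    altr <- if (length(dim(ad)) == 3L) as.integer(ad[i, j, 2])
    else vapply(ad[i, j], function(x)
      if (length(x) >= 2) as.integer(x[2]) else NA_integer_, integer(1))
    data.table(
      sample_id = samples[j],
      chrom = as.character(GenomicRanges::seqnames(rr))[i],
      pos = GenomicRanges::start(rr)[i],
      ref = as.character(rr$REF)[i],
      alt = as.character(rr$ALT)[i],
      gene = as.character(get_info("gene", NA_character_))[i],
      depth = as.integer(dp[i, j]),
      alt_reads = altr,
      gnomad_ac = as.integer(get_info("gnomad_ac"))[i],
      gnomad_af = as.numeric(get_info("gnomad_af"))[i],
      gnomad_hom = as.integer(get_info("gnomad_hom"))[i],
      consequence = as.character(get_info("consequence", NA_character_))[i],
      clinvar = as.character(get_info("clinvar", NA_character_))[i],
      provean = as.numeric(get_info("provean"))[i],
      squirls = as.numeric(get_info("squirls"))[i],
      spliceai = as.numeric(get_info("spliceai"))[i],
      splice_ada = as.numeric(get_info("splice_ada"))[i],
      splice_rf = as.numeric(get_info("splice_rf"))[i],
      predictor_calls =
        as.character(get_info("predictor_calls", NA_character_))[i],
      zygosity = ifelse(gt[i, j] %in% c("1/1", "1|1"), "hom", "het"))
  })
  rbindlist(rows)
}

#' Read a cohort variant table (flat TSV or VCF)
#'
#' TSV: one row per (sample, variant) with the documented column names.
#' VCF 4.x: annotations taken from INFO keys per `mapping`; genotype depth
#' and alt reads from the `DP`/`AD` FORMAT fields; one record per called
#' alt allele per sample (multi-allelic sites are expanded). Rows violating
#' record invariants are rejected with a warning.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param mapping INFO-key mapping for VCF input (see [vcf_mapping()]).
#' @return A validated variant table.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf"),
                          mapping = vcf_mapping()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  dt <- if (format == "vcf") .read_variants_vcf(path, mapping)
  else fread(path, sep = "\t", na.strings = "NA")
  validate_variants(dt)
}

#' Read a CNV call table
#'
#' Accepts either the caller-A (XHMM-like) dialect with an interval string
#' column (`interval` = "chr:start-end", `q_some` as Phred) or the caller-B
#' (ExomeDepth-like) flat dialect (`chrom`, `start`, `end`, `bf` on the
#' caller-B Phred scale). Already-normalized tables (with `phred`) pass
#' through.
#'
#' @param path Input TSV.
#' @param caller `"A"` or `"B"`.
#' @return data.table with `sample_id`, `chrom`, `start`, `end`, `type`,
#'   `phred`, `caller`.
#' @export
read_cnv_calls <- function(path, caller = c("A", "B")) {
  caller <- match.arg(caller)
  dt <- fread(path, sep = "\t")
  if ("interval" %in% names(dt) && !"chrom" %in% names(dt)) {
    parts <- tstrsplit(dt$interval, "[:-]")
    dt[, chrom := parts[[1]]]
    dt[, start := as.integer(parts[[2]])]
    dt[, end := as.integer(parts[[3]])]
  }
  if (!"phred" %in% names(dt)) {
    if ("q_some" %in% names(dt)) dt[, phred := q_some]
    else if ("bf" %in% names(dt)) dt[, phred := bf]
    else stop("CNV table needs a quality column (phred, q_some or bf)")
  }
  .validate_cnv_calls(dt[, .(sample_id, chrom, start, end, type, phred)],
                      caller)
}

#' Per-sample coverage summary over panel positions
#'
#' Positions inside panel target regions that are absent from the depth
#' table count as zero coverage. Mirrors the published QC: mean target
#' depth and the fractions of targeted positions covered at >= 10x and
#' >= 50x, plus target regions with no covered base.
#'
#' @param depths data.frame with `sample_id`, `chrom`, `pos` (1-based),
#'   `depth`.
#' @param panel A [panel_definition()] with at least one region.
#' @return List with `per_sample` (data.table: `sample_id`, `mean_depth`,
#'   `frac_ge10`, `frac_ge50`) and `zero_regions` (per sample, regions with
#'   no covered base).
#' @export
coverage_summary <- function(depths, panel) {
  stopifnot(inherits(panel, "panel_definition"))
  if (length(panel$regions) == 0L) stop("empty panel")
  dt <- as.data.table(depths)
  need <- c("sample_id", "chrom", "pos", "depth")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("depth table lacks column(s): ", paste(miss, collapse = ", "))
  total_bases <- sum(GenomicRanges::width(panel$regions))
  keep <- in_panel(dt$chrom, dt$pos, panel)
  dt <- dt[keep]
  per_sample <- dt[, .(
    mean_depth = sum(depth) / total_bases,
    frac_ge10 = sum(depth >= 10) / total_bases,
    frac_ge50 = sum(depth >= 50) / total_bases), by = sample_id]
  gr <- panel$regions
  zero <- rbindlist(lapply(split(dt, dt$sample_id), function(sd) {
    q <- GenomicRanges::GRanges(sd$chrom,
                                IRanges::IRanges(sd$pos, sd$pos))
    covered <- suppressWarnings(IRanges::overlapsAny(gr, q[sd$depth > 0]))
    if (all(covered)) return(NULL)
    data.table(sample_id = sd$sample_id[1],
               gene = gr$gene[!covered],
               chrom = as.character(GenomicRanges::seqnames(gr))[!covered],
               start = GenomicRanges::start(gr)[!covered] - 1L,
               end = GenomicRanges::end(gr)[!covered])
  }))
  list(per_sample = per_sample[], zero_regions = zero)
}

#' Write triage run outputs
#'
#' Emits `decisions.tsv` (stable column order), `summary.json` (per-sample
#' counts plus cohort summary) and `config.json` (thresholds, mode and seed
#' echo) into `dir`.
#'
#' @param result A `triage_result` from [run_triage()].
#' @param dir Output directory.
#' @param thresholds The [triage_thresholds()] used.
#' @param seed Optional seed to echo.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, dir, thresholds = triage_thresholds(),
                          seed = NULL) {
  stopifnot(inherits(result, "triage_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dec <- result$decisions
  cols <- intersect(c(VARIANT_REQUIRED_COLS, VARIANT_OPTIONAL_COLS,
                      "status", "reasons", "artifact_flag"), names(dec))
  fwrite(dec[, ..cols], file.path(dir, "decisions.tsv"), sep = "\t",
         na = "NA", quote = FALSE)
  jsonlite::write_json(
    list(summary = result$summary,
         per_sample = result$per_sample,
         stage_counts = as.list(table(dec$status))),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(thresholds = unclass(thresholds), seed = seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
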