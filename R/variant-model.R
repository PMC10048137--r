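#' @useDynLib nddtriage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
#' @importFrom stats chisq.test pchisq qnorm wilcox.test hclust as.dist cutree
#'   rbinom rpois runif setNames median sd
#' @importFrom utils head modifyList
#' @importFrom methods is
"_PACKAGE"

# Consequence vocabulary. The first four classes are loss-of-function.
LOF_CONSEQUENCES <- c("stop_gain", "frameshift", "canonical_splice", "start_loss")

CONSEQUENCES <- c(LOF_CONSEQUENCES, "stop_loss", "inframe_indel", "missense",
                  "synonymous", "intronic", "other")

CLINVAR_LEVELS <- c("pathogenic", "likely_pathogenic", "other", "absent")

TRIAGE_STATUSES <- c("off_panel", "discarded_quality", "discarded_frequency",
                     "discarded_consequence", "retained", "candidate")

SPLICE_SCORE_COLS <- c("squirls", "spliceai", "splice_ada", "splice_rf")

#' In-silico deleteriousness predictors used for missense majority voting
#'
#' The 36 predictors whose categorical calls (deleterious / tolerated /
#' missing) feed [missense_majority_vote()]: 27 function-based predictors and
#' 9 conservation-based scores. Raw scores are never interpreted by this
#' package; the upstream annotation supplies the calls.
#'
#' @return Character vector of predictor names, in the canonical order used by
#'   the compact `predictor_calls` string encoding.
#' @export
predictor_names <- function() {
  c("SIFT", "SIFT4G", "Polyphen2_HDIV", "Polyphen2_HVAR", "LRT",
    "MutationTaster2", "MutationAssessor", "FATHMM", "MetaSVM", "MetaLR",
    "CADD", "VEST4", "PROVEAN", "FATHMM_MKL", "FATHMM_XF", "fitCons", "DANN",
    "GenoCanyon", "Eigen", "Eigen_PC", "M_CAP", "REVEL", "MutPred", "MVP",
    "MPC", "PrimateAI", "DEOGEN2",
    "bStatistic", "phyloP100way_vertebrate", "phyloP30way_mammal",
    "phyloP17way_primate", "phastCons100way_vertebrate",
    "phastCons30way_mammal", "phastCons17way_primate", "GERPpp", "SiPhy")
}

#' Filter thresholds for the SNV triage cascade
#'
#' Returns the default thresholds of the filter cascade; any of them can be
#' overridden. Defaults implement the published rules: discard depth < 10;
#' discard gnomAD allele count > 4; primary mode discards variant allele
#' fraction (VAF) < 30%; re-analysis mode discards VAF < 20% (LoF) / < 25%
#' (non-LoF) in the 10 <= depth < 50 band and VAF < 10% at depth >= 50 (the
#' mosaic band); splice ensemble cutoff 0.5; PROVEAN cutoff -2.5 for in-frame
#' indels; missense majority fraction 0.5; recurrent-artifact flagging of
#' gnomAD-absent variants seen in more than 3 cohort samples; recessive
#' discard at gnomAD AF >= 0.1% or > 4 homozygotes.
#'
#' @param min_depth Minimum read depth; below it the variant is discarded.
#' @param max_gnomad_ac Maximum tolerated gnomAD allele count (strict `>`
#'   discards).
#' @param min_vaf_primary Minimum VAF in primary mode.
#' @param lowdp_max Exclusive upper bound of the low-depth band in re-analysis
#'   mode; at `depth >= lowdp_max` the mosaic rule applies.
#' @param min_vaf_lof_lowdp,min_vaf_nonlof_lowdp Minimum VAF in the low-depth
#'   band for LoF / non-LoF variants (re-analysis mode).
#' @param mosaic_min_vaf Minimum VAF at `depth >= lowdp_max` (re-analysis).
#' @param artifact_min_carriers Minimum number of distinct carrier samples for
#'   a gnomAD-absent variant to be flagged as a putative recurrent artifact
#'   (the published rule "> 3 patients" means 4 or more).
#' @param splice_cutoff Score at or above which any of the four splice
#'   predictors marks a variant as splice-affecting.
#' @param provean_cutoff PROVEAN score at or below which an in-frame indel
#'   counts as strongly protein-affecting.
#' @param majority_fraction Fraction of available predictors that must call a
#'   missense variant deleterious.
#' @param recessive_max_af gnomAD allele frequency at or above which a variant
#'   is discarded in the recessive filter.
#' @param recessive_max_hom gnomAD homozygote count above which a variant is
#'   discarded in the recessive filter.
#' @param priority_mode `"any"` (default): a variant is a candidate if it is
#'   ClinVar pathogenic/likely-pathogenic OR absent from gnomAD OR predicted
#'   to strongly affect protein function. `"conjunction"`: all three must
#'   hold.
#' @return A named list of class `triage_thresholds`.
#' @export
triage_thresholds <- function(min_depth = 10L,
                              max_gnomad_ac = 4L,
                              min_vaf_primary = 0.30,
                              lowdp_max = 50L,
                              min_vaf_lof_lowdp = 0.20,
                              min_vaf_nonlof_lowdp = 0.25,
                              mosaic_min_vaf = 0.10,
                              artifact_min_carriers = 4L,
                              splice_cutoff = 0.5,
                              provean_cutoff = -2.5,
                              majority_fraction = 0.5,
                              recessive_max_af = 0.001,
                              recessive_max_hom = 4L,
                              priority_mode = c("any", "conjunction")) {
  priority_mode <- match.arg(priority_mode)
  th <- list(min_depth = as.integer(min_depth),
             max_gnomad_ac = as.integer(max_gnomad_ac),
             min_vaf_primary = min_vaf_primary,
             lowdp_max = as.integer(lowdp_max),
             min_vaf_lof_lowdp = min_vaf_lof_lowdp,
             min_vaf_nonlof_lowdp = min_vaf_nonlof_lowdp,
             mosaic_min_vaf = mosaic_min_vaf,
             artifact_min_carriers = as.integer(artifact_min_carriers),
             splice_cutoff = splice_cutoff,
             provean_cutoff = provean_cutoff,
             majority_fraction = majority_fraction,
             recessive_max_af = recessive_max_af,
             recessive_max_hom = as.integer(recessive_max_hom),
             priority_mode = priority_mode)
  stopifnot(th$min_depth >= 0L, th$lowdp_max >= th$min_depth,
            th$min_vaf_primary >= 0, th$min_vaf_primary <= 1,
            th$artifact_min_carriers >= 1L)
  structure(th, class = "triage_thresholds")
}

#' Is a consequence loss-of-function?
#'
#' LoF covers stop gain, frameshift, canonical splice-site and start loss.
#' Stop loss is protein-affecting but, by convention, not LoF.
#'
#' @param consequence Character vector of consequence classes.
#' @return Logical vector.
#' @export
is_lof <- function(consequence) {
  bad <- !is.na(consequence) & !(consequence %in% CONSEQUENCES)
  if (any(bad))
    stop("unknown consequence class(es): ",
         paste(unique(consequence[bad]), collapse = ", "))
  consequence %in% LOF_CONSEQUENCES
}

#' Build a virtual-panel definition
#'
#' A panel is a gene list plus target regions (coding exons padded by 20 bp of
#' flanking intron on each side). Regions are merged per gene so they are
#' non-overlapping; coordinates are half-open 0-based internally (BED
#' convention), so a 1-based variant position `pos` lies in `[start, end)`
#' iff `start < pos <= end`.
#'
#' @param regions data.frame with columns `chrom`, `start` (0-based),
#'   `end` (exclusive), `gene`.
#' @param genes Optional character vector of panel gene symbols; defaults to
#'   the genes present in `regions`.
#' @return An object of class `panel_definition` with elements `genes`
#'   (character) and `regions` (a `GRanges` with a `gene` metadata column).
#' @export
panel_definition <- function(regions, genes = NULL) {
  regions <- as.data.table(regions)
  need <- c("chrom", "start", "end", "gene")
  miss <- setdiff(need, names(regions))
  if (length(miss))
    stop("panel regions lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(regions) && any(regions$end <= regions$start))
    stop("malformed panel interval: end must be > start")
  if (is.null(genes)) genes <- sort(unique(regions$gene))
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    # 0-based half-open [start, end) -> 1-based inclusive [start+1, end]
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    gene = regions$gene)
  # merge per gene so regions are non-overlapping
  merged <- unlist(GenomicRanges::reduce(
    GenomicRanges::split(gr, gr$gene)))
  merged$gene <- names(merged)
  names(merged) <- NULL
  structure(list(genes = genes, regions = merged),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("Virtual panel: %d genes, %d target regions, %.2f Mb\n",
              length(x$genes), length(x$regions),
              sum(GenomicRanges::width(x$regions)) / 1e6))
  invisible(x)
}

#' Read a panel from a BED file and a gene list
#'
#' @param bed_path BED file of target regions; the 4th (name) column carries
#'   the gene symbol.
#' @param genes_path Optional plain-text file with one gene symbol per line.
#' @return A [panel_definition()] object.
#' @export
read_panel <- function(bed_path, genes_path = NULL) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name))
    stop("panel BED must carry the gene symbol in its name column")
  regions <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        gene = gr$name)
  genes <- NULL
  if (!is.null(genes_path))
    genes <- scan(genes_path, what = character(), quiet = TRUE)
  panel_definition(regions, genes)
}

#' Write panel target regions to BED
#'
#' @param panel A [panel_definition()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  gr <- panel$regions
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = gr$gene)
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Test whether variant positions fall inside panel target regions
#'
#' @param chrom Character vector of chromosomes.
#' @param pos Integer vector of 1-based positions.
#' @param panel A [panel_definition()].
#' @return Logical vector, `TRUE` where the position lies in a target region.
#'   An empty panel returns all `FALSE`.
#' @export
in_panel <- function(chrom, pos, panel) {
  stopifnot(inherits(panel, "panel_definition"), length(chrom) == length(pos))
  if (length(panel$regions) == 0L || length(pos) == 0L)
    return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  # differing seqlevel sets between query and panel are expected
  suppressWarnings(
    IRanges::overlapsAny(q, panel$regions, ignore.strand = TRUE))
}

# ---- variant table -------------------------------------------------------

VARIANT_REQUIRED_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                           "depth", "alt_reads", "consequence")

VARIANT_OPTIONAL_COLS <- c("vaf", "gnomad_ac", "gnomad_af", "gnomad_hom",
                           "clinvar", "provean", SPLICE_SCORE_COLS,
                           "zygosity", "n_pred_avail", "n_pred_del",
                           "predictor_calls")

#' Parse compact predictor-call strings into counts
#'
#' Calls are encoded as comma-separated one-letter codes in the order of
#' [predictor_names()]: `D` deleterious, `T` tolerated, `.` missing.
#'
#' @param calls Character vector of encoded call strings (NA allowed).
#' @return data.table with columns `n_pred_avail` and `n_pred_del`.
#' @export
parse_predictor_calls <- function(calls) {
  n_avail <- integer(length(calls))
  n_del <- integer(length(calls))
  ok <- !is.na(calls) & nzchar(calls)
  if (any(ok)) {
    # "|" is accepted as an alternative separator (safe inside VCF INFO)
    parts <- strsplit(calls[ok], "[,|]")
    n_del[ok] <- vapply(parts, function(p) sum(p == "D"), integer(1))
    n_avail[ok] <- n_del[ok] +
      vapply(parts, function(p) sum(p == "T"), integer(1))
  }
  data.table(n_pred_avail = n_avail, n_pred_del = n_del)
}

#' Validate a cohort variant table
#'
#' Enforces the record invariants: required columns present, `alt_reads <=
#' depth`, non-negative counts, known consequence and ClinVar levels, unique
#' (sample, chrom, pos, ref, alt) keys, `gnomad_af = 0` only with
#' `gnomad_ac = 0`. The VAF is (re)computed as `alt_reads / depth` (NA at
#' depth 0). Rows violating row-level invariants are dropped with a warning
#' and returned in the `rejected` attribute.
#'
#' @param variants data.frame of variant records.
#' @return A validated data.table (class `variant_table`).
#' @export
validate_variants <- function(variants) {
  dt <- as.data.table(variants)
  miss <- setdiff(VARIANT_REQUIRED_COLS, names(dt))
  if (length(miss))
    stop("variant table lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  chr_cols <- c("clinvar", "zygosity", "predictor_calls")
  for (col in setdiff(VARIANT_OPTIONAL_COLS, names(dt)))
    dt[, (col) := if (col %in% chr_cols) NA_character_ else NA_real_]
  # all-NA columns read back from TSV come in as logical; fix their type
  for (col in VARIANT_OPTIONAL_COLS)
    if (is.logical(dt[[col]]))
      dt[, (col) := if (col %in% chr_cols) as.character(get(col))
        else as.numeric(get(col))]
  if (all(is.na(dt$n_pred_avail)) && any(!is.na(dt$predictor_calls))) {
    cnt <- parse_predictor_calls(dt$predictor_calls)
    dt[, c("n_pred_avail", "n_pred_del") :=
         list(cnt$n_pred_avail, cnt$n_pred_del)]
  }
  dt[is.na(n_pred_avail), c("n_pred_avail", "n_pred_del") := list(0L, 0L)]
  dt[is.na(clinvar), clinvar := "absent"]
  bad <- is.na(dt$depth) | is.na(dt$alt_reads) |
    dt$depth < 0 | dt$alt_reads < 0 | dt$alt_reads > dt$depth |
    !(dt$consequence %in% CONSEQUENCES) |
    !(dt$clinvar %in% CLINVAR_LEVELS) |
    (!is.na(dt$gnomad_af) & !is.na(dt$gnomad_ac) &
       dt$gnomad_af == 0 & dt$gnomad_ac > 0)
  rejected <- dt[bad]
  if (nrow(rejected))
    warning(sprintf("rejected %d invalid variant row(s)", nrow(rejected)))
  dt <- dt[!bad]
  dt[, vaf := ifelse(depth > 0, alt_reads / depth, NA_real_)]
  if (anyDuplicated(dt, by = c("sample_id", "chrom", "pos", "ref", "alt")))
    stop("duplicated (sample, chrom, pos, ref, alt) keys in variant table")
  setattr(dt, "rejected", rejected)
  setattr(dt, "class", c("variant_table", class(dt)))
  dt[]
}

#' Variant identifier key
#'
#' @param variants A variant table.
#' @param with_sample Include the sample id in the key?
#' @return Character vector of keys.
#' @export
variant_key <- function(variants, with_sample = TRUE) {
  base <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
                sep = ":")
  if (with_sample) paste(variants$sample_id, base, sep = ":") else base
}
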