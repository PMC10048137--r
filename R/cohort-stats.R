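# Diagnostic-yield summaries and the cohort association statistics:
# chi-square tests (Yates-corrected 2x2 and uncorrected goodness of fit —
# the combination that reproduces the published p-values), phi coefficient,
# and the Glass rank-biserial effect size.

#' Diagnostic yield as a percentage
#'
#' @param diagnosed Number of diagnosed patients.
#' @param total Total patients (> 0).
#' @return `100 * diagnosed / total`.
#' @export
diagnostic_yield <- function(diagnosed, total) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(diagnosed > total)) stop("diagnosed cannot exceed total")
  100 * diagnosed / total
}

#' Build a 2x2 contingency table
#'
#' Rows are groups, columns outcomes: `a`,`b` in row 1, `c`,`d` in row 2.
#'
#' @param a,b,c,d Non-negative integer counts with positive total.
#' @return 2x2 integer matrix of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be non-negative with positive total")
  structure(matrix(as.numeric(counts), 2, 2, byrow = TRUE),
            class = c("contingency_2x2", "matrix"))
}

#' Chi-square test of independence on a 2x2 table (Yates-corrected)
#'
#' Continuity-corrected statistic `sum((|O-E|-0.5)^2/E)` on 1 df. This is the
#' variant that reproduces the published subset and sex comparisons.
#'
#' @param table A 2x2 matrix (e.g. [contingency_2x2()]).
#' @param correct Apply the Yates continuity correction (default `TRUE`).
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi2_2x2_yates <- function(table, correct = TRUE) {
  m <- unclass(as.matrix(table))
  if (any(dim(m) != 2L)) stop("need a 2x2 table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in 2x2 table")
  ct <- stats::chisq.test(m, correct = correct)
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Chi-square goodness-of-fit test against equal proportions
#'
#' Uncorrected `sum((O - n/2)^2 / (n/2))` on 1 df; this variant reproduces
#' the published male-enrichment p-value.
#'
#' @param counts Length-2 vector of observed counts.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi2_gof_equal <- function(counts) {
  stopifnot(length(counts) == 2L, sum(counts) > 0)
  ct <- stats::chisq.test(counts, p = c(0.5, 0.5))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Phi correlation coefficient of a 2x2 table
#'
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`; satisfies
#' `phi^2 * n = chi2` (uncorrected).
#'
#' @param table A 2x2 matrix.
#' @return Value in `[-1, 1]`.
#' @export
phi_coefficient <- function(table) {
  m <- unclass(as.matrix(table))
  if (any(dim(m) != 2L)) stop("need a 2x2 table")
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  denom <- sqrt((a + b)) * sqrt((c + d)) * sqrt((a + c)) * sqrt((b + d))
  if (denom == 0) stop("zero margin: phi undefined")
  (a * d - b * c) / denom
}

#' Glass rank-biserial correlation
#'
#' Effect size of a binary grouping on a ranked quantity:
#' `r = 2 (meanrank_1 - meanrank_0) / n`, with midranks for ties. +1 when
#' every group-1 value exceeds every group-0 value.
#'
#' @param values Numeric vector.
#' @param labels Binary vector (0/1 or logical) of the same length; both
#'   groups must be non-empty.
#' @return Value in `[-1, 1]`.
#' @export
glass_rank_biserial <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(values) == length(labels))
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both groups must be non-empty")
  r <- rank(values)   # midranks for ties
  2 * (mean(r[labels == 1L]) - mean(r[labels == 0L])) / length(values)
}

#' Cohort summary: yields, inheritance patterns and variant types
#'
#' Reproduces the layout of the published summary table: patient counts and
#' diagnostic yields overall / by subset / by sex, plus pathogenic-variant
#' breakdowns by inheritance class and variant type (percentages over the
#' number of pathogenic/likely-pathogenic variants). X-linked is a
#' cross-cutting axis: `inheritance` must be one of `de_novo`, `inherited`,
#' `uncertain_na`, with a separate logical `x_linked` column.
#'
#' @param patients data.frame with `patient_id`, `sex` (`M`/`F`), `subset`
#'   (`ID_GDD`/`ASD`), `diagnosed` (logical).
#' @param variants data.frame of pathogenic/likely-pathogenic variants with
#'   `patient_id`, `inheritance`, `x_linked`, `var_type` (one of `lof`,
#'   `missense`, `inframe`, `cryptic_splice`, `cnv_del`, `cnv_dup`). May be
#'   empty.
#' @return Nested list of class `cohort_summary` with elements `patients`,
#'   `yield`, `inheritance`, `variant_type`.
#' @export
build_summary <- function(patients, variants) {
  p <- as.data.table(patients)
  v <- as.data.table(variants)
  stopifnot(all(p$sex %in% c("M", "F")),
            all(p$subset %in% c("ID_GDD", "ASD")))
  if (nrow(v)) {
    bad <- setdiff(v$patient_id, p$patient_id)
    if (length(bad))
      stop("variant rows reference unknown patient(s): ",
           paste(head(bad, 5), collapse = ", "))
    undiag <- setdiff(v$patient_id, p[diagnosed == TRUE, patient_id])
    if (length(undiag))
      stop("variant rows for patients not flagged diagnosed: ",
           paste(head(undiag, 5), collapse = ", "))
    stopifnot(all(v$inheritance %in%
                    c("de_novo", "inherited", "uncertain_na")),
              all(v$var_type %in% c("lof", "missense", "inframe",
                                    "cryptic_splice", "cnv_del", "cnv_dup")))
  }
  pct <- function(k, n) if (n > 0) round(100 * k / n, 1) else 0
  yield_block <- function(sub) {
    list(n = nrow(sub),
         diagnosed = sum(sub$diagnosed),
         yield = pct(sum(sub$diagnosed), max(nrow(sub), 1L)))
  }
  groups <- list(all = p, id_gdd = p[subset == "ID_GDD"],
                 asd = p[subset == "ASD"],
                 male = p[sex == "M"], female = p[sex == "F"])
  nv <- nrow(v)
  inh_counts <- sapply(c("de_novo", "inherited", "uncertain_na"),
                       function(k) sum(v$inheritance == k))
  type_counts <- sapply(c("lof", "missense", "inframe", "cryptic_splice",
                          "cnv_del", "cnv_dup"),
                        function(k) sum(v$var_type == k))
  structure(list(
    patients = list(total = nrow(p),
                    male = sum(p$sex == "M"), female = sum(p$sex == "F"),
                    id_gdd = sum(p$subset == "ID_GDD"),
                    asd = sum(p$subset == "ASD")),
    yield = lapply(groups, yield_block),
    inheritance = list(
      counts = as.list(inh_counts),
      percent = lapply(as.list(inh_counts), pct, n = max(nv, 1L)),
      x_linked = list(count = sum(v$x_linked),
                      percent = pct(sum(v$x_linked), max(nv, 1L)))),
    variant_type = list(
      counts = as.list(type_counts),
      percent = lapply(as.list(type_counts), pct, n = max(nv, 1L)),
      n_variants = nv)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d patients (%d M / %d F), %d ID/GDD, %d ASD\n",
              x$patients$total, x$patients$male, x$patients$female,
              x$patients$id_gdd, x$patients$asd))
  cat(sprintf("Diagnostic yield: %.1f%% overall (ID/GDD %.1f%%, ASD %.1f%%; M %.1f%%, F %.1f%%)\n",
              x$yield$all$yield, x$yield$id_gdd$yield, x$yield$asd$yield,
              x$yield$male$yield, x$yield$female$yield))
  cat(sprintf("P/LP variants: %d (LoF %.1f%%, de novo %.1f%%, X-linked %.1f%%)\n",
              x$variant_type$n_variants, x$variant_type$percent$lof,
              x$inheritance$percent$de_novo, x$inheritance$x_linked$percent))
  invisible(x)
}
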