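# Phenotype profiling: balanced random forest predicting the presence of a
# pathogenic variant from the 16 category flags, sex and the number of
# affected categories; OOB evaluation; proximity-based prototype analysis.

#' Build the predictor matrix for profiling
#'
#' Columns: the 16 category flags (0/1), `sex` (M = 1, F = 0) and
#' `n_categories`. The outcome is the diagnosed flag.
#'
#' @param patients data.table with `sex`, `n_categories`, `diagnosed`
#'   (from [annotate_phenotypes()] plus a diagnosed flag).
#' @param flags Logical matrix of category flags (patients x 16).
#' @return List with numeric matrix `x` and integer outcome `y`.
#' @export
build_predictor_matrix <- function(patients, flags) {
  p <- as.data.table(patients)
  stopifnot(nrow(p) == nrow(flags), !anyNA(p$diagnosed))
  x <- cbind(flags * 1, sex = as.integer(p$sex == "M"),
             n_categories = p$n_categories)
  storage.mode(x) <- "double"
  list(x = x, y = as.integer(p$diagnosed))
}

#' Fit a balanced random forest with OOB votes and proximities
#'
#' Grows `ntree` unpruned CART trees; each draws, without replacement,
#' `floor(sample_fraction * n_minority)` cases from each outcome class
#' (class-balanced under-sampling, 80% of the least frequent class by
#' default). OOB vote fractions are computed from the trees not containing a
#' case; proximity between two cases is the fraction of trees in which they
#' share a terminal leaf.
#'
#' @param x Numeric predictor matrix (cases x features).
#' @param y Binary outcome (0/1 or logical), both classes present.
#' @param ntree Number of trees (default 5000).
#' @param mtry Features tried per split; default `floor(sqrt(ncol(x)))`.
#' @param sample_fraction Per-class draw as a fraction of the minority class
#'   size (default 0.8).
#' @param proximity Accumulate the proximity matrix (default `TRUE`).
#' @param seed Optional RNG seed applied via `set.seed()`.
#' @return Object of class `rf_profile`: `votes` (OOB vote fraction for the
#'   diagnosed class; NA if a case was never OOB), `oob_trees`, `proximity`,
#'   `y`, `ntree`, `mtry`.
#' @export
fit_forest <- function(x, y, ntree = 5000L, mtry = NULL,
                       sample_fraction = 0.8, proximity = TRUE,
                       seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) stop("outcome must contain both classes")
  if (min(table(y)) < 2L) stop("need at least 2 cases per class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  draw <- max(1L, floor(sample_fraction * min(table(y))))
  if (!is.null(seed)) set.seed(seed)
  fit <- .grow_forest_cpp(x, y, as.integer(ntree), as.integer(mtry),
                          as.integer(draw), isTRUE(proximity))
  votes <- ifelse(fit$oob_total > 0, fit$oob_pos / fit$oob_total, NA_real_)
  structure(list(votes = votes, oob_trees = fit$oob_total,
                 proximity = if (proximity) fit$proximity else NULL,
                 y = y, ntree = as.integer(ntree), mtry = as.integer(mtry),
                 per_class_draw = draw),
            class = "rf_profile")
}

#' AUC of scores against binary labels (rank statistic)
#'
#' Mann-Whitney form with midranks for ties.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("need both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate an OOB-fitted profile
#'
#' Confusion metrics at the majority-vote threshold (OOB vote fraction >=
#' 0.5) plus the rank AUC with a normal-approximation confidence interval
#' (Hanley-McNeil standard error).
#'
#' @param fit An `rf_profile` from [fit_forest()].
#' @param threshold Vote threshold for calling a case positive (default 0.5).
#' @param conf_level Confidence level for the AUC interval (default 0.95).
#' @return List with `sensitivity`, `specificity`, `accuracy`, `auc`,
#'   `auc_ci` (length-2), `threshold`.
#' @export
evaluate_profile <- function(fit, threshold = 0.5, conf_level = 0.95) {
  stopifnot(inherits(fit, "rf_profile"))
  ok <- !is.na(fit$votes)
  votes <- fit$votes[ok]; y <- fit$y[ok]
  pred <- as.integer(votes >= threshold)
  tp <- sum(pred == 1L & y == 1L); fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
  auc <- rank_auc(votes, y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(y), auc = auc,
       auc_ci = c(max(0, auc - z * se), min(1, auc + z * se)),
       threshold = threshold)
}

#' Mann-Whitney comparison of OOB votes between outcome groups
#'
#' Two-sided test of the vote distributions of diagnosed vs undiagnosed
#' patients, reporting the difference of group medians. Small tie-free
#' samples use the exact distribution; otherwise the normal approximation
#' with tie correction (stats::wilcox.test defaults).
#'
#' @param votes Numeric vote vector.
#' @param labels Binary vector.
#' @return List with `median_difference` (group1 - group0), `statistic`
#'   (U for group 1), `p_value`.
#' @export
mann_whitney_votes <- function(votes, labels) {
  labels <- as.integer(as.logical(labels))
  ok <- !is.na(votes)
  votes <- votes[ok]; labels <- labels[ok]
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both groups must be non-empty")
  wt <- suppressWarnings(
    wilcox.test(votes[labels == 1L], votes[labels == 0L]))
  list(median_difference =
         median(votes[labels == 1L]) - median(votes[labels == 0L]),
       statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Proximity-based prototype analysis
#'
#' Transforms RF proximities to dissimilarities (1 - PROX), performs Ward
#' hierarchical clustering, and replaces the published manual dendrogram
#' inspection with a reproducible rule: report every clade of at least
#' `min_size` patients whose diagnosed fraction exceeds the cohort fraction
#' by at least `margin`. A fixed cut into `k` groups is also returned when
#' `k` is given.
#'
#' @param proximity Symmetric proximity matrix with unit diagonal.
#' @param diagnosed Logical/binary outcome vector.
#' @param k Optional number of groups for a flat cut.
#' @param min_size Minimum clade size to report (default 10).
#' @param margin Required excess of the clade diagnosed fraction over the
#'   cohort fraction (default 0.1).
#' @param method Agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D2"`).
#' @return List with `hclust`, `groups` (flat-cut assignment or NULL),
#'   `group_yield` (per-group diagnostic yield for the flat cut),
#'   `prototype_clades` (data.table: clade id, size, diagnosed, yield),
#'   `cohort_yield`.
#' @export
prototype_groups <- function(proximity, diagnosed, k = NULL, min_size = 10L,
                             margin = 0.1, method = "ward.D2") {
  proximity <- as.matrix(proximity)
  if (!isTRUE(all.equal(proximity, t(proximity), tolerance = 1e-8)))
    stop("proximity matrix must be symmetric")
  diagnosed <- as.logical(diagnosed)
  n <- nrow(proximity)
  stopifnot(length(diagnosed) == n)
  hc <- hclust(as.dist(1 - proximity), method = method)
  cohort_yield <- mean(diagnosed)

  # members of every internal clade via the merge tree
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    pick <- function(j) if (j < 0) -j else members[[j]]
    members[[i]] <- c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2]))
  }
  clades <- rbindlist(lapply(seq_len(n - 1), function(i) {
    m <- members[[i]]
    data.table(clade = i, size = length(m), diagnosed = sum(diagnosed[m]),
               yield = mean(diagnosed[m]))
  }))
  proto <- clades[size >= min_size & yield >= cohort_yield + margin]
  proto[, patient_idx := lapply(clade, function(i) members[[i]])]

  groups <- group_yield <- NULL
  if (!is.null(k)) {
    groups <- cutree(hc, k = k)
    group_yield <- rbindlist(lapply(seq_len(k), function(g) {
      data.table(group = g, size = sum(groups == g),
                 diagnosed = sum(diagnosed[groups == g]),
                 yield = mean(diagnosed[groups == g]))
    }))
  }
  list(hclust = hc, groups = groups, group_yield = group_yield,
       prototype_clades = proto[], cohort_yield = cohort_yield)
}
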