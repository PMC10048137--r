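# HPO-based patient stratification: ASD vs ID/GDD subsets and the 16
# phenotype categories used as predictors in the profiling model.

#' HPO codes defining the autism-behaviour set
#'
#' A patient with at least one of these codes and none of the ID/GDD codes is
#' assigned to the ASD subset.
#'
#' @return Character vector of HPO codes.
#' @export
hpo_autism_codes <- function() {
  c("HP:0000729", "HP:0000735", "HP:0000728", "HP:0008763", "HP:0000758",
    "HP:0000717", "HP:0031433", "HP:0000723", "HP:0000753")
}

#' HPO codes defining the ID/GDD set
#'
#' Any of these codes vetoes ASD membership: the patient is classified ID/GDD
#' regardless of autism codes.
#'
#' @return Character vector of HPO codes.
#' @export
hpo_id_gdd_codes <- function() {
  c("HP:0001249", "HP:0001256", "HP:0010864", "HP:0006887", "HP:0006889",
    "HP:0002187", "HP:0002342", "HP:0001263", "HP:0012758", "HP:0100543")
}

#' The 16 phenotype category labels
#'
#' @return Character vector of the 16 category names, in canonical order.
#' @export
phenotype_categories <- function() {
  c("Abnormality of metabolism/homeostasis",
    "Abnormality of prenatal development or birth",
    "Abnormality of the cardiovascular system",
    "Abnormality of the digestive system",
    "Abnormality of the ear",
    "Abnormality of the endocrine system",
    "Abnormality of the eye",
    "Abnormality of the genitourinary system",
    "Abnormality of the head",
    "Abnormality of the integument",
    "Abnormality of the musculoskeletal system",
    "Abnormality of the respiratory system",
    "Abnormal nervous system morphology",
    "Abnormal nervous system physiology",
    "Behavioral abnormality",
    "Intellectual disability")
}

#' Classify patients into ID/GDD vs ASD subsets
#'
#' ASD iff the term set contains at least one autism-behaviour code and no
#' ID/GDD code; everything else (including empty sets, with a warning) is
#' ID/GDD. Order and duplication of terms are irrelevant.
#'
#' @param hpo_terms A character vector of HPO codes (one patient) or a list
#'   of such vectors (many patients).
#' @return Character vector of `"ASD"` / `"ID_GDD"`, one per patient.
#' @export
classify_subset <- function(hpo_terms) {
  if (!is.list(hpo_terms)) hpo_terms <- list(hpo_terms)
  if (any(lengths(hpo_terms) == 0L))
    warning("patient(s) with empty HPO term set classified as ID_GDD")
  asd <- vapply(hpo_terms, function(terms) {
    any(terms %in% hpo_autism_codes()) && !any(terms %in% hpo_id_gdd_codes())
  }, logical(1))
  ifelse(asd, "ASD", "ID_GDD")
}

#' Read a category map (HPO code -> category label)
#'
#' @param path TSV with columns `code` and `category`. Defaults to the
#'   approximate map shipped with the package (hand-curated, synthetic
#'   stand-in for the published appendix assignments).
#' @return data.table with columns `code`, `category`.
#' @export
read_category_map <- function(path = system.file(
  "extdata", "hpo_category_map_synthetic.tsv", package = "nddtriage")) {
  map <- fread(path, sep = "\t", colClasses = "character")
  if (!all(c("code", "category") %in% names(map)))
    stop("category map needs 'code' and 'category' columns")
  if (anyDuplicated(map$code))
    stop("category map assigns some code to more than one category")
  bad <- setdiff(unique(map$category), phenotype_categories())
  if (length(bad))
    stop("unknown category label(s): ", paste(bad, collapse = "; "))
  map
}

#' Derive the 16 category flags from HPO terms
#'
#' A category flag is `TRUE` iff at least one of the patient's terms maps to
#' it; `n_categories` counts true flags. Unmapped codes are reported, not
#' errors.
#'
#' @param hpo_terms Character vector (one patient) or list of vectors.
#' @param category_map data.table from [read_category_map()].
#' @return List with `flags` (logical matrix, patients x 16 categories),
#'   `n_categories` (integer vector) and `unmapped` (character vector of
#'   codes seen but absent from the map).
#' @export
categorize <- function(hpo_terms, category_map = read_category_map()) {
  if (!is.list(hpo_terms)) hpo_terms <- list(hpo_terms)
  cats <- phenotype_categories()
  lookup <- setNames(category_map$category, category_map$code)
  flags <- t(vapply(hpo_terms, function(terms) {
    hit <- unique(lookup[unique(terms)])
    cats %in% hit
  }, logical(length(cats))))
  colnames(flags) <- cats
  all_terms <- unique(unlist(hpo_terms))
  list(flags = flags,
       n_categories = as.integer(rowSums(flags)),
       unmapped = setdiff(all_terms, category_map$code))
}

#' Read a patient phenotype table
#'
#' @param path TSV with columns `patient_id`, `sex` (`M`/`F`), `hpo_terms`
#'   (pipe-separated codes) and optionally `diagnosed` (0/1 or logical).
#' @return data.table with a list-column `hpo_terms`.
#' @export
read_patients <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("patient_id", "sex", "hpo_terms")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("patient table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(dt$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  dt[, hpo_terms := strsplit(as.character(hpo_terms), "|", fixed = TRUE)]
  if ("diagnosed" %in% names(dt)) dt[, diagnosed := as.logical(diagnosed)]
  dt[]
}

#' Write a patient phenotype table
#'
#' @param patients data.table as produced by [read_patients()] or
#'   [simulate_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  dt <- as.data.table(patients)
  out <- dt[, .(patient_id, sex,
                hpo_terms = vapply(hpo_terms, paste, "", collapse = "|"))]
  if ("diagnosed" %in% names(dt)) out[, diagnosed := as.integer(dt$diagnosed)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Assemble the full phenotype annotation for a cohort
#'
#' Combines subset classification and category derivation into one table.
#'
#' @param patients data.table with `patient_id`, `sex`, list-column
#'   `hpo_terms`, optional `diagnosed`.
#' @param category_map data.table from [read_category_map()].
#' @return List with `patients` (the input plus `subset`, `n_categories`),
#'   `flags` (category matrix) and `unmapped`.
#' @export
annotate_phenotypes <- function(patients,
                                category_map = read_category_map()) {
  dt <- copy(as.data.table(patients))
  dt[, subset := classify_subset(hpo_terms)]
  cz <- categorize(dt$hpo_terms, category_map)
  dt[, n_categories := cz$n_categories]
  list(patients = dt[], flags = cz$flags, unmapped = cz$unmapped)
}
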