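#' Construct a paired metastasis/primary cohort
#'
#' Bundles an expression matrix with per-sample annotation and the
#' patient-level pairing that is the backbone of the paired design: every
#' patient contributes exactly one metastasis and one primary sample.
#'
#' @param expr expression matrix (see [expression_matrix()]).
#' @param samples data.frame with columns `sample`, `patient`,
#'   `role` (`"metastasis"` or `"primary"`), and optionally `site`,
#'   `study`, `subtype`.
#' @param pairs data.frame with columns `patient`, `metastasis`, `primary`
#'   naming the two samples of each patient. If `NULL`, derived from
#'   `samples` for patients having exactly one sample of each role.
#' @return an object of class `paired_cohort`: a list with elements
#'   `expr`, `samples`, `pairs`.
#' @export
paired_cohort <- function(expr, samples, pairs = NULL) {
  .assert(is.data.frame(samples) &&
            all(c("sample", "patient", "role") %in% names(samples)),
          "samples needs columns sample, patient, role")
  .assert(all(samples$role %in% c("metastasis", "primary")),
          "role must be 'metastasis' or 'primary'")
  .assert(all(samples$sample %in% colnames(expr)),
          "annotation references samples absent from the matrix")
  if (is.null(pairs)) {
    met <- samples[samples$role == "metastasis", ]
    pri <- samples[samples$role == "primary", ]
    common <- intersect(met$patient, pri$patient)
    common <- common[!(common %in% met$patient[duplicated(met$patient)]) &
                     !(common %in% pri$patient[duplicated(pri$patient)])]
    pairs <- data.frame(
      patient = common,
      metastasis = met$sample[match(common, met$patient)],
      primary = pri$sample[match(common, pri$patient)],
      stringsAsFactors = FALSE)
  }
  .assert(!anyDuplicated(pairs$patient), "a patient appears in two pairs")
  .assert(all(pairs$metastasis %in% colnames(expr)) &&
            all(pairs$primary %in% colnames(expr)),
          "pairing references samples absent from the matrix")
  role_of <- setNames(samples$role, samples$sample)
  .assert(all(role_of[pairs$metastasis] == "metastasis") &&
            all(role_of[pairs$primary] == "primary"),
          "pairing roles disagree with annotation")
  structure(list(expr = expr, samples = samples, pairs = pairs),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("paired_cohort: %d genes, %d samples, %d pairs (%s units)\n",
              nrow(x$expr), ncol(x$expr), nrow(x$pairs),
              expr_units(x$expr)))
  invisible(x)
}

# Matrix of per-patient metastasis-minus-primary differences
# (genes x pairs), column names = patient ids.
pair_differences <- function(cohort) {
  d <- cohort$expr[, cohort$pairs$metastasis, drop = FALSE] -
       cohort$expr[, cohort$pairs$primary, drop = FALSE]
  colnames(d) <- cohort$pairs$patient
  d
}
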