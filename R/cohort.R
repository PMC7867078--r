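#' Classify breast-tumor receptor status from IHC parameters
#'
#' Applies the standard immunohistochemistry classification rules: a tumor
#' is ER- or PR-positive when at least 1% of tumor-cell nuclei stain
#' (ASCO/CAP 1% rule); PR expression is "high" at >= 20% stained nuclei;
#' the Ki67 low/high cut-off is 20%; HER2 is positive only at score 3 (3+),
#' with scores 0/1+/2+ negative (no reflex in situ hybridisation).
#' Missing percentages propagate as `NA` calls.
#'
#' @param patients `data.frame` with columns `patient_id`, `er_pct`,
#'   `pr_pct`, `ki67_pct` (percent positive nuclei, 0-100 or NA) and
#'   `her2_score` (0, 1, 2 or 3).
#' @return the input with added logical columns `er_pos`, `pr_pos`,
#'   `pr_high`, `ki67_high`, `her2_pos` and a `group` column from
#'   [assignGroup()].
#' @examples
#' classifyReceptors(data.frame(patient_id = "PT1", er_pct = 80,
#'                              pr_pct = 70, ki67_pct = 30, her2_score = 3))
#' @export
classifyReceptors <- function(patients) {
    for (col in c("er_pct", "pr_pct", "ki67_pct")) {
        v <- patients[[col]]
        if (any(v < 0 | v > 100, na.rm = TRUE))
            stop("'", col, "' outside [0, 100]")
    }
    if (any(!patients$her2_score %in% c(0L, 1L, 2L, 3L)))
        stop("'her2_score' must be 0, 1, 2 or 3")
    patients$er_pos <- patients$er_pct >= 1
    patients$pr_pos <- patients$pr_pct >= 1
    patients$pr_high <- patients$pr_pct >= 20
    patients$ki67_high <- patients$ki67_pct >= 20
    patients$her2_pos <- patients$her2_score == 3
    patients$group <- assignGroup(patients)
    patients
}

#' Assign the ER-alpha treatment-response group
#'
#' `ER_positive` iff the tumor is ER-positive; everything else —
#' triple-negative tumors as well as ER-negative tumors positive for PR
#' and/or HER2 — is `ER_negative`.
#'
#' @param status `data.frame` with a logical `er_pos` column (e.g. from
#'   [classifyReceptors()]).
#' @return character vector of `"ER_positive"` / `"ER_negative"`.
#' @export
assignGroup <- function(status) {
    ifelse(status$er_pos, "ER_positive", "ER_negative")
}

.foldCall <- function(ratio, config = quantConfig()) {
    ifelse(ratio >= config@foldUp, "up",
    ifelse(ratio <= config@foldDown, "down", "unchanged"))
}

#' Paired tumor vs normal expression ratio
#'
#' For each patient with both tissues measured under the control arm, the
#' ratio tumor / paired normal is computed and classified by the same
#' inclusive 2-fold rule used for the miRNome (`down` iff ratio <= 0.5,
#' `up` iff ratio >= 2). Patients missing either tissue are skipped with a
#' warning.
#'
#' @param measurements `data.frame` with columns `patient_id`, `tissue`
#'   (`tumor`/`normal`), `treatment` (`ctrl`/`MC3324`) and `value`
#'   (relative expression, strictly positive).
#' @param config a [quantConfig()] supplying the fold thresholds.
#' @return `data.frame` with columns `patient_id`, `tumor`, `normal`,
#'   `ratio`, `call`.
#' @export
tumorVsNormal <- function(measurements, config = quantConfig()) {
    if (any(measurements$value <= 0))
        stop("expression values must be strictly positive")
    m <- measurements[measurements$treatment == "ctrl", , drop = FALSE]
    pts <- unique(m$patient_id)
    rows <- lapply(pts, function(p) {
        tv <- m$value[m$patient_id == p & m$tissue == "tumor"]
        nv <- m$value[m$patient_id == p & m$tissue == "normal"]
        if (length(tv) != 1L || length(nv) != 1L) {
            warning("patient '", p, "' lacks a complete tumor/normal pair; ",
                    "skipped")
            return(NULL)
        }
        data.frame(patient_id = p, tumor = tv, normal = nv,
                   ratio = tv / nv, stringsAsFactors = FALSE)
    })
    out <- .rbindRows(rows)
    if (is.null(out)) stop("no complete tumor/normal pair found")
    out$call <- .foldCall(out$ratio, config)
    out
}

#' Per-(patient, tissue) treatment-response fold
#'
#' Fold = treated value / control value for every (patient, tissue) with
#' both arms measured, classified by the inclusive 2-fold rule; incomplete
#' pairs are skipped with a warning.
#'
#' @inheritParams tumorVsNormal
#' @return `data.frame` with columns `patient_id`, `tissue`, `ctrl`,
#'   `treated`, `fold`, `call`.
#' @export
treatmentResponse <- function(measurements, config = quantConfig()) {
    if (any(measurements$value <= 0))
        stop("expression values must be strictly positive")
    key <- unique(measurements[, c("patient_id", "tissue")])
    rows <- lapply(seq_len(nrow(key)), function(i) {
        sel <- measurements$patient_id == key$patient_id[i] &
               measurements$tissue == key$tissue[i]
        cv <- measurements$value[sel & measurements$treatment == "ctrl"]
        tv <- measurements$value[sel & measurements$treatment == "MC3324"]
        if (length(cv) != 1L || length(tv) != 1L) {
            warning("(", key$patient_id[i], ", ", key$tissue[i],
                    ") lacks both treatment arms; skipped")
            return(NULL)
        }
        data.frame(patient_id = key$patient_id[i], tissue = key$tissue[i],
                   ctrl = cv, treated = tv, fold = tv / cv,
                   stringsAsFactors = FALSE)
    })
    out <- .rbindRows(rows)
    if (is.null(out)) stop("no complete treatment pair found")
    out$call <- .foldCall(out$fold, config)
    out
}

#' Percent difference in treatment response between ER groups
#'
#' The group-contrast statistic is
#' \eqn{D = (\bar f_{ER+} - \bar f_{ER-}) / \bar f_{ER-} \times 100},
#' where \eqn{\bar f} is the mean treatment-response fold over the
#' patients of a group within one tissue. A `D` of 73 means a 73% larger
#' mean response in ER-alpha-positive than in ER-alpha-negative patients.
#'
#' @param folds table from [treatmentResponse()].
#' @param groups `data.frame` with columns `patient_id`, `group`
#'   (`ER_positive`/`ER_negative`).
#' @param tissue which tissue to contrast (`"tumor"` or `"normal"`).
#' @return one-row `data.frame` with columns `tissue`, `mean_fold_pos`,
#'   `mean_fold_neg`, `n_pos`, `n_neg`, `percent_difference`.
#' @export
groupResponseContrast <- function(folds, groups, tissue) {
    f <- folds[folds$tissue == tissue, , drop = FALSE]
    f$group <- groups$group[match(f$patient_id, groups$patient_id)]
    pos <- f$fold[f$group == "ER_positive"]
    neg <- f$fold[f$group == "ER_negative"]
    if (!length(pos)) stop("group 'ER_positive' is empty for tissue ", tissue)
    if (!length(neg)) stop("group 'ER_negative' is empty for tissue ", tissue)
    data.frame(tissue = tissue,
               mean_fold_pos = mean(pos), mean_fold_neg = mean(neg),
               n_pos = length(pos), n_neg = length(neg),
               percent_difference = (mean(pos) - mean(neg)) / mean(neg) * 100,
               stringsAsFactors = FALSE)
}
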