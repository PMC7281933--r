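#' Regional medians and clinical associations
#'
#' After group inference localizes where the IVIM parameters differ, the
#' median parameter value inside that region is extracted per subject and
#' regressed against clinical covariates (cognitive domain Z-scores, disease
#' activity). The region must be fixed by the inference stage before the
#' covariates are seen; the pipeline enforces that ordering.
#'
#' @name association
NULL

#' Median parameter value within a region
#'
#' @param map 3D parameter map (NA outside the validity mask).
#' @param mask Logical region mask.
#' @return Median of the finite masked voxel values (even counts average the
#'   central pair, the usual sample-median convention).
#' @export
regional_median <- function(map, mask) {
  stopifnot(identical(dim(map), dim(mask)))
  vals <- map[mask & is.finite(map)]
  if (length(vals) == 0) stop("empty effective region after masking")
  median(vals)
}

#' Correlate per-subject regional values with a covariate
#'
#' Pearson correlation (Spearman optional) with the two-sided p value from
#' the t transform on n - 2 degrees of freedom, plus the least-squares
#' regression line. Incomplete pairs are dropped pairwise; the count of
#' dropped subjects is recorded on the result.
#'
#' @param values Per-subject regional scalars.
#' @param covariate Per-subject covariate values (same order).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row data.frame: `n`, `r`, `p`, `slope`, `intercept`,
#'   `n_dropped`.
#' @export
correlate_region <- function(values, covariate,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(values) == length(covariate))
  ok <- is.finite(values) & is.finite(covariate)
  n_dropped <- sum(!ok)
  x <- values[ok]; y <- covariate[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance: correlation undefined")
  r <- cor(x, y, method = method)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  slope <- cov(x, y) / var(x)
  data.frame(n = n, r = r, p = p, slope = slope,
             intercept = mean(y) - slope * mean(x), n_dropped = n_dropped)
}

#' Run the full parameter-by-covariate association battery
#'
#' For every requested IVIM parameter, the per-subject regional median inside
#' `region_mask` is correlated with every requested covariate. Unadjusted
#' p values are primary (flagged at p < 0.05 and at trending p < 0.1); a
#' Benjamini-Hochberg adjusted column is always emitted alongside.
#'
#' @param subject_maps Named list (by subject_id) of `ivim_maps` (or plain
#'   lists of parameter arrays).
#' @param region_mask Logical 3D region mask, fixed upstream.
#' @param cohort Cohort data.frame with `subject_id`, `group` and covariate
#'   columns.
#' @param parameters Character vector of parameter names (default the four
#'   IVIM maps).
#' @param covariates Character vector of covariate column names.
#' @param group Restrict to one group label (default `"patient"`, the
#'   within-patient design); NULL uses all subjects.
#' @param method Correlation method, see [correlate_region()].
#' @return data.frame with one row per parameter x covariate: `parameter`,
#'   `covariate`, `n`, `r`, `p`, `p_bh`, `slope`, `intercept`,
#'   `significant` (p < 0.05), `trending` (p < 0.1).
#' @export
run_association_battery <- function(subject_maps, region_mask, cohort,
                                    parameters = c("v_bw", "D", "D_star",
                                                   "flow"),
                                    covariates, group = "patient",
                                    method = "pearson") {
  stopifnot(all(c("subject_id", "group") %in% names(cohort)))
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov))
    stop("covariate(s) absent from cohort table: ",
         paste(missing_cov, collapse = ", "))
  tab <- if (is.null(group)) cohort else cohort[cohort$group == group, ]
  ids <- tab$subject_id
  if (!all(ids %in% names(subject_maps)))
    stop("maps missing for subject(s): ",
         paste(setdiff(ids, names(subject_maps)), collapse = ", "))
  med <- sapply(parameters, function(par)
    vapply(ids, function(id)
      regional_median(subject_maps[[id]][[par]], region_mask), numeric(1)))
  rows <- list()
  for (par in parameters) for (cv in covariates) {
    y <- tab[[cv]]
    if (all(!is.finite(y))) stop("covariate '", cv, "' has no finite values")
    res <- correlate_region(med[, par], y, method = method)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(parameter = par, covariate = cv,
                       stringsAsFactors = FALSE), res)
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < 0.05
  out$trending <- out$p < 0.1
  rownames(out) <- NULL
  out[, c("parameter", "covariate", "n", "r", "p", "p_bh", "slope",
          "intercept", "significant", "trending", "n_dropped")]
}
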