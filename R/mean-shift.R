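#' Rank-based inverse normal transform
#'
#' Blom-offset rankit transform `qnorm((rank - 3/8) / (n + 1/4))`, with
#' average ranks for ties, optionally within strata (e.g. per sex). Any
#' strictly monotone transformation of the input leaves the result
#' unchanged, which is the property that makes mean shifts comparable
#' across cohorts measured on different raw scales.
#'
#' @param y Numeric vector.
#' @param strata Optional factor of the same length; transform is applied
#'   within each stratum.
#' @return Transformed vector.
#' @export
inverse_normal_transform <- function(y, strata = NULL) {
  one <- function(v) {
    out <- rep(NA_real_, length(v))
    ok <- is.finite(v)
    r <- rank(v[ok], ties.method = "average")
    out[ok] <- qnorm((r - 0.375) / (sum(ok) + 0.25))
    out
  }
  if (is.null(strata)) return(one(y))
  if (length(strata) != length(y)) stop("`strata` length mismatch.")
  out <- rep(NA_real_, length(y))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    out[idx] <- one(y[idx])
  }
  out
}

#' Standardized mean shift between a selected sample and a reference cohort
#'
#' Computes `delta_hat = (mean_sample - mean_reference) / sd_sample`, the
#' observed analogue of the model mean shift, after an optional pooled
#' rank-based inverse normal transform and covariate residualization.
#'
#' Processing order mirrors common biobank practice: (1) the INT, when
#' requested, is computed on the *pooled* cohorts (optionally within
#' strata) so that a cohort-level location difference survives the
#' transform; (2) covariate slopes are estimated on the pooled data with a
#' cohort fixed effect — so that the cohort-level shift is not absorbed
#' into the slopes when covariate composition differs between cohorts —
#' and only the covariate part is subtracted from the phenotype; (3) the
#' difference in cohort means of the residuals is standardized by the
#' sample-cohort residual SD.
#'
#' @param sample_y Phenotype values in the selected sample (participants).
#' @param reference_y Phenotype values in the population-representative
#'   reference cohort.
#' @param sample_covariates,reference_covariates Optional numeric matrices
#'   (or data.frames) of covariates, same column layout in both cohorts.
#' @param inverse_normal Apply the pooled rank-based INT first?
#'   Default `TRUE`.
#' @param sample_strata,reference_strata Optional strata for the INT.
#' @return The standardized mean shift `delta_hat`, with attribute `"n"`
#'   giving the two cohort sizes.
#' @export
compute_mean_shift <- function(sample_y, reference_y,
                               sample_covariates = NULL,
                               reference_covariates = NULL,
                               inverse_normal = TRUE,
                               sample_strata = NULL,
                               reference_strata = NULL) {
  sample_y <- as.numeric(sample_y); reference_y <- as.numeric(reference_y)
  ns <- length(sample_y); nr <- length(reference_y)
  if (ns == 0 || nr == 0) stop("both cohorts must be nonempty.")
  has_cov <- !is.null(sample_covariates)
  if (has_cov != !is.null(reference_covariates))
    stop("supply covariates for both cohorts or neither.")

  y <- c(sample_y, reference_y)
  grp <- rep(c("sample", "reference"), c(ns, nr))
  if (inverse_normal) {
    strata <- if (is.null(sample_strata)) NULL else {
      if (is.null(reference_strata))
        stop("supply strata for both cohorts or neither.")
      c(as.character(sample_strata), as.character(reference_strata))
    }
    y <- inverse_normal_transform(y, strata)
  }
  if (has_cov) {
    C <- rbind(as.matrix(sample_covariates), as.matrix(reference_covariates))
    if (nrow(C) != length(y)) stop("covariate rows do not match phenotypes.")
    X <- cbind(1, grp == "sample", C)
    q <- qr(X)
    if (q$rank < ncol(X)) stop("covariate design matrix is rank deficient.")
    beta <- qr.coef(q, y)
    y <- y - C %*% beta[-(1:2)]      # remove the covariate part only
  }
  ys <- y[grp == "sample"]; yr <- y[grp == "reference"]
  sds <- sd(ys)
  if (!is.finite(sds) || sds == 0)
    stop("sample-cohort SD is zero: mean shift undefined.")
  structure((mean(ys) - mean(yr)) / sds, n = c(sample = ns, reference = nr))
}
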