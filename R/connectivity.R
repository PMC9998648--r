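#' Pearson functional-connectivity matrix with per-link p-values
#'
#' Correlates every pair of ROI time series. The returned weighted matrix
#' is the raw (unmasked) Pearson correlation with zero diagonal; the
#' p-value matrix holds two-sided p-values from
#' \eqn{t = r \sqrt{(T-2)/(1-r^2)}} on \eqn{T - 2} degrees of freedom,
#' with 1 on the diagonal.
#'
#' @param ts T x N numeric matrix of ROI time series with ROI column names
#'   (as from [read_roi_timeseries()]).
#' @return List with \code{r} (N x N weighted matrix) and \code{p}
#'   (N x N p-value matrix), both labelled.
#' @export
compute_fc_matrix <- function(ts) {
  stopifnot(is.matrix(ts), is.numeric(ts))
  if (is.null(colnames(ts))) stop("time-series matrix must have ROI names")
  t_len <- nrow(ts)
  if (t_len < 4L) stop("need T >= 4 timepoints (df = T - 2 >= 2)")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0))
    stop("constant-valued ROI time series (correlation undefined): ",
         paste(colnames(ts)[sds == 0], collapse = ", "))
  r <- stats::cor(ts)
  df <- t_len - 2
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  diag(r) <- 0
  diag(p) <- 1
  p[p > 1] <- 1
  list(r = r, p = p)
}

#' Zero out non-significant correlations
#'
#' Keeps each link weight (positive or negative) unchanged when its p-value
#' is below \code{alpha} and sets it to exactly 0 otherwise. No
#' multiple-comparison correction is applied at this stage.
#'
#' @param r Unmasked weighted FC matrix.
#' @param p Matching p-value matrix.
#' @param alpha Significance level, strictly inside (0, 1).
#' @return Masked weighted FC matrix.
#' @export
significance_mask <- function(r, p, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)")
  if (!identical(dim(r), dim(p)))
    stop("correlation and p-value matrices must have matching shapes")
  r[p >= alpha] <- 0
  diag(r) <- 0
  r
}

#' Binarize a masked FC matrix at a positive threshold
#'
#' An edge is present iff the masked weight strictly exceeds \code{tau};
#' negative and sub-threshold weights give 0. The threshold is defined as
#' positive, so \code{tau <= 0} is an error.
#'
#' @param w Masked weighted FC matrix.
#' @param tau Positive threshold (default 0.5).
#' @return Binary 0/1 matrix with zero diagonal and the same labels.
#' @export
binarize <- function(w, tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0)
    stop("binarization threshold tau must be a positive number")
  b <- (w > tau) * 1
  diag(b) <- 0
  b
}
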