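#' Linear partial correlation
#'
#' Pearson correlation between the residuals of \code{x} and \code{y} after
#' ordinary-least-squares regression on an intercept plus the covariate
#' columns. Constant covariate columns (e.g. sex in a single-sex subset)
#' are dropped with a warning rather than causing a rank failure; any other
#' rank deficiency is an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Numeric matrix (or NULL for the plain Pearson
#'   correlation), one row per observation.
#' @return List with \code{r} (the partial correlation) and \code{k} (the
#'   number of covariate columns actually used).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (is.null(covariates)) covariates <- matrix(numeric(0), n, 0)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n) stop("covariate rows must match observations")
  keep <- apply(covariates, 2, function(col) stats::sd(col) > 0)
  if (any(!keep)) {
    warning("dropping constant covariate column(s): ",
            paste(if (is.null(colnames(covariates))) which(!keep)
                  else colnames(covariates)[!keep], collapse = ", "))
    covariates <- covariates[, keep, drop = FALSE]
  }
  design <- cbind(1, covariates)
  if (qr(design)$rank < ncol(design))
    stop("covariate matrix is rank-deficient after adding the intercept")
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  list(r = stats::cor(rx, ry), k = ncol(covariates))
}

#' Fisher r-to-z transform
#' @param r Correlation(s), strictly inside (-1, 1).
#' @return \code{atanh(r)}.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' Zygosity-specific intra-pair partial correlations
#'
#' For each feature column, correlates Twin 1 against Twin 2 values
#' separately within MZ and within DZ pairs, partialling out the pair-level
#' covariates age and sex (numeric-coded, F = 0 / M = 1). With
#' \code{double_entry = TRUE} each pair contributes both orderings
#' (Twin1, Twin2) and (Twin2, Twin1), removing the arbitrary within-pair
#' ordering; the reported pair counts stay at the number of distinct pairs.
#'
#' @param features Subject-by-feature numeric matrix with subject ids as
#'   row names (e.g. from [extract_feature_table()] or
#'   [simulate_feature_cohort()]).
#' @param manifest A \code{twin_manifest}.
#' @param double_entry Logical; default FALSE (single entry, manifest
#'   ordering).
#' @return Data frame with one row per feature: \code{feature_id},
#'   \code{rMZ}, \code{rDZ}, \code{nMZ}, \code{nDZ}, \code{kMZ},
#'   \code{kDZ} (covariates used per group).
#' @export
zygosity_correlations <- function(features, manifest, double_entry = FALSE) {
  manifest <- validate_manifest(as.data.frame(manifest))
  miss <- setdiff(c(manifest$twin1_id, manifest$twin2_id), rownames(features))
  if (length(miss))
    stop("manifest subject(s) missing from feature table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  groups <- split(manifest, manifest$zygosity)
  for (z in c("MZ", "DZ")) {
    if (is.null(groups[[z]]))
      stop("no ", z, " pairs in manifest")
  }
  one_group <- function(g) {
    x <- features[g$twin1_id, , drop = FALSE]
    y <- features[g$twin2_id, , drop = FALSE]
    cov <- cbind(age = g$age, sex = as.numeric(g$sex == "M"))
    if (double_entry) {
      xy <- rbind(x, y); y <- rbind(y, x); x <- xy
      cov <- rbind(cov, cov)
    }
    keep <- apply(cov, 2, function(col) stats::sd(col) > 0)
    if (any(!keep))
      warning("dropping constant covariate(s) in ",
              g$zygosity[1], " group: ",
              paste(colnames(cov)[!keep], collapse = ", "))
    cov <- cov[, keep, drop = FALSE]
    k <- ncol(cov)
    if (nrow(g) < k + 4)
      stop("fewer than k + 4 = ", k + 4, " ", g$zygosity[1],
           " pairs; Fisher variance undefined")
    design <- cbind(1, cov)
    rx <- as.matrix(stats::lm.fit(design, x)$residuals)
    ry <- as.matrix(stats::lm.fit(design, y)$residuals)
    r <- colSums(rx * ry) /
      sqrt(colSums(rx^2) * colSums(ry^2))
    list(r = r, n = nrow(g), k = k)
  }
  mz <- one_group(groups$MZ)
  dz <- one_group(groups$DZ)
  data.frame(feature_id = colnames(features),
             rMZ = unname(mz$r), rDZ = unname(dz$r),
             nMZ = mz$n, nDZ = dz$n, kMZ = mz$k, kDZ = dz$k,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-sided Fisher-Z comparison of two correlations
#'
#' Tests rMZ > rDZ via
#' \deqn{Z = \frac{\mathrm{atanh}(r_{MZ}) - \mathrm{atanh}(r_{DZ})}
#'   {\sqrt{1/(n_{MZ}-3-k) + 1/(n_{DZ}-3-k)}}}
#' with \code{k} covariates partialled out of each correlation, and the
#' one-sided upper-tail standard-normal p-value.
#'
#' @param r_mz,r_dz Correlations, |r| < 1.
#' @param n_mz,n_dz Pair counts per zygosity group.
#' @param k Number of covariates (default 2: age, sex). May be a length-2
#'   vector giving (kMZ, kDZ).
#' @return List with \code{Z} and \code{p}.
#' @export
compare_correlations <- function(r_mz, r_dz, n_mz, n_dz, k = 2) {
  k <- rep(k, length.out = 2)
  v1 <- n_mz - 3 - k[1]
  v2 <- n_dz - 3 - k[2]
  if (any(v1 <= 0) || any(v2 <= 0))
    stop("need n - 3 - k > 0 in both zygosity groups")
  z <- (fisher_z(r_mz) - fisher_z(r_dz)) / sqrt(1 / v1 + 1 / v2)
  list(Z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Scenario gating from the rMZ/rDZ ratio
#'
#' Classifies a feature by the relation between its zygosity-specific
#' correlations: \code{EPISTASIS} when \eqn{r_{MZ} > 4 r_{DZ} > 0} (the
#' classical linear designs cannot model it), \code{ADE} when
#' \eqn{0 < 2 r_{DZ} < r_{MZ} \le 4 r_{DZ}}, \code{ACE} when
#' \eqn{0 < r_{DZ} < r_{MZ} \le 2 r_{DZ}}, and \code{UNMODELED} otherwise
#' (covers \eqn{r_{MZ} \le 0}, \eqn{r_{DZ} \le 0} and
#' \eqn{r_{MZ} \le r_{DZ}}). The boundaries \eqn{r_{MZ} = 2 r_{DZ}} and
#' \eqn{r_{MZ} = 4 r_{DZ}} go to ACE (C = 0) and ADE (A = 0) respectively,
#' which keeps the component estimates continuous across them.
#'
#' @param r_mz,r_dz Finite correlations (vectorised).
#' @return Character vector of labels.
#' @export
classify_scenario <- function(r_mz, r_dz) {
  stopifnot(length(r_mz) == length(r_dz))
  out <- rep("UNMODELED", length(r_mz))
  admissible <- is.finite(r_mz) & is.finite(r_dz) & r_dz > 0 & r_mz > r_dz
  out[admissible & r_mz > 4 * r_dz] <- "EPISTASIS"
  out[admissible & r_mz <= 4 * r_dz & r_mz > 2 * r_dz] <- "ADE"
  out[admissible & r_mz <= 2 * r_dz] <- "ACE"
  out
}

#' Falconer ADE decomposition
#'
#' For features gated ADE: \eqn{A = 4 r_{DZ} - r_{MZ}},
#' \eqn{D = 2 r_{MZ} - 4 r_{DZ}}, \eqn{E = 1 - r_{MZ}}; broad-sense
#' heritability \eqn{H^2 = A + D = r_{MZ}}. Components are proportions of
#' phenotypic variance and sum to 1 by construction.
#'
#' @param r_mz,r_dz Correlations satisfying the ADE gating condition.
#' @return List with \code{model = "ADE"}, \code{A}, \code{D}, \code{E},
#'   \code{H2}.
#' @export
ade_decompose <- function(r_mz, r_dz) {
  if (any(classify_scenario(r_mz, r_dz) != "ADE"))
    stop("inputs do not satisfy the ADE condition 0 < 2 rDZ < rMZ <= 4 rDZ")
  list(model = "ADE", A = 4 * r_dz - r_mz, D = 2 * r_mz - 4 * r_dz,
       E = 1 - r_mz, H2 = r_mz)
}

#' Falconer ACE decomposition
#'
#' For features gated ACE: \eqn{A = 2 (r_{MZ} - r_{DZ})},
#' \eqn{C = 2 r_{DZ} - r_{MZ}}, \eqn{E = 1 - r_{MZ}}; narrow-sense
#' heritability \eqn{h^2 = A}.
#'
#' @param r_mz,r_dz Correlations satisfying the ACE gating condition.
#' @return List with \code{model = "ACE"}, \code{A}, \code{C}, \code{E},
#'   \code{h2}.
#' @export
ace_decompose <- function(r_mz, r_dz) {
  if (any(classify_scenario(r_mz, r_dz) != "ACE"))
    stop("inputs do not satisfy the ACE condition 0 < rDZ < rMZ <= 2 rDZ")
  list(model = "ACE", A = 2 * (r_mz - r_dz), C = 2 * r_dz - r_mz,
       E = 1 - r_mz, h2 = 2 * (r_mz - r_dz))
}

#' Bonferroni adjustment with an explicit family size
#'
#' @param p Vector of p-values.
#' @param n_condition Family size (number of comparisons in the condition);
#'   must be at least \code{length(p)} and at least 1.
#' @return Data frame with \code{p}, \code{p_bonferroni}
#'   (\code{min(1, n_condition * p)}), \code{significant_unc} and
#'   \code{significant_bonf} flags at 0.05.
#' @export
bonferroni_adjust <- function(p, n_condition) {
  if (!is.numeric(n_condition) || n_condition < 1)
    stop("n_condition must be >= 1")
  if (n_condition < length(p))
    stop("family size smaller than the number of p-values")
  p_adj <- pmin(1, n_condition * p)
  data.frame(p = p, p_bonferroni = p_adj,
             significant_unc = p < 0.05,
             significant_bonf = p_adj < 0.05)
}
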