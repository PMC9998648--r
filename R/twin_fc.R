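#' Fit the twin genetic/environmental decomposition to a feature table
#'
#' The central fitting function of the package. For every feature column it
#' (1) estimates zygosity-specific intra-pair partial correlations adjusted
#' for age and sex, (2) gates the feature into an EPISTASIS / ADE / ACE /
#' UNMODELED scenario from the rMZ/rDZ ratio, (3) computes the Falconer
#' variance decomposition and heritability where a linear model applies,
#' and (4) tests rMZ > rDZ with a one-sided Fisher-Z comparison, Bonferroni
#' corrected within families defined by (spatial scale x scenario).
#'
#' Feature scale is inferred from the column-name prefixes used by
#' [extract_feature_table()] (\code{link:}, \code{node:}, \code{net:});
#' any other name is treated as scale \code{"feature"}.
#'
#' @param features Subject-by-feature numeric matrix with subject ids as
#'   row names.
#' @param manifest A \code{twin_manifest} covering every subject.
#' @param alpha Significance level for the Fisher comparison flags
#'   (default 0.05).
#' @param require_significant_r If TRUE, features whose rMZ or rDZ is not
#'   individually significantly positive (one-sided t test at
#'   \code{alpha}, df = n - 2 - k) are set to UNMODELED before gating.
#'   Default FALSE.
#' @param double_entry Passed to [zygosity_correlations()].
#' @return An object of class \code{twin_fc}: a list with components
#'   \code{results} (one data-frame row per feature: correlations,
#'   scenario, A/C/D/E, H2, h2, Z, p, p_bonferroni, significance flags),
#'   \code{n_mz}, \code{n_dz}, \code{alpha}, \code{call}.
#' @seealso [summary.twin_fc()], [coef.twin_fc()], [write_results_table()]
#' @export
#' @examples
#' sim <- simulate_feature_cohort(variance_components(a2 = 0.5, e2 = 0.5),
#'                                n_mz = 30, n_dz = 40, n_features = 5,
#'                                seed = 2)
#' fit <- twin_fc(sim$features, sim$manifest)
#' summary(fit)
twin_fc <- function(features, manifest, alpha = 0.05,
                    require_significant_r = FALSE, double_entry = FALSE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)")
  zc <- zygosity_correlations(features, manifest,
                              double_entry = double_entry)
  scale <- feature_scale(zc$feature_id)
  scenario <- classify_scenario(zc$rMZ, zc$rDZ)

  if (require_significant_r) {
    sig_pos <- function(r, n, k) {
      ok <- is.finite(r) & abs(r) < 1
      p <- rep(NA_real_, length(r))
      df <- n - 2 - k
      tt <- r[ok] * sqrt(df / (1 - r[ok]^2))
      p[ok] <- stats::pt(tt, df, lower.tail = FALSE)
      !is.na(p) & p < alpha
    }
    keep <- sig_pos(zc$rMZ, zc$nMZ, zc$kMZ) &
      sig_pos(zc$rDZ, zc$nDZ, zc$kDZ)
    scenario[!keep] <- "UNMODELED"
  }

  n_feat <- nrow(zc)
  A <- C <- D <- E <- H2 <- h2 <- rep(NA_real_, n_feat)
  i_ade <- scenario == "ADE"
  if (any(i_ade)) {
    d <- ade_decompose(zc$rMZ[i_ade], zc$rDZ[i_ade])
    A[i_ade] <- d$A; D[i_ade] <- d$D; E[i_ade] <- d$E; H2[i_ade] <- d$H2
  }
  i_ace <- scenario == "ACE"
  if (any(i_ace)) {
    d <- ace_decompose(zc$rMZ[i_ace], zc$rDZ[i_ace])
    A[i_ace] <- d$A; C[i_ace] <- d$C; E[i_ace] <- d$E; h2[i_ace] <- d$h2
  }

  Z <- p <- rep(NA_real_, n_feat)
  testable <- is.finite(zc$rMZ) & is.finite(zc$rDZ) &
    abs(zc$rMZ) < 1 & abs(zc$rDZ) < 1
  if (any(testable)) {
    fc <- compare_correlations(zc$rMZ[testable], zc$rDZ[testable],
                               zc$nMZ[testable], zc$nDZ[testable],
                               k = c(zc$kMZ[1], zc$kDZ[1]))
    Z[testable] <- fc$Z
    p[testable] <- fc$p
  }

  # Bonferroni family: comparisons within the same (scale, scenario) cell
  p_bonf <- rep(NA_real_, n_feat)
  fam <- interaction(scale, scenario, drop = TRUE)
  for (f in levels(fam)) {
    idx <- which(fam == f & !is.na(p))
    if (length(idx))
      p_bonf[idx] <- pmin(1, length(idx) * p[idx])
  }

  results <- data.frame(
    feature_id = zc$feature_id, scale = scale,
    rMZ = zc$rMZ, rDZ = zc$rDZ, scenario = scenario,
    A = A, C = C, D = D, E = E, H2 = H2, h2 = h2,
    Z = Z, p = p, p_bonferroni = p_bonf,
    significant_unc = !is.na(p) & p < alpha,
    significant_bonf = !is.na(p_bonf) & p_bonf < alpha,
    stringsAsFactors = FALSE
  )
  structure(list(results = results, n_mz = zc$nMZ[1], n_dz = zc$nDZ[1],
                 k = c(MZ = zc$kMZ[1], DZ = zc$kDZ[1]), alpha = alpha,
                 require_significant_r = require_significant_r,
                 double_entry = double_entry, call = match.call()),
            class = "twin_fc")
}

feature_scale <- function(feature_id) {
  scale <- rep("feature", length(feature_id))
  scale[startsWith(feature_id, "link:")] <- "link"
  scale[startsWith(feature_id, "node:")] <- "node"
  scale[startsWith(feature_id, "net:")] <- "network"
  scale
}

#' @export
print.twin_fc <- function(x, ...) {
  cat("Twin genetic/environmental decomposition\n")
  cat("  ", nrow(x$results), " features; ", x$n_mz, " MZ and ", x$n_dz,
      " DZ pairs; covariates partialled out: ", x$k[1], " (MZ) / ",
      x$k[2], " (DZ)\n", sep = "")
  tab <- table(factor(x$results$scenario,
                      c("EPISTASIS", "ADE", "ACE", "UNMODELED")))
  cat("  scenarios:",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a twin decomposition fit
#'
#' @param object A \code{twin_fc} fit.
#' @param ... Unused.
#' @return A list of class \code{summary.twin_fc} with the scenario-by-scale
#'   count table, mean variance components per modelled scenario, mean
#'   heritability estimates, and counts of significant Fisher comparisons.
#' @export
summary.twin_fc <- function(object, ...) {
  r <- object$results
  scen <- factor(r$scenario, c("EPISTASIS", "ADE", "ACE", "UNMODELED"))
  out <- list(
    counts = table(scale = r$scale, scenario = scen),
    mean_ade = if (any(r$scenario == "ADE"))
      colMeans(r[r$scenario == "ADE", c("A", "D", "E", "H2")]) else NULL,
    mean_ace = if (any(r$scenario == "ACE"))
      colMeans(r[r$scenario == "ACE", c("A", "C", "E", "h2")]) else NULL,
    n_sig_unc = sum(r$significant_unc),
    n_sig_bonf = sum(r$significant_bonf),
    alpha = object$alpha,
    n_mz = object$n_mz, n_dz = object$n_dz
  )
  class(out) <- "summary.twin_fc"
  out
}

#' @export
print.summary.twin_fc <- function(x, ...) {
  cat("Scenario counts by spatial scale:\n")
  print(x$counts)
  if (!is.null(x$mean_ade)) {
    cat("\nMean ADE components (proportion of variance):\n")
    print(round(x$mean_ade, 4))
  }
  if (!is.null(x$mean_ace)) {
    cat("\nMean ACE components (proportion of variance):\n")
    print(round(x$mean_ace, 4))
  }
  cat("\nFisher rMZ > rDZ comparisons significant at alpha = ", x$alpha,
      ": ", x$n_sig_unc, " uncorrected, ", x$n_sig_bonf,
      " after Bonferroni\n", sep = "")
  invisible(x)
}

#' Extract variance-component estimates
#'
#' @param object A \code{twin_fc} fit.
#' @param ... Unused.
#' @return Numeric matrix (features x A, C, D, E, H2, h2) with NA where a
#'   component does not belong to the feature's scenario.
#' @export
coef.twin_fc <- function(object, ...) {
  m <- as.matrix(object$results[, c("A", "C", "D", "E", "H2", "h2")])
  rownames(m) <- object$results$feature_id
  m
}

#' @export
as.data.frame.twin_fc <- function(x, ...) x$results

#' Plot scenario composition of a twin decomposition fit
#'
#' Stacked-bar summary of scenario proportions per spatial scale.
#'
#' @param x A \code{twin_fc} fit.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the proportion matrix plotted.
#' @export
plot.twin_fc <- function(x, ...) {
  scen <- factor(x$results$scenario,
                 c("EPISTASIS", "ADE", "ACE", "UNMODELED"))
  tab <- table(scen, x$results$scale)
  prop <- prop.table(tab, margin = 2)
  graphics::barplot(prop, legend.text = rownames(prop),
                    ylab = "proportion of features",
                    xlab = "spatial scale", ...)
  invisible(prop)
}
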