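#' Specify twin variance components
#'
#' A variance-components specification gives the proportions of phenotypic
#' variance attributed to additive genetics (\code{a2}), shared environment
#' (\code{c2}), dominance/nonadditive genetics (\code{d2}) and unique
#' environment (\code{e2}). Proportions must be non-negative and sum to 1.
#' Under the standard biometrical assumptions (additive genetic correlation
#' 1 in MZ / 0.5 in DZ pairs, dominance 1 / 0.25, shared environment 1 in
#' both) the implied intra-pair correlations are
#' \code{rMZ = a2 + d2 + c2} and \code{rDZ = a2/2 + d2/4 + c2}.
#'
#' @param a2,c2,d2,e2 Variance proportions.
#' @param classical If \code{TRUE} (default), require at most one of
#'   \code{c2}, \code{d2} to be nonzero, matching the identifiability of the
#'   classical ACE/ADE designs.
#' @return An object of class \code{variance_components} (named list with
#'   the four proportions).
#' @export
#' @examples
#' variance_components(a2 = 0.4, c2 = 0.2, e2 = 0.4)
variance_components <- function(a2 = 0, c2 = 0, d2 = 0, e2 = 0,
                                classical = TRUE) {
  v <- c(a2 = a2, c2 = c2, d2 = d2, e2 = e2)
  if (any(!is.finite(v)) || any(v < 0))
    stop("variance components must be finite and >= 0")
  if (abs(sum(v) - 1) > 1e-12)
    stop("variance components must sum to 1 (got ", format(sum(v)), ")")
  if (classical && c2 > 0 && d2 > 0)
    stop("classical twin designs cannot carry both c2 and d2; ",
         "set classical = FALSE to simulate anyway")
  structure(as.list(v), class = "variance_components")
}

#' @rdname variance_components
#' @param spec A \code{variance_components} object.
#' @return \code{implied_twin_correlations}: named vector \code{c(rMZ, rDZ)}.
#' @export
implied_twin_correlations <- function(spec) {
  stopifnot(inherits(spec, "variance_components"))
  c(rMZ = spec$a2 + spec$d2 + spec$c2,
    rDZ = spec$a2 / 2 + spec$d2 / 4 + spec$c2)
}

# Derive a reproducible sub-seed for an independent stream; keeps values
# inside the 32-bit integer range R requires.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}

# Draw a synthetic same-sex pair manifest: ages uniform on age_range shared
# within pair, pair sex Bernoulli(1/2).
draw_manifest <- function(n_mz, n_dz, age_range, seed) {
  n <- n_mz + n_dz
  set.seed(sub_seed(seed, 1L))
  data.frame(
    pair_id = sprintf("pair%03d", seq_len(n)),
    zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)),
    twin1_id = sprintf("subj%03dA", seq_len(n)),
    twin2_id = sprintf("subj%03dB", seq_len(n)),
    age = stats::runif(n, age_range[1], age_range[2]),
    sex = ifelse(stats::runif(n) < 0.5, "F", "M"),
    stringsAsFactors = FALSE
  )
}

# Correlated standard-normal pair draws: returns list(t1, t2), each
# n_pairs x n_features, with within-pair correlation rho.
paired_normals <- function(n_pairs, n_features, rho) {
  z1 <- matrix(stats::rnorm(n_pairs * n_features), n_pairs)
  z2 <- matrix(stats::rnorm(n_pairs * n_features), n_pairs)
  list(t1 = z1, t2 = rho * z1 + sqrt(1 - rho^2) * z2)
}

#' Simulate feature-level twin cohorts with known variance structure
#'
#' Generates a same-sex twin cohort and per-subject feature values from the
#' biometrical model
#' \deqn{y = \sqrt{a^2} A + \sqrt{c^2} C + \sqrt{d^2} D + \sqrt{e^2} E
#'   + \beta_{age} \cdot age + \beta_{sex} \cdot sex,}
#' where the standard-normal latent factors are correlated within a pair at
#' 1 (MZ) / 0.5 (DZ) for A, 1 / 0.25 for D, 1 for C in both zygosities and
#' 0 for E. Ages are uniform on \code{age_range} and shared within pair;
#' pair sex is Bernoulli(1/2) (coded 0 = F, 1 = M for the covariate effect).
#'
#' @param spec A [variance_components()] specification.
#' @param n_mz,n_dz Numbers of MZ and DZ pairs (each >= 2).
#' @param n_features Number of independent features to draw from the same
#'   specification.
#' @param beta_age,beta_sex Additive covariate effects on the feature scale.
#' @param age_range Length-2 numeric, years.
#' @param seed Integer; fixes all randomness.
#' @return List with \code{manifest} (a \code{twin_manifest}) and
#'   \code{features}, a (2 * (n_mz + n_dz)) x n_features matrix with subject
#'   ids as row names and columns \code{f1, f2, ...}.
#' @export
#' @examples
#' sim <- simulate_feature_cohort(variance_components(a2 = 0.6, e2 = 0.4),
#'                                n_mz = 18, n_dz = 25, seed = 1)
#' dim(sim$features)
simulate_feature_cohort <- function(spec, n_mz, n_dz, n_features = 1L,
                                    beta_age = 0, beta_sex = 0,
                                    age_range = c(10, 30), seed = 1L) {
  stopifnot(inherits(spec, "variance_components"))
  if (n_mz < 2L || n_dz < 2L)
    stop("need at least 2 pairs per zygosity group")
  manifest <- draw_manifest(n_mz, n_dz, age_range, seed)
  n <- n_mz + n_dz
  is_mz <- manifest$zygosity == "MZ"

  set.seed(sub_seed(seed, 2L))
  y1 <- matrix(0, n, n_features)
  y2 <- matrix(0, n, n_features)
  add_factor <- function(weight, rho_mz, rho_dz) {
    if (weight <= 0) return(invisible(NULL))
    for (grp in list(which(is_mz), which(!is_mz))) {
      rho <- if (identical(grp, which(is_mz))) rho_mz else rho_dz
      z <- paired_normals(length(grp), n_features, rho)
      y1[grp, ] <<- y1[grp, ] + sqrt(weight) * z$t1
      y2[grp, ] <<- y2[grp, ] + sqrt(weight) * z$t2
    }
  }
  add_factor(spec$a2, 1, 0.5)
  add_factor(spec$c2, 1, 1)
  add_factor(spec$d2, 1, 0.25)
  add_factor(spec$e2, 0, 0)

  cov_shift <- beta_age * manifest$age + beta_sex * (manifest$sex == "M")
  y1 <- y1 + cov_shift
  y2 <- y2 + cov_shift

  features <- rbind(y1, y2)
  rownames(features) <- c(manifest$twin1_id, manifest$twin2_id)
  colnames(features) <- paste0("f", seq_len(n_features))
  # interleave back into manifest subject order (twin1s then twin2s is fine
  # for downstream joins, which go through ids)
  list(manifest = validate_manifest(manifest), features = features)
}

#' Simulate BOLD-like ROI time series for a twin cohort
#'
#' Each subject receives a target correlation matrix built from a shared
#' base template perturbed on the Fisher (atanh) scale by link-wise draws
#' from the twin model, mapped back through \code{tanh}, projected to the
#' nearest positive-definite correlation matrix (eigenvalue clipping at
#' \code{pd_tol}, then re-normalisation to unit diagonal), and then sampled
#' as \code{t_points} multivariate-normal observations.
#'
#' @param base N x N symmetric correlation template with unit diagonal
#'   (e.g. RSN-style blocks); row/col names are the parcellation. An
#'   unlabelled matrix gets labels \code{ROI1..ROIN}.
#' @param n_mz,n_dz Pair counts.
#' @param t_points Timepoints per subject (default 200).
#' @param sigma Standard deviation of the link-wise Fisher-scale
#'   perturbation; 0 gives every subject the base matrix.
#' @param spec [variance_components()] governing the within-pair covariance
#'   of the perturbations (default pure unique environment).
#' @param age_range,seed As in [simulate_feature_cohort()].
#' @param pd_tol Eigenvalue floor for the positive-definite projection.
#' @return List with \code{manifest} and \code{series}, a named list of
#'   T x N matrices keyed by subject id.
#' @export
simulate_timeseries_cohort <- function(base, n_mz, n_dz, t_points = 200L,
                                       sigma = 0,
                                       spec = variance_components(e2 = 1),
                                       age_range = c(10, 30), seed = 1L,
                                       pd_tol = 1e-8) {
  stopifnot(is.matrix(base), nrow(base) == ncol(base))
  if (!isTRUE(all.equal(base, t(base))))
    stop("base template must be symmetric")
  if (any(abs(diag(base) - 1) > 1e-12))
    stop("base template must have unit diagonal")
  if (min(eigen(base, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("base template is not positive semi-definite beyond repair tolerance")
  if (is.null(rownames(base))) {
    rownames(base) <- colnames(base) <- paste0("ROI", seq_len(nrow(base)))
  }
  n_roi <- nrow(base)
  n_link <- n_roi * (n_roi - 1) / 2
  manifest <- draw_manifest(n_mz, n_dz, age_range, seed)

  # link-wise twin-structured perturbations on the Fisher scale
  if (sigma > 0) {
    pert <- simulate_feature_cohort(spec, n_mz, n_dz, n_features = n_link,
                                    age_range = age_range,
                                    seed = sub_seed(seed, 101L))$features
    pert <- sigma * pert
  } else {
    pert <- matrix(0, 2 * (n_mz + n_dz), n_link)
    rownames(pert) <- c(manifest$twin1_id, manifest$twin2_id)
  }

  ut <- upper.tri(base)
  base_z <- atanh(pmin(pmax(base[ut], -1 + 1e-12), 1 - 1e-12))
  subjects <- c(manifest$twin1_id, manifest$twin2_id)
  series <- vector("list", length(subjects))
  names(series) <- subjects
  for (i in seq_along(subjects)) {
    target <- matrix(0, n_roi, n_roi)
    target[ut] <- tanh(base_z + pert[subjects[i], ])
    target <- target + t(target)
    diag(target) <- 1
    target <- nearest_pd_correlation(target, pd_tol)
    set.seed(sub_seed(seed, 1000L + i))
    z <- matrix(stats::rnorm(t_points * n_roi), t_points)
    x <- z %*% chol(target)
    colnames(x) <- rownames(base)
    series[[i]] <- x
  }
  list(manifest = manifest, series = series)
}

# Eigenvalue clipping followed by re-normalisation to a correlation matrix.
nearest_pd_correlation <- function(m, tol = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= tol) return(m)
  v <- pmax(e$values, tol)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  diag(m2) <- 1
  (m2 + t(m2)) / 2
}

#' Small named graphs for metric oracle checks
#'
#' Returns binary adjacency matrices for a handful of graphs whose metric
#' values are known in closed form: the triangle \code{K3}, the 3-node path
#' \code{P3}, the 4-node star \code{S4} (hub first), \code{K4me} (complete
#' 4-graph minus the edge between nodes 3 and 4), and \code{K3K3} (two
#' disjoint triangles).
#'
#' @return Named list of labelled 0/1 adjacency matrices.
#' @export
toy_graph_fixtures <- function() {
  lab <- function(m) {
    rownames(m) <- colnames(m) <- paste0("v", seq_len(nrow(m)))
    storage.mode(m) <- "double"
    m
  }
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  s4 <- matrix(0, 4, 4); s4[1, 2:4] <- s4[2:4, 1] <- 1
  k4me <- matrix(1, 4, 4); diag(k4me) <- 0; k4me[3, 4] <- k4me[4, 3] <- 0
  k3k3 <- matrix(0, 6, 6); k3k3[1:3, 1:3] <- k3; k3k3[4:6, 4:6] <- k3
  list(K3 = lab(k3), P3 = lab(p3), S4 = lab(s4), K4me = lab(k4me),
       K3K3 = lab(k3k3))
}
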