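#' Scenario percentages within resting-state networks
#'
#' For each RSN, restricts the link-scale results to connections with both
#' endpoint ROIs inside the RSN and reports the percentage of those links
#' gated into each scenario. The denominator is the number of within-RSN
#' ROI pairs, so the EPISTASIS/ADE/ACE/UNMODELED percentages sum to 100
#' when every within-RSN link was analysed.
#'
#' @param results Results data frame (from \code{as.data.frame} of a
#'   [twin_fc()] fit) containing link-scale records with \code{feature_id}
#'   of the form \code{link:A|B}.
#' @param rsn_map Named list of ROI-label vectors (see [read_rsn_map()]).
#' @param parcellation Labels used to validate the map.
#' @return Data frame with one row per RSN: \code{rsn}, \code{n_links},
#'   \code{pct_epistasis}, \code{pct_ade}, \code{pct_ace},
#'   \code{pct_unmodeled}.
#' @export
rsn_effect_percentages <- function(results, rsn_map,
                                   parcellation = aal90_labels()) {
  rsn_map <- validate_rsn_map(rsn_map, parcellation)
  results <- as.data.frame(results)
  links <- results[startsWith(results$feature_id, "link:"), ]
  if (!nrow(links)) stop("results contain no link-scale records")
  ends <- strsplit(sub("^link:", "", links$feature_id), "|", fixed = TRUE)
  a <- vapply(ends, `[`, character(1), 1L)
  b <- vapply(ends, `[`, character(1), 2L)
  out <- lapply(names(rsn_map), function(nm) {
    rois <- rsn_map[[nm]]
    inside <- a %in% rois & b %in% rois
    n <- sum(inside)
    if (n == 0)
      stop("RSN ", nm, " has no analysed within-network links")
    scen <- links$scenario[inside]
    data.frame(rsn = nm, n_links = n,
               pct_epistasis = 100 * mean(scen == "EPISTASIS"),
               pct_ade = 100 * mean(scen == "ADE"),
               pct_ace = 100 * mean(scen == "ACE"),
               pct_unmodeled = 100 * mean(scen == "UNMODELED"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pooled two-sample t test from summary statistics
#'
#' Equal-variance (pooled) two-sample t computed from group means, standard
#' deviations and sizes, with a two-sided p-value on
#' \code{n1 + n2 - 2} degrees of freedom. Used to compare demographic
#' summaries (e.g. MZ vs DZ pair age) when only the printed summaries are
#' available.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return List with \code{t} (signed, group1 minus group2), \code{df},
#'   \code{p}.
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square for a 2x2 table, no continuity correction
#'
#' @param a,b First row counts (e.g. MZ female pairs, MZ male pairs).
#' @param c,d Second row counts.
#' @return List with \code{chi2}, \code{df = 1}, \code{p}.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square undefined with a zero margin")
  expect <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expect)^2 / expect)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
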