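#' Read a twin-pair manifest
#'
#' The manifest is a tab-separated UTF-8 file with header columns
#' \code{pair_id}, \code{zygosity}, \code{twin1_id}, \code{twin2_id},
#' \code{age}, \code{sex}. One row describes one same-sex twin pair:
#' zygosity is \code{MZ} or \code{DZ}, age is the pair's age in years
#' (decimal allowed) and sex is \code{F} or \code{M}.
#'
#' @param path Path to the manifest file.
#' @return A data frame of class \code{twin_manifest} with the six columns
#'   above, validated: subject ids unique across all pairs, zygosity in
#'   \{MZ, DZ\}, finite non-negative ages.
#' @seealso [write_pair_manifest()], [simulate_feature_cohort()]
#' @export
read_pair_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("pair_id", "zygosity", "twin1_id", "twin2_id", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  age <- suppressWarnings(as.numeric(df$age))
  if (anyNA(age))
    stop("non-numeric age in manifest row(s): ",
         paste(which(is.na(age)), collapse = ", "))
  df$age <- age
  validate_manifest(df)
}

validate_manifest <- function(df) {
  ids <- c(df$twin1_id, df$twin2_id)
  if (anyDuplicated(ids))
    stop("duplicate subject id in manifest: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(df$pair_id))
    stop("duplicate pair_id in manifest")
  bad <- !df$zygosity %in% c("MZ", "DZ")
  if (any(bad))
    stop("zygosity must be MZ or DZ; offending pair(s): ",
         paste(df$pair_id[bad], collapse = ", "))
  if (any(!is.finite(df$age) | df$age < 0))
    stop("age must be finite and >= 0")
  if (any(!df$sex %in% c("F", "M")))
    stop("sex must be F or M (one shared value per same-sex pair)")
  class(df) <- c("twin_manifest", "data.frame")
  df
}

#' Write a twin-pair manifest
#'
#' @param manifest A validated manifest as returned by
#'   [read_pair_manifest()] or [simulate_feature_cohort()].
#' @param path Output path; tab-separated with header.
#' @return The path, invisibly.
#' @export
write_pair_manifest <- function(manifest, path) {
  validate_manifest(as.data.frame(manifest))
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read ROI-mean BOLD time series for one subject
#'
#' Expects a tab-separated numeric matrix with a header row of ROI labels,
#' T rows (timepoints) by N columns (ROIs). Columns are reordered to match
#' the parcellation, which is the single positional source of truth.
#'
#' @param path Path to the time-series file.
#' @param parcellation Character vector of ROI labels (default
#'   [aal90_labels()]).
#' @return A T x N numeric matrix with \code{colnames} equal to
#'   \code{parcellation}.
#' @export
read_roi_timeseries <- function(path, parcellation = aal90_labels()) {
  check_parcellation(parcellation)
  df <- utils::read.delim(path, check.names = FALSE)
  miss <- setdiff(parcellation, names(df))
  if (length(miss))
    stop("time-series file ", path, " is missing ROI column(s): ",
         paste(miss, collapse = ", "))
  m <- as.matrix(df[, parcellation])
  if (!is.numeric(m) || anyNA(m)) {
    bad <- which(apply(is.na(m) | is.nan(m), 1, any))
    stop("non-numeric or missing value in time series, row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (nrow(m) < 4L)
    stop("need at least 4 timepoints for correlation inference (df = T - 2)")
  m
}

#' Write ROI time series
#' @param ts T x N numeric matrix with ROI column names.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(is.matrix(ts), is.numeric(ts), !is.null(colnames(ts)))
  utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a resting-state-network membership map
#'
#' The map is a YAML file of \code{RSN name: [ROI labels]} entries, e.g.
#' \preformatted{
#' VIS:
#'   - Calcarine_L
#'   - Calcarine_R
#' }
#' RSNs may overlap; every ROI must exist in the parcellation and every
#' RSN must have at least two member ROIs (a network needs a link).
#'
#' @param path Path to the YAML file.
#' @param parcellation Character vector of ROI labels to validate against.
#' @return Named list of character vectors.
#' @export
read_rsn_map <- function(path, parcellation = aal90_labels()) {
  m <- yaml::read_yaml(path)
  validate_rsn_map(m, parcellation)
}

validate_rsn_map <- function(map, parcellation = aal90_labels()) {
  check_parcellation(parcellation)
  if (!is.list(map) || is.null(names(map)) || any(!nzchar(names(map))))
    stop("RSN map must be a named list of ROI label vectors")
  map <- lapply(map, function(x) as.character(unlist(x)))
  for (nm in names(map)) {
    rois <- map[[nm]]
    unknown <- setdiff(rois, parcellation)
    if (length(unknown))
      stop("RSN ", nm, " references unknown ROI(s): ",
           paste(unknown, collapse = ", "))
    if (length(unique(rois)) < 2L)
      stop("RSN ", nm, " needs >= 2 member ROIs")
  }
  map
}

#' Read and write square labelled FC matrices
#'
#' Matrices are stored dense as tab-separated text with ROI labels in the
#' header row and first column. Weighted matrices hold Pearson correlations
#' (significance-masked zeros included); binary matrices hold \{0, 1\}.
#' Writing an asymmetric matrix is an error; reading validates symmetry
#' and, when \code{parcellation} is given, label agreement.
#'
#' @param mat Square symmetric numeric matrix with identical row and column
#'   names.
#' @param path File path.
#' @param parcellation Optional label vector the read matrix must match.
#' @return \code{read_fc_matrix}: the labelled matrix.
#' @name matrix_io
#' @export
write_fc_matrix <- function(mat, path) {
  check_square_labelled(mat)
  if (!isTRUE(all.equal(mat, t(mat), tolerance = 0)))
    stop("matrix is not symmetric; refusing to write")
  df <- data.frame(ROI = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_fc_matrix <- function(path, parcellation = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("stored matrix is not square with matching labels: ", path)
  if (!isTRUE(all.equal(m, t(m))))
    stop("stored matrix is not symmetric: ", path)
  if (!is.null(parcellation)) {
    check_parcellation(parcellation)
    if (!setequal(rownames(m), parcellation))
      stop("matrix labels do not match the parcellation: ", path)
    m <- m[parcellation, parcellation]
  }
  m
}

check_square_labelled <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat) || nrow(mat) != ncol(mat))
    stop("expected a square numeric matrix")
  if (is.null(rownames(mat)) || !identical(rownames(mat), colnames(mat)))
    stop("matrix must carry identical row and column ROI labels")
  invisible(mat)
}

#' Write a long-format twin-analysis results table
#'
#' One row per analysed feature with columns \code{feature_id}, \code{scale},
#' \code{rMZ}, \code{rDZ}, \code{scenario}, \code{A}, \code{C}, \code{D},
#' \code{E}, \code{H2}, \code{h2}, \code{Z}, \code{p}, \code{p_bonferroni}.
#' Rows are ordered deterministically by scale then feature_id so repeated
#' writes of the same results are byte-identical.
#'
#' @param results Data frame of results (e.g. \code{as.data.frame} of a
#'   [twin_fc()] fit).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results_table <- function(results, path) {
  results <- as.data.frame(results)
  need <- c("feature_id", "scale", "rMZ", "rDZ", "scenario",
            "A", "C", "D", "E", "H2", "h2", "Z", "p", "p_bonferroni")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("results table missing column(s): ", paste(miss, collapse = ", "))
  results <- results[, need]
  o <- order(match(results$scale, c("link", "node", "network")),
             results$feature_id, method = "radix")
  utils::write.table(results[o, ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
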