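graph_from_binary <- function(b) {
  if (!all(b %in% c(0, 1))) stop("matrix is not binary (entries must be 0/1)")
  check_square_labelled(b)
  igraph::graph_from_adjacency_matrix(b, mode = "undirected", diag = FALSE)
}

# Mean inverse shortest-path length over unordered pairs (1/Inf = 0).
efficiency_from_distances <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Node-level binary-graph metrics
#'
#' Computes, from a binarized FC matrix, the four binary nodal features:
#' degree (row sum), clustering coefficient
#' \eqn{2 t_i / (k_i (k_i - 1))} with \eqn{t_i} the number of edges among
#' node i's neighbours (0 when \eqn{k_i < 2}), local efficiency (the global
#' efficiency of the subgraph induced by i's neighbours, 0 when
#' \eqn{k_i < 2}), and betweenness centrality as raw unnormalised
#' shortest-path pair counts \eqn{\sum_{s<t} \sigma_{st}(i)/\sigma_{st}}.
#'
#' @param b Binary adjacency matrix with ROI labels.
#' @return Data frame with one row per ROI and columns \code{roi},
#'   \code{degree}, \code{clustering}, \code{local_efficiency},
#'   \code{betweenness}.
#' @export
node_metrics_binary <- function(b) {
  g <- graph_from_binary(b)
  n <- nrow(b)
  deg <- rowSums(b)
  clust <- igraph::transitivity(g, type = "local", isolates = "zero")
  leff <- vapply(seq_len(n), function(i) {
    nb <- which(b[i, ] == 1)
    if (length(nb) < 2) return(0)
    efficiency_from_distances(
      igraph::distances(igraph::induced_subgraph(g, nb)))
  }, numeric(1))
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  data.frame(roi = rownames(b), degree = as.numeric(deg),
             clustering = clust, local_efficiency = leff,
             betweenness = as.numeric(btw), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Signed nodal strengths from the weighted FC matrix
#'
#' @param w Masked weighted FC matrix.
#' @return Data frame with columns \code{roi}, \code{strength_pos} (sum of
#'   positive weights per row) and \code{strength_neg} (sum of absolute
#'   negative weights).
#' @export
node_strengths_signed <- function(w) {
  check_square_labelled(w)
  data.frame(roi = rownames(w),
             strength_pos = rowSums(pmax(w, 0)),
             strength_neg = rowSums(pmax(-w, 0)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Whole-network binary-graph metrics
#'
#' Global efficiency is the mean of inverse shortest-path lengths over
#' unordered node pairs (disconnected pairs contribute 0); the
#' characteristic path length averages only the finite distances, and a
#' \code{disconnected} flag records whether any pair was excluded. Mean
#' degree is \eqn{2m/N} and density \eqn{2m/(N(N-1))}.
#'
#' @param b Binary adjacency matrix.
#' @return Named list: \code{global_efficiency}, \code{char_path_length}
#'   (NA for an edgeless graph), \code{mean_degree}, \code{density},
#'   \code{disconnected}.
#' @export
network_metrics <- function(b) {
  if (nrow(b) < 2) stop("network metrics need at least 2 nodes")
  g <- graph_from_binary(b)
  n <- nrow(b)
  d <- igraph::distances(g)[upper.tri(matrix(0, n, n))]
  finite <- is.finite(d)
  m <- sum(b) / 2
  list(
    global_efficiency = efficiency_from_distances(igraph::distances(g)),
    char_path_length = if (any(finite)) mean(d[finite]) else NA_real_,
    mean_degree = 2 * m / n,
    density = 2 * m / (n * (n - 1)),
    disconnected = !all(finite)
  )
}

# Modularity of a partition at resolution gamma, recomputed from first
# principles: Q = sum_c [ e_c/m - gamma * (d_c / 2m)^2 ].
modularity_q <- function(b, membership, gamma = 1) {
  m <- sum(b) / 2
  if (m == 0) stop("modularity undefined for an edgeless graph")
  deg <- rowSums(b)
  q <- 0
  for (cm in unique(membership)) {
    idx <- which(membership == cm)
    e_c <- sum(b[idx, idx, drop = FALSE]) / 2
    d_c <- sum(deg[idx])
    q <- q + e_c / m - gamma * (d_c / (2 * m))^2
  }
  q
}

#' Louvain community detection with seeded restarts
#'
#' Runs Louvain community detection \code{restarts} times under seeded
#' random node-order shuffles and keeps the partition with the highest
#' modularity. The reported Q is always recomputed from the returned
#' partition via \eqn{Q = \sum_c [e_c/m - \gamma (d_c/2m)^2]}, so it is
#' self-consistent by construction.
#'
#' @param b Binary adjacency matrix with at least one edge.
#' @param gamma Resolution parameter (default 1).
#' @param seed Integer seed controlling the node shuffles.
#' @param restarts Number of restarts (default 10).
#' @return List with \code{membership} (named integer vector) and \code{Q}.
#' @export
louvain_modularity <- function(b, gamma = 1, seed = 1L, restarts = 10L) {
  g <- graph_from_binary(b)
  if (sum(b) == 0) stop("Louvain requires at least one edge")
  n <- nrow(b)
  best <- NULL
  set.seed(sub_seed(seed, 42L))
  for (i in seq_len(restarts)) {
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp, resolution = gamma)
    memb <- integer(n)
    memb[perm] <- igraph::membership(cl)
    q <- modularity_q(b, memb, gamma)
    if (is.null(best) || q > best$Q) best <- list(membership = memb, Q = q)
  }
  names(best$membership) <- rownames(b)
  best
}

feature_column_names <- function(labels) {
  n <- length(labels)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  link <- paste0("link:", labels[pairs[, 1]], "|", labels[pairs[, 2]])
  node_metrics <- c("degree", "strength_pos", "strength_neg", "clustering",
                    "local_efficiency", "betweenness")
  node <- as.vector(vapply(node_metrics,
                           function(mname) paste0("node:", mname, ":", labels),
                           character(n)))
  net <- paste0("net:", c("global_efficiency", "char_path_length",
                          "mean_degree", "density", "louvain_Q"))
  c(link, node, net)
}

#' Assemble the subject-by-feature table
#'
#' Collects, for every subject, the link weights from the masked weighted
#' matrix (upper triangle, \code{link:A|B}), the six nodal metrics
#' (\code{node:metric:ROI}) and the five network metrics (\code{net:name})
#' into one numeric matrix with a fixed deterministic column order. For an
#' N-ROI parcellation this yields \eqn{C(N,2) + 6N + 5} columns
#' (4005 + 540 + 5 = 4550 for N = 90).
#'
#' @param cohort Named list keyed by subject id; each element is a list with
#'   components \code{weighted} (masked weighted FC matrix) and
#'   \code{binary} (binarized FC matrix), sharing one parcellation.
#' @param seed Seed forwarded to [louvain_modularity()].
#' @return Numeric matrix, subjects x features, of class
#'   \code{fc_feature_table} with attribute \code{parcellation}.
#' @export
extract_feature_table <- function(cohort, seed = 1L) {
  if (!length(cohort) || is.null(names(cohort)))
    stop("cohort must be a named list keyed by subject id")
  labels <- rownames(cohort[[1]]$weighted)
  check_parcellation(labels)
  cols <- feature_column_names(labels)
  out <- matrix(NA_real_, length(cohort), length(cols),
                dimnames = list(names(cohort), cols))
  for (s in names(cohort)) {
    w <- cohort[[s]]$weighted
    b <- cohort[[s]]$binary
    if (!identical(rownames(w), labels) || !identical(rownames(b), labels))
      stop("subject ", s, " has a different parcellation / label order")
    nm <- node_metrics_binary(b)
    st <- node_strengths_signed(w)
    net <- network_metrics(b)
    lq <- if (sum(b) > 0) louvain_modularity(b, seed = seed)$Q else NA_real_
    ut <- t(w)[lower.tri(w)]  # row-major upper triangle = (i<j) pairs
    out[s, ] <- c(ut, nm$degree, st$strength_pos, st$strength_neg,
                  nm$clustering, nm$local_efficiency, nm$betweenness,
                  net$global_efficiency, net$char_path_length,
                  net$mean_degree, net$density, lq)
  }
  structure(out, parcellation = labels,
            class = c("fc_feature_table", "matrix", "array"))
}
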