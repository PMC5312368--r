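#' Cluster-to-cluster autocorrelation matrix (R-STOCSY)
#'
#' With X the autoscaled SRV cluster matrix of NS spectra x NV clusters,
#' the statistical total correlation spectroscopy matrix is
#' \eqn{C = X'X / (NS - 1)}, which equals the pairwise Pearson correlation
#' of the raw cluster intensities: symmetric, unit diagonal, entries in
#' `[-1, 1]`.
#'
#' @param xs an [autoscale()]d cluster matrix (NS >= 3).
#' @param variant label stored with the result (`"R-STOCSY"` or
#'   `"OR-STOCSY"`).
#' @param filter_meta optional metadata about an orthogonal filter applied
#'   upstream.
#' @return A `correlation_matrix`: NV x NV matrix with attributes `NS`,
#'   `variant`, `filter`.
#' @export
correlation_matrix <- function(xs, variant = "R-STOCSY", filter_meta = NULL) {
  x <- unclass(as.matrix(xs))
  ns <- nrow(x)
  if (ns < 3) stop("correlation matrix needs NS >= 3 spectra")
  C <- crossprod(x) / (ns - 1)
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  structure(C, class = c("correlation_matrix", "matrix", "array"),
            NS = ns, variant = variant, filter = filter_meta)
}

#' Orthogonal filter for OR-STOCSY
#'
#' Removes the class-orthogonal structured variation before correlation
#' analysis: the `n_ortho` orthogonal components of the OPLS extraction are
#' deflated from the autoscaled matrix, so correlations driven by
#' systematic variation unrelated to the contrast (diet, batch, a latent
#' physiological factor) disappear while class-linked correlations remain.
#' Columns are re-autoscaled after deflation so the downstream matrix is a
#' true correlation matrix; every removed score is uncorrelated with the
#' class code (|cor| < 1e-8).
#'
#' @param xs autoscaled cluster matrix.
#' @param groups two-level class labels (a stage-vs-control contrast).
#' @param n_ortho number of orthogonal components to remove (default 1).
#' @param control reference class.
#' @return The filtered, re-autoscaled matrix (same column count) with
#'   attributes `removed_scores`, `contrast`, `n_ortho`.
#' @export
orthogonal_filter <- function(xs, groups, n_ortho = 1, control = NULL) {
  if (n_ortho < 1) stop("n_ortho must be >= 1")
  x <- unclass(as.matrix(xs))
  enc <- encode_y(groups, control)
  fit <- opls_core(x, enc$y, n_ortho)
  xf <- fit$x_filtered
  # re-autoscale so that downstream crossprod/(NS-1) is a correlation matrix
  ctr <- colMeans(xf)
  sc <- apply(xf, 2, stats::sd)
  sc[sc < .Machine$double.eps^0.5] <- 1
  xf <- sweep(sweep(xf, 2, ctr), 2, sc, "/")
  structure(xf, class = c("scaled_matrix", "matrix", "array"),
            NS = nrow(xf), NV = ncol(xf),
            removed_scores = fit$to,
            contrast = paste(enc$case, "vs", enc$control),
            n_ortho = n_ortho)
}

#' Threshold a correlation matrix into an edge list
#'
#' Returns every unordered cluster pair with `|r| >= threshold` (diagonal
#' excluded), sorted by `|r|` descending. Sign is retained for display.
#'
#' @param C a [correlation_matrix()].
#' @param threshold absolute-correlation threshold in (0, 1]; default 0.9.
#' @return A data frame: `i`, `j` (column indices, `i < j`), `var_i`,
#'   `var_j`, `r`, `sign`.
#' @export
threshold_edges <- function(C, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  idx <- which(upper.tri(C) & abs(C) >= threshold, arr.ind = TRUE)
  nm <- colnames(C)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(C)))
  out <- data.frame(i = idx[, 1], j = idx[, 2],
                    var_i = nm[idx[, 1]], var_j = nm[idx[, 2]],
                    r = C[idx], sign = ifelse(C[idx] >= 0, "+", "-"),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Classify correlation edges as intra- or inter-metabolite
#'
#' Each cluster is mapped to a metabolite by maximal ppm-window overlap
#' ([assign_clusters()]); an edge between clusters of the same metabolite is
#' `intra` (same spin system, useful for assignment), between different
#' metabolites `inter` (pathway-driven co-variation), and `unassigned` when
#' either cluster maps to no window.
#'
#' @param edges output of [threshold_edges()]; its `i`/`j` index the rows of
#'   `clusters`.
#' @param clusters the `cluster_set` the correlation matrix was built on.
#' @param map an `assignment_map`.
#' @return The edge data frame with `metabolite_i`, `metabolite_j`, `type`
#'   columns, plus attribute `inter_pairs`: the deduplicated unique
#'   metabolite pairs of the inter edges (network input).
#' @export
classify_edges <- function(edges, clusters, map) {
  met <- assign_clusters(clusters, map)
  mi <- met[edges$i]; mj <- met[edges$j]
  type <- ifelse(mi == "unassigned" | mj == "unassigned", "unassigned",
                 ifelse(mi == mj, "intra", "inter"))
  out <- cbind(edges, metabolite_i = mi, metabolite_j = mj, type = type,
               stringsAsFactors = FALSE)
  inter <- out[out$type == "inter", c("metabolite_i", "metabolite_j"), drop = FALSE]
  if (nrow(inter)) {
    swap <- inter$metabolite_i > inter$metabolite_j
    tmp <- inter$metabolite_i[swap]
    inter$metabolite_i[swap] <- inter$metabolite_j[swap]
    inter$metabolite_j[swap] <- tmp
    inter <- unique(inter)
    rownames(inter) <- NULL
  }
  attr(out, "inter_pairs") <- inter
  out
}
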