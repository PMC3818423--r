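## Pairwise cell-correlation assay and the thresholded network of
## correlating cells.

#' Min-max normalize a feature matrix
#'
#' Column-wise rescaling to `[0, 1]`. Constant columns map to 0 with a
#' warning. Idempotent: normalizing an already normalized matrix is the
#' identity.
#'
#' @param mat numeric matrix (observations x features), finite entries.
#' @return matrix of the same shape in `[0, 1]`.
#' @export
normalize_minmax <- function(mat) {
  if (!all(is.finite(mat))) stop("non-finite entries", call. = FALSE)
  lo <- apply(mat, 2, min)
  hi <- apply(mat, 2, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) {
    warning("constant column(s) mapped to 0: ",
            paste(which(const), collapse = ","), call. = FALSE)
    rng[const] <- 1
  }
  out <- sweep(sweep(mat, 2, lo, "-"), 2, rng, "/")
  out[, const] <- 0
  out
}

#' Correlation between two cells
#'
#' Similarity of two cells across their (normalized) feature vectors:
#' `sum((x - mean(x)) * (y - mean(y))) / (p * sigma_x * sigma_y)` with
#' population standard deviations, i.e. the sample Pearson correlation of
#' the two vectors. Self-correlation is 1; values never exceed 1 (negative
#' values are possible in principle and simply never pass high thresholds).
#'
#' @param c1,c2 numeric vectors of equal length (the 14 normalized
#'   characteristics).
#' @return scalar correlation.
#' @export
corr_cells <- function(c1, c2) {
  stopifnot(length(c1) == length(c2))
  p <- length(c1)
  s1 <- sqrt(sum((c1 - mean(c1))^2) / p)
  s2 <- sqrt(sum((c2 - mean(c2))^2) / p)
  if (s1 == 0 || s2 == 0)
    stop("degenerate cell vector (zero variance)", call. = FALSE)
  sum((c1 - mean(c1)) * (c2 - mean(c2))) / (p * s1 * s2)
}

#' Build the network of correlating cells
#'
#' Exhaustive pairwise correlation of all cells; two cells are connected
#' when their correlation reaches `threshold` (ties at the threshold are
#' included). Connected components are computed and the largest one
#' reported.
#'
#' @param cell_mat numeric matrix, cells x features (e.g. from
#'   [cell_feature_matrix()], possibly pooled over the images of both
#'   conditions).
#' @param threshold correlation threshold.
#' @param meta optional data.frame aligned with rows of `cell_mat` with
#'   columns such as `condition` and `n_sides`, stored as node attributes.
#' @param normalize min-max normalize columns first (default `TRUE`).
#' @return object of class `correlation_graph`: list with `graph` (igraph),
#'   `threshold`, `components` (igraph components), `largest_component`
#'   (vertex ids).
#' @export
build_correlation_network <- function(cell_mat, threshold, meta = NULL,
                                      normalize = TRUE) {
  n <- nrow(cell_mat)
  stopifnot(n >= 2)
  if (n > 8000)
    stop("correlation matrix would need ", round(n^2 * 8 / 2^30, 1),
         " GiB; subsample the cells", call. = FALSE)
  if (normalize) cell_mat <- normalize_minmax(cell_mat)
  C <- stats::cor(t(cell_mat))
  sel <- which(upper.tri(C) & C >= threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(sel)) g <- igraph::add_edges(g, t(sel),
                                        corr = C[sel])
  if (!is.null(meta))
    for (nm in names(meta))
      g <- igraph::set_vertex_attr(g, nm, value = meta[[nm]])
  comp <- igraph::components(g)
  structure(list(graph = g, threshold = threshold, components = comp,
                 largest_component = which(comp$membership ==
                                             which.max(comp$csize))),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf(paste0("<correlation_graph> %d cells, %d links at threshold ",
                     "%.4f; largest component %d cells\n"),
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$threshold, length(x$largest_component)))
  invisible(x)
}

#' Find a threshold giving a target largest-component size
#'
#' The largest-component size is non-increasing in the threshold; a
#' bisection over `range` returns a threshold whose largest component falls
#' inside `[lo, hi]`, or an error stating the attainable sizes around the
#' gap.
#'
#' @param cell_mat cells x features matrix (normalized internally).
#' @param target integer `(lo, hi)` component-size window.
#' @param range search interval for the threshold.
#' @return list with `threshold` and `component_size`.
#' @export
threshold_sweep <- function(cell_mat, target, range = c(0.9, 1.0)) {
  stopifnot(length(target) == 2, target[1] <= target[2])
  cell_mat <- normalize_minmax(cell_mat)
  C <- stats::cor(t(cell_mat))
  diag(C) <- -Inf
  comp_size <- function(t) {
    sel <- which(upper.tri(C) & C >= t, arr.ind = TRUE)
    g <- igraph::make_empty_graph(nrow(C), directed = FALSE)
    if (nrow(sel)) g <- igraph::add_edges(g, t(sel))
    max(igraph::components(g)$csize)
  }
  lo <- range[1]; hi <- range[2]
  s_lo <- comp_size(lo); s_hi <- comp_size(hi)
  if (s_lo < target[1] || s_hi > target[2])
    stop("target component size unattainable: sizes range from ", s_hi,
         " (threshold ", hi, ") to ", s_lo, " (threshold ", lo, ")",
         call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    s <- comp_size(mid)
    if (s >= target[1] && s <= target[2])
      return(list(threshold = mid, component_size = s))
    if (s > target[2]) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  stop("target component size unattainable: sizes jump from ",
       comp_size(hi), " to ", comp_size(lo), " around threshold ",
       signif((lo + hi) / 2, 6), call. = FALSE)
}

#' Polygon-class assortment of a correlation network
#'
#' Fraction of links joining cells of the same polygon class, with a
#' permutation p-value obtained by shuffling the class labels over nodes.
#' Mirrors the observation that correlating cells share their number of
#' sides.
#'
#' @param cg a `correlation_graph` whose nodes carry an `n_sides` attribute.
#' @param n_perm number of label shuffles (>= 1000 recommended).
#' @param seed RNG seed.
#' @param attribute node attribute defining the classes (default
#'   `"n_sides"`; use `"condition"` to test stage mixing instead).
#' @return list with `same_class_edge_fraction` and `permutation_p`.
#' @export
polygon_assortment <- function(cg, n_perm = 1000L, seed = 1L,
                               attribute = "n_sides") {
  g <- cg$graph
  cls <- igraph::vertex_attr(g, attribute)
  if (is.null(cls)) stop("nodes carry no ", attribute, " attribute",
                         call. = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) < 20L) stop("fewer than 20 edges", call. = FALSE)
  if (length(unique(cls)) < 2L)
    return(list(same_class_edge_fraction = 1, permutation_p = 1))
  obs <- mean(cls[el[, 1]] == cls[el[, 2]])
  set.seed(seed)
  perm <- replicate(n_perm, {
    p <- sample(cls)
    mean(p[el[, 1]] == p[el[, 2]])
  })
  list(same_class_edge_fraction = obs,
       permutation_p = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Export a correlation network as GraphML
#'
#' Node attributes `condition` and `n_sides` travel with the graph so any
#' network tool can reproduce the class-coloured view.
#'
#' @param cg a `correlation_graph`.
#' @param path file path (.graphml).
#' @export
write_correlation_network <- function(cg, path) {
  igraph::write_graph(cg$graph, path, format = "graphml")
  invisible(path)
}
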