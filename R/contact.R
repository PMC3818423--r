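## Cell-contact graph and its per-node / whole-image characteristics.

#' Names of the 40 image-level characteristics
#'
#' Ordered names of the image feature vector: means and standard deviations
#' of the per-cell quantities (1-28) followed by the 12 whole-network
#' characteristics (29-40).
#' @export
image_feature_names <- c(
  "avg_area", "sd_area", "avg_major_axis", "avg_minor_axis",
  "avg_relation_axis", "sd_relation_axis", "avg_convex_hull",
  "sd_convex_hull", "avg_neighbours", "sd_neighbours",
  "avg_rel_neigh_area", "sd_rel_neigh_area",
  "avg_rel_neigh_major", "sd_rel_neigh_major",
  "avg_rel_neigh_minor", "sd_rel_neigh_minor",
  "avg_rel_neigh_relation_axis", "sd_rel_neigh_relation_axis",
  "avg_rel_neigh_convex_hull", "sd_rel_neigh_convex_hull",
  "avg_strength", "sd_strength", "avg_clustering", "sd_clustering",
  "avg_eccentricity", "sd_eccentricity", "avg_betweenness",
  "sd_betweenness",
  "avg_path_length", "sd_path_length", "radius", "diameter",
  "efficiency", "pearson_correlation", "algebraic_connectivity",
  "s_metric", "assortativity", "density", "transitivity", "modularity")

#' Names of the 14 per-cell characteristics used in the correlation assay
#'
#' The grey-column subset: five geometric features, five neighbour-relation
#' ratios and four per-node network metrics. "Number of sides" is
#' deliberately not among them.
#' @export
cell_feature_names <- c(
  "area", "major_axis", "minor_axis", "relation_axis", "convex_hull_ratio",
  "rel_neigh_area", "rel_neigh_major", "rel_neigh_minor",
  "rel_neigh_relation_axis", "rel_neigh_convex_hull",
  "strength", "clustering", "eccentricity", "betweenness")

## offsets (dy,dx), dy>0 or (dy==0,dx>0), with dy^2+dx^2 <= r^2
half_disc_offsets <- function(r) {
  off <- expand.grid(dy = 0:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2 & off$dy^2 + off$dx^2 > 0, ]
  off[off$dy > 0 | off$dx > 0, ]
}

## pairs (a,b), a<b, of labels with pixel-to-pixel distance <= r
proximity_pairs <- function(lab, r) {
  h <- nrow(lab); w <- ncol(lab)
  off <- half_disc_offsets(r)
  n <- max(lab)
  keys <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    dy <- off$dy[k]; dx <- off$dx[k]
    r1 <- seq_len(h - dy); r2 <- seq_len(h - dy) + dy
    if (dx >= 0) { c1 <- seq_len(w - dx); c2 <- seq_len(w - dx) + dx }
    else         { c1 <- seq_len(w + dx) - dx; c2 <- seq_len(w + dx) }
    a <- lab[r1, c1]; b <- lab[r2, c2]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      aa <- a[sel]; bb <- b[sel]
      keys[[k]] <- unique((pmin(aa, bb) - 1) * n + pmax(aa, bb))
    }
  }
  keys <- unique(unlist(keys))
  if (is.null(keys)) return(cbind(integer(0), integer(0)))
  keys <- sort(keys)
  cbind(as.integer((keys - 1) %/% n) + 1L, as.integer((keys - 1) %% n) + 1L)
}

## edge weights: number of background pixels lying within distance r of both
## members of each adjacent pair (a shared-boundary contact-length proxy)
boundary_weights <- function(lab, r, pairs) {
  h <- nrow(lab); w <- ncol(lab)
  n <- max(lab)
  off <- half_disc_offsets(r)
  off <- rbind(off, -off)              # full disc, both signs
  acc <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    dy <- off$dy[k]; dx <- off$dx[k]
    rr1 <- max(1L, 1L - dy):min(h, h - dy)
    cc1 <- max(1L, 1L - dx):min(w, w - dx)
    a <- lab[rr1, cc1]                  # pixel p
    b <- lab[rr1 + dy, cc1 + dx]        # pixel p + delta
    sel <- a == 0L & b > 0L
    if (any(sel)) {
      pix <- outer((rr1 - 1L), (cc1 - 1L) * h, "+")[sel] + 1L
      acc[[k]] <- pix * (n + 1) + b[sel]
    }
  }
  pl <- unique(unlist(acc))             # unique (bg pixel, nearby label)
  if (is.null(pl)) return(rep(1, nrow(pairs)))
  pl <- sort(pl)
  pix <- (pl - 1) %/% (n + 1)
  labv <- as.integer(pl - pix * (n + 1))
  ## for each bg pixel with m >= 2 nearby labels, count all label pairs;
  ## vectorized by grouping pixels with the same number of nearby labels
  rl <- rle(pix)
  key_of <- (pairs[, 1] - 1) * n + pairs[, 2]
  counts <- numeric(nrow(pairs))
  ends <- cumsum(rl$lengths)
  for (m in unique(rl$lengths)) {
    if (m < 2L) next
    sel_runs <- which(rl$lengths == m)
    idx <- outer(seq_len(m) - m, ends[sel_runs], "+")   # m x k label indices
    Lm <- matrix(labv[idx], nrow = m)
    ci <- combn(m, 2L)
    for (q in seq_len(ncol(ci))) {
      a <- Lm[ci[1, q], ]; b <- Lm[ci[2, q], ]
      mi <- match((pmin(a, b) - 1) * n + pmax(a, b), key_of)
      mi <- mi[!is.na(mi)]
      if (length(mi)) counts <- counts + tabulate(mi, nrow(pairs))
    }
  }
  pmax(counts, 1)                       # adjacency implies contact
}

#' Build the cell-contact graph of a label image
#'
#' Two cells are adjacent when the dilation of one region by a disc of
#' radius `r` overlaps the other, i.e. when their minimal pixel-to-pixel
#' distance is at most `r` -- background gaps up to `r` px (boundaries,
#' vertices) are bridged. Edge weight is the number of background pixels
#' within distance `r` of both regions, a proxy for shared boundary length;
#' weights are used only by the node strength, all path-based metrics are
#' unweighted.
#'
#' @param image a `label_image`.
#' @param r neighbour-detection radius in px (default 4).
#' @param weighted compute boundary-contact edge weights (default `TRUE`;
#'   skip for speed when only degrees are needed, weights are then 1).
#' @return object of class `contact_graph`: list with `graph` (an igraph
#'   with vertex attributes `row`, `col`, `in_roi` and edge attribute
#'   `weight`), `r`, and `n_cells`.
#' @export
build_contact_graph <- function(image, r = 4, weighted = TRUE) {
  lab <- image$labels
  n <- max(lab)
  pairs <- proximity_pairs(lab, r)
  wts <- if (weighted && nrow(pairs))
    boundary_weights(lab, r, pairs) else rep(1, nrow(pairs))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(pairs))
    g <- igraph::add_edges(g, t(pairs), weight = wts)
  cells <- extract_centroids(lab, n)
  roi_cells <- attr(image, "roi_cells")
  if (is.null(roi_cells))
    roi_cells <- sort(unique(lab[image$roi_mask & lab > 0L]))
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  g <- igraph::set_vertex_attr(g, "row", value = cells$row)
  g <- igraph::set_vertex_attr(g, "col", value = cells$col)
  g <- igraph::set_vertex_attr(g, "in_roi",
                               value = seq_len(n) %in% roi_cells)
  iso <- which(igraph::degree(g) == 0)
  if (length(iso))
    warning("isolated cell(s): ", paste(iso, collapse = ","), call. = FALSE)
  structure(list(graph = g, r = r, n_cells = n), class = "contact_graph")
}

extract_centroids <- function(lab, n) {
  fg <- which(lab > 0L)
  l <- lab[fg]
  h <- nrow(lab)
  cnt <- tabulate(l, n)
  list(row = rowsum(((fg - 1L) %% h) + 0.5, l)[, 1] / cnt,
       col = rowsum(((fg - 1L) %/% h) + 0.5, l)[, 1] / cnt)
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %d cells, %d contacts (r = %g px), %d in ROI\n",
              x$n_cells, igraph::ecount(x$graph), x$r,
              sum(igraph::V(x$graph)$in_roi)))
  invisible(x)
}

#' Polygon class (number of sides) of a cell
#'
#' The polygon class of a cell is its number of contact-graph neighbours.
#'
#' @param graph a `contact_graph`.
#' @param cell_id integer id(s); default all cells.
#' @return integer vector of side counts.
#' @export
polygon_class <- function(graph, cell_id = NULL) {
  deg <- igraph::degree(graph$graph)
  if (is.null(cell_id)) return(as.integer(unname(deg)))
  if (any(cell_id < 1L | cell_id > graph$n_cells))
    stop("cell id out of graph", call. = FALSE)
  as.integer(unname(deg[cell_id]))
}

#' Per-node network metrics
#'
#' Strength (sum of incident edge weights), local clustering coefficient
#' (unweighted; 0 for degree < 2), eccentricity and betweenness centrality
#' (both unweighted; betweenness normalized by (n-1)(n-2)/2), computed on
#' the full graph so that out-of-ROI neighbours contribute.
#'
#' @param graph a `contact_graph`.
#' @return data.frame with columns cell_id, strength, clustering,
#'   eccentricity, betweenness.
#' @export
node_metrics <- function(graph) {
  g <- graph$graph
  n <- igraph::vcount(g)
  if (n < 3L) stop("betweenness undefined for fewer than 3 nodes",
                   call. = FALSE)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  cl[is.nan(cl)] <- 0
  data.frame(cell_id = seq_len(n),
             strength = unname(igraph::strength(g)),
             clustering = cl,
             eccentricity = unname(igraph::eccentricity(g, weights = NA)),
             betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                                      weights = NA)) /
               ((n - 1) * (n - 2) / 2))
}

## in-ROI induced subgraph; largest component if disconnected (warning)
roi_subgraph <- function(graph) {
  g <- igraph::induced_subgraph(graph$graph,
                                which(igraph::V(graph$graph)$in_roi))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("in-ROI subgraph disconnected; using largest component (",
            max(comp$csize), "/", igraph::vcount(g), " nodes)",
            call. = FALSE)
    g <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  }
  g
}

#' Whole-image network characteristics
#'
#' The 12 image-level network metrics, computed unweighted on the subgraph
#' induced by the in-ROI cells (largest component if disconnected): mean and
#' sd of shortest-path lengths, radius, diameter, global efficiency (mean of
#' 1/d over pairs), degree-degree Pearson correlation over edges, algebraic
#' connectivity (second-smallest Laplacian eigenvalue), s-metric (sum of
#' d_i d_j over edges), Newman degree assortativity, density, global
#' transitivity, and the modularity of a deterministic fast-greedy community
#' partition.
#'
#' @param graph a `contact_graph`.
#' @return named numeric vector of length 12 (names
#'   `image_feature_names[29:40]`).
#' @export
global_metrics <- function(graph) {
  g <- roi_subgraph(graph)
  n <- igraph::vcount(g)
  if (n < 3L) stop("in-ROI subgraph has fewer than 3 nodes", call. = FALSE)
  d <- igraph::distances(g, weights = NA)
  ut <- d[upper.tri(d)]
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  d1 <- deg[el[, 1]]; d2 <- deg[el[, 2]]
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  L <- diag(deg) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  ## canonical vertex order (by centroid when present) so the greedy
  ## community partition -- and hence modularity -- does not depend on the
  ## arbitrary ordering of cell labels
  rowa <- igraph::vertex_attr(g, "row")
  canon <- if (!is.null(rowa))
    order(rowa, igraph::vertex_attr(g, "col")) else seq_len(n)
  gc <- igraph::permute(g, order(canon))
  comm <- igraph::cluster_fast_greedy(igraph::simplify(gc), weights = NULL)
  mod <- igraph::modularity(gc, igraph::membership(comm))
  ## degree-degree correlation is undefined on regular graphs; use 0
  ddc <- if (stats::var(deg) == 0) 0 else
    suppressWarnings(stats::cor(c(d1, d2), c(d2, d1)))
  assort <- if (stats::var(deg) == 0) 0 else
    igraph::assortativity_degree(g)
  if (!is.finite(ddc)) ddc <- 0
  if (!is.finite(assort)) assort <- 0
  out <- c(mean(ut), stats::sd(ut),
           igraph::radius(g, weights = NA),
           igraph::diameter(g, weights = NA),
           mean(1 / ut),
           ddc,
           ev[2],
           sum(d1 * d2),
           assort,
           igraph::edge_density(g),
           igraph::transitivity(g, type = "global"),
           mod)
  names(out) <- image_feature_names[29:40]
  out
}

#' Assemble the 40-characteristic image feature vector
#'
#' Entries 1-28 are the mean and standard deviation over in-ROI cells of the
#' per-cell base quantities (for major and minor axis only the mean is
#' kept); entries 29-40 are the whole-image network metrics of
#' [global_metrics()].
#'
#' @param cells a `cell_table` with geometric, relation and node-metric
#'   columns filled (see [compute_image_features()] for the one-call path).
#' @param graph the matching `contact_graph`.
#' @param image_id,condition identifiers stored as attributes.
#' @return named numeric vector of length 40, class `image_features`.
#' @export
image_feature_vector <- function(cells, graph, image_id = NA_character_,
                                 condition = NA_character_) {
  roi <- cells[cells$in_roi, ]
  need <- c("area", "major_axis", "minor_axis", "relation_axis",
            "convex_hull_ratio", "n_sides", "rel_neigh_area",
            "rel_neigh_major", "rel_neigh_minor", "rel_neigh_relation_axis",
            "rel_neigh_convex_hull", "strength", "clustering",
            "eccentricity", "betweenness")
  if (anyNA(roi[, need]))
    stop("unset feature(s): run fill_neighbor_relations()/node_metrics() first",
         call. = FALSE)
  m <- function(x) mean(x); s <- function(x) stats::sd(x)
  v <- c(m(roi$area), s(roi$area), m(roi$major_axis), m(roi$minor_axis),
         m(roi$relation_axis), s(roi$relation_axis),
         m(roi$convex_hull_ratio), s(roi$convex_hull_ratio),
         m(roi$n_sides), s(roi$n_sides),
         m(roi$rel_neigh_area), s(roi$rel_neigh_area),
         m(roi$rel_neigh_major), s(roi$rel_neigh_major),
         m(roi$rel_neigh_minor), s(roi$rel_neigh_minor),
         m(roi$rel_neigh_relation_axis), s(roi$rel_neigh_relation_axis),
         m(roi$rel_neigh_convex_hull), s(roi$rel_neigh_convex_hull),
         m(roi$strength), s(roi$strength),
         m(roi$clustering), s(roi$clustering),
         m(roi$eccentricity), s(roi$eccentricity),
         m(roi$betweenness), s(roi$betweenness),
         global_metrics(graph))
  names(v) <- image_feature_names
  structure(v, image_id = image_id, condition = condition,
            class = c("image_features", "numeric"))
}

#' One-call per-image feature extraction
#'
#' Convenience wrapper: extracts cells, builds the contact graph, fills
#' neighbour relations and node metrics, and returns everything.
#'
#' @param image a `label_image`.
#' @param r neighbour radius in px.
#' @param image_id identifier for the image.
#' @return list with `cells` (complete `cell_table`), `graph`
#'   (`contact_graph`) and `features` (length-40 `image_features`).
#' @export
compute_image_features <- function(image, r = 4, image_id = NA_character_) {
  cells <- extract_cells(image)
  graph <- build_contact_graph(image, r = r)
  cells$n_sides <- polygon_class(graph)
  nm <- node_metrics(graph)
  cells$strength <- nm$strength
  cells$clustering <- nm$clustering
  cells$eccentricity <- nm$eccentricity
  cells$betweenness <- nm$betweenness
  cells <- fill_neighbor_relations(cells, graph)
  list(cells = cells, graph = graph,
       features = image_feature_vector(cells, graph, image_id = image_id,
                                       condition = image$condition))
}

#' The 14-feature matrix of in-ROI cells
#'
#' Rows are in-ROI cells, columns the 14 correlation-assay characteristics
#' in [cell_feature_names] order.
#'
#' @param cells a complete `cell_table`.
#' @return numeric matrix (n_roi x 14) with rownames = cell ids.
#' @export
cell_feature_matrix <- function(cells) {
  roi <- cells[cells$in_roi, ]
  m <- as.matrix(roi[, cell_feature_names])
  if (anyNA(m)) stop("unset feature(s) in cell table", call. = FALSE)
  rownames(m) <- roi$cell_id
  m
}

#' Write / read a contact graph as GraphML
#'
#' Node attributes: centroid (`row`, `col`), `in_roi`, and `n_sides`
#' (degree); edge attribute `weight`.
#'
#' @param graph a `contact_graph`.
#' @param path file path (.graphml).
#' @export
write_contact_graph <- function(graph, path) {
  g <- igraph::set_vertex_attr(graph$graph, "n_sides",
                               value = polygon_class(graph))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_contact_graph
#' @param r the neighbour radius recorded on the restored object.
#' @export
read_contact_graph <- function(path, r = 4) {
  g <- igraph::read_graph(path, format = "graphml")
  structure(list(graph = g, r = r, n_cells = igraph::vcount(g)),
            class = "contact_graph")
}
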