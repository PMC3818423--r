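## Per-cell geometric features and neighbour-relation features.

#' Extract per-cell geometric features from a label image
#'
#' Computes, for every labelled region (including out-of-ROI cells, which are
#' needed later as neighbours): centroid, area (px^2), major/minor axis of
#' the ellipse with identical normalized second central moments (regionprops
#' convention, with the 1/12 pixel-extent correction), their ratio
#' (`relation_axis` >= 1), and the convex-hull ratio (pixel area divided by
#' the area of the convex hull of the pixel corners; 1 for convex regions).
#' Neighbour-relation and network columns are initialized to `NA` and filled
#' by [fill_neighbor_relations()] and [node_metrics()].
#'
#' @param image a `label_image`.
#' @return data.frame of class `cell_table`, one row per cell.
#' @export
extract_cells <- function(image) {
  lab <- image$labels
  n <- max(lab)
  if (n < 1L) stop("no cells: label image is empty", call. = FALSE)
  fg <- which(lab > 0L)
  l <- lab[fg]
  h <- nrow(lab)
  ## pixel centres, 0-based frame: centre of pixel (i,j) is (i-0.5, j-0.5)
  r <- ((fg - 1L) %% h) + 0.5
  c <- ((fg - 1L) %/% h) + 0.5
  area <- tabulate(l, n)
  if (any(area == 0L)) stop("label image has empty labels", call. = FALSE)
  rbar <- rowsum(r, l)[, 1] / area
  cbar <- rowsum(c, l)[, 1] / area
  ## second central moments + 1/12 pixel-extent correction
  mrr <- rowsum(r^2, l)[, 1] / area - rbar^2 + 1 / 12
  mcc <- rowsum(c^2, l)[, 1] / area - cbar^2 + 1 / 12
  mrc <- rowsum(r * c, l)[, 1] / area - rbar * cbar
  tr2 <- (mrr + mcc) / 2
  det <- sqrt(pmax(((mrr - mcc) / 2)^2 + mrc^2, 0))
  l1 <- tr2 + det
  l2 <- pmax(tr2 - det, 1e-12)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  hull_ratio <- convex_hull_ratios(lab, n, fg, l, r, c, area)
  roi_cells <- attr(image, "roi_cells")
  if (is.null(roi_cells))
    roi_cells <- sort(unique(lab[image$roi_mask & lab > 0L]))
  out <- data.frame(cell_id = seq_len(n),
                    row = rbar, col = cbar,
                    in_roi = seq_len(n) %in% roi_cells,
                    area = as.numeric(area),
                    major_axis = major, minor_axis = minor,
                    relation_axis = major / minor,
                    convex_hull_ratio = hull_ratio)
  for (f in c("rel_neigh_area", "rel_neigh_major", "rel_neigh_minor",
              "rel_neigh_relation_axis", "rel_neigh_convex_hull",
              "n_sides", "strength", "clustering", "eccentricity",
              "betweenness"))
    out[[f]] <- NA_real_
  class(out) <- c("cell_table", "data.frame")
  out
}

## convex hull area from pixel corners; only region-boundary pixels matter
convex_hull_ratios <- function(lab, n, fg, l, r, c, area) {
  h <- nrow(lab); w <- ncol(lab)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- lab
  ctr <- pad[2:(h + 1L), 2:(w + 1L)]
  edge <- (pad[1:h, 2:(w + 1L)] != ctr) | (pad[3:(h + 2L), 2:(w + 1L)] != ctr) |
          (pad[2:(h + 1L), 1:w] != ctr) | (pad[2:(h + 1L), 3:(w + 2L)] != ctr)
  bidx <- which(ctr > 0L & edge)
  bl <- lab[bidx]
  br <- ((bidx - 1L) %% h) + 0.5
  bc <- ((bidx - 1L) %/% h) + 0.5
  ord <- order(bl)
  bl <- bl[ord]; br <- br[ord]; bc <- bc[ord]
  starts <- c(1L, which(diff(bl) > 0L) + 1L, length(bl) + 1L)
  ratio <- numeric(n)
  for (k in seq_len(n)) {
    i0 <- starts[k]; i1 <- starts[k + 1L] - 1L
    rr <- br[i0:i1]; cc <- bc[i0:i1]
    ## the 4 corners of each boundary pixel
    pr <- c(rr - 0.5, rr - 0.5, rr + 0.5, rr + 0.5)
    pc <- c(cc - 0.5, cc + 0.5, cc - 0.5, cc + 0.5)
    hull <- grDevices::chull(pc, pr)
    hx <- pc[hull]; hy <- pr[hull]
    a2 <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy))
    ratio[k] <- min(area[k] / (a2 / 2), 1)
  }
  ratio
}

#' Fill neighbour-relation features
#'
#' For each cell with at least one contact-graph neighbour and each base
#' feature f in {area, major_axis, minor_axis, relation_axis,
#' convex_hull_ratio}, sets `rel_neigh_f = f(cell) / mean(f over graph
#' neighbours)`. Values near 1 mean the cell resembles its neighbourhood.
#' An in-ROI cell with no neighbours is a segmentation fault upstream and
#' raises an error.
#'
#' @param cells a `cell_table` from [extract_cells()].
#' @param graph a `contact_graph` built on the same image.
#' @return the `cell_table` with the five `rel_neigh_*` columns filled.
#' @export
fill_neighbor_relations <- function(cells, graph) {
  g <- graph$graph
  stopifnot(igraph::vcount(g) == nrow(cells))
  adj <- igraph::as_adj_list(g, mode = "all")
  deg <- lengths(adj)
  if (any(deg == 0L & cells$in_roi))
    stop("in-ROI cell(s) with zero neighbours: ",
         paste(which(deg == 0L & cells$in_roi), collapse = ","), call. = FALSE)
  base <- c(area = "area", major = "major_axis", minor = "minor_axis",
            relation_axis = "relation_axis", convex_hull = "convex_hull_ratio")
  rel <- c("rel_neigh_area", "rel_neigh_major", "rel_neigh_minor",
           "rel_neigh_relation_axis", "rel_neigh_convex_hull")
  for (j in seq_along(base)) {
    v <- cells[[base[j]]]
    nm <- vapply(adj, function(a) if (length(a)) mean(v[as.integer(a)]) else NA_real_,
                 numeric(1))
    cells[[rel[j]]] <- v / nm
  }
  cells
}

#' Write / read a per-cell feature table
#'
#' Plain CSV, one row per cell, fixed documented column order (the order of
#' [extract_cells()] output).
#'
#' @param cells a `cell_table`.
#' @param path file path.
#' @export
write_cell_table <- function(cells, path) {
  write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  out <- read.csv(path)
  class(out) <- c("cell_table", "data.frame")
  out
}
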