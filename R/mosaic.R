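## Synthetic epithelial mosaics: hardcore Voronoi tessellation with Lloyd
## relaxation and a controllable polygon-distribution shift.

#' Specification of a synthetic epithelial mosaic
#'
#' Describes one synthetic confluent epithelium: a Voronoi tessellation of
#' hardcore-sampled seed points in a pixel frame, optionally regularized by
#' Lloyd (centroidal) relaxation. `polygon_shift` interpolates the seed
#' points toward a more relaxed (positive shift, more hexagons -- the
#' prepupa-like direction) or a less ordered (negative shift, fewer hexagons)
#' configuration, producing small, smooth changes in the polygon-class
#' distribution like those seen between consecutive developmental stages.
#'
#' Defaults emulate a proliferating wing-disc field: ~515 cells per
#' 512x512 image and, at `lloyd_iterations = 2`, interior polygon-class
#' frequencies near 3% tetragons / 23% pentagons / 46% hexagons /
#' 24% heptagons.
#'
#' @param n_cells number of cells (>= 1).
#' @param image_size integer `(width, height)` in pixels, each >= 32.
#' @param lloyd_iterations non-negative integer; Lloyd relaxation steps
#'   applied to the seed points (regularity knob).
#' @param polygon_shift real in `[-1, 1]`; 0 is the baseline condition.
#' @param seed integer RNG seed; the same `(spec, seed)` always yields a
#'   bit-identical label image.
#' @return an object of class `mosaic_spec`.
#' @seealso [generate_mosaic()], [generate_condition_pair()]
#' @export
mosaic_spec <- function(n_cells = 515L, image_size = c(512L, 512L),
                        lloyd_iterations = 2L, polygon_shift = 0,
                        seed = 1L) {
  stopifnot(length(n_cells) == 1L, n_cells >= 1,
            length(image_size) == 2L, all(image_size >= 32),
            length(lloyd_iterations) == 1L, lloyd_iterations >= 0,
            length(polygon_shift) == 1L, is.finite(polygon_shift),
            polygon_shift >= -1, polygon_shift <= 1,
            length(seed) == 1L, is.finite(seed))
  structure(list(n_cells = as.integer(n_cells),
                 image_size = as.integer(image_size),
                 lloyd_iterations = as.integer(lloyd_iterations),
                 polygon_shift = as.numeric(polygon_shift),
                 seed = as.integer(seed)),
            class = "mosaic_spec")
}

#' @export
print.mosaic_spec <- function(x, ...) {
  cat(sprintf("<mosaic_spec> %d cells, %dx%d px, lloyd=%d, shift=%+.2f, seed=%d\n",
              x$n_cells, x$image_size[1], x$image_size[2],
              x$lloyd_iterations, x$polygon_shift, x$seed))
  invisible(x)
}

## pixel-centre grid of an h x w frame, (row, col), column-major order
pixel_grid <- function(w, h) {
  cbind(rep(seq_len(h) - 0.5, times = w), rep(seq_len(w) - 0.5, each = h))
}

## nearest-seed label for every pixel centre; deterministic tie-break
## (lowest seed index)
assign_nearest <- function(pts, w, h) {
  .nearest_seed(pts, as.integer(w), as.integer(h))
}

## one Lloyd step: move each seed to the centroid of its pixel region
lloyd_relax <- function(pts, w, h, iterations) {
  if (iterations == 0L) return(pts)
  grid <- pixel_grid(w, h)
  for (i in seq_len(iterations)) {
    lab <- as.vector(assign_nearest(pts, w, h))
    n <- tabulate(lab, nrow(pts))
    keep <- n > 0L
    sums <- rowsum(grid, lab)
    pts[as.integer(rownames(sums)), ] <- sums / n[keep]
  }
  pts
}

## hardcore (minimum-separation) uniform sampling in the frame interior;
## separation is a fraction of the mean inter-cell spacing sqrt(w*h/n)
sample_hardcore <- function(n, w, h, min_sep_frac = 0.5) {
  sep2 <- (min_sep_frac * sqrt(w * h / n))^2
  pts <- matrix(NA_real_, n, 2)
  k <- 0L
  tries <- 0L
  max_tries <- 300L * n
  while (k < n) {
    m <- max(16L, n - k)
    cand <- cbind(runif(m, 1, h - 1), runif(m, 1, w - 1))
    for (i in seq_len(m)) {
      tries <- tries + 1L
      if (k > 0L) {
        d2 <- (pts[seq_len(k), 1] - cand[i, 1])^2 +
              (pts[seq_len(k), 2] - cand[i, 2])^2
        if (min(d2) < sep2) {
          if (tries > max_tries)
            stop("overcrowded: cannot place ", n, " cells with minimum ",
                 "separation in a ", w, "x", h, " frame", call. = FALSE)
          next
        }
      }
      k <- k + 1L
      pts[k, ] <- cand[i, ]
      if (k == n) break
    }
  }
  pts
}

## background boundary: pixel whose right or down neighbour carries a
## different label, plus the 1-px frame border
draw_boundaries <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  bg <- matrix(FALSE, h, w)
  d <- lab[-h, ] != lab[-1, ]
  bg[-h, ][d] <- TRUE
  d <- lab[, -w] != lab[, -1]
  bg[, -w][d] <- TRUE
  out <- lab
  out[bg] <- 0L
  out[c(1L, h), ] <- 0L
  out[, c(1L, w)] <- 0L
  out
}

## labels touching the frame border of the pre-boundary assignment
border_labels <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  sort(unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w])))
}

#' Construct a label image from a segmentation matrix
#'
#' Wraps an integer label matrix (0 = background/membrane, k >= 1 = cell k)
#' as a `label_image`. With a mask, a cell is in the ROI when all its
#' pixels fall inside the mask (the mask author decides about border
#' cells). Without one, the ROI defaults to the cells with no pixel in the
#' outer `border_band` pixels of the frame; excluded cells still serve as
#' neighbours.
#'
#' @param labels integer matrix of cell labels.
#' @param roi_mask optional logical matrix of the same shape.
#' @param condition optional condition tag.
#' @param border_band width in px of the border exclusion zone used when no
#'   mask is given.
#' @return a `label_image`.
#' @export
label_image <- function(labels, roi_mask = NULL, condition = NA_character_,
                        border_band = 2L) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  h <- nrow(labels); w <- ncol(labels)
  n <- max(labels)
  if (n < 1L) stop("no cells", call. = FALSE)
  if (!is.null(roi_mask)) {
    stopifnot(dim(roi_mask) == dim(labels))
    outside <- unique(labels[!roi_mask & labels > 0L])
    roi_cells <- setdiff(seq_len(n), outside)
  } else {
    b <- seq_len(border_band)
    touching <- unique(c(labels[b, ], labels[h + 1L - b, ],
                         labels[, b], labels[, w + 1L - b]))
    roi_cells <- setdiff(seq_len(n), touching)
  }
  mask <- matrix(labels %in% roi_cells, h, w)
  structure(list(labels = labels, roi_mask = mask, condition = condition,
                 seeds = NULL, spec = NULL),
            class = "label_image", roi_cells = roi_cells)
}

#' Validate a label image
#'
#' Checks the structural invariants of a segmented mosaic: labels are
#' exactly `1..n` with no gaps, and every labelled region is a single
#' 4-connected component.
#'
#' @param image a `label_image`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_label_image <- function(image) {
  lab <- image$labels
  n <- max(lab)
  cnt <- tabulate(lab[lab > 0L], n)
  if (any(cnt == 0L))
    stop("label integrity: labels ", paste(which(cnt == 0L), collapse = ","),
         " have no pixels", call. = FALSE)
  comp <- label_components4(lab)
  if (any(comp$n_components > 1L))
    stop("label integrity: labels ",
         paste(which(comp$n_components > 1L), collapse = ","),
         " are not 4-connected", call. = FALSE)
  invisible(TRUE)
}

## clear stray minor fragments: where boundary drawing severs a thin wedge
## tip from its cell, keep the largest 4-connected component of each label
## and turn the rest into background
repair_minor_components <- function(lab) {
  pc <- pixel_components4(lab)
  if (all(pc$n_components == 1L)) return(lab)
  l <- pc$label; m <- pc$membership
  sz <- table(factor(m))
  ord <- order(l, -as.numeric(sz[as.character(m)]), m)
  best <- m[ord[!duplicated(l[ord])]]       # largest component per label
  names(best) <- l[ord[!duplicated(l[ord])]]
  drop <- pc$pixel[m != best[as.character(l)]]
  lab[drop] <- 0L
  lab
}

## 4-connected components of the foreground pixels, per label, via igraph
## on the pixel adjacency restricted to equal labels
pixel_components4 <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  idx <- matrix(seq_len(h * w), h, w)
  vert <- which(lab[-h, ] > 0L & lab[-h, ] == lab[-1, ])
  horiz <- which(lab[, -w] > 0L & lab[, -w] == lab[, -1])
  e1 <- cbind(idx[-h, ][vert], idx[-1, ][vert])
  e2 <- cbind(idx[, -w][horiz], idx[, -1][horiz])
  fg <- which(lab > 0L)
  remap <- integer(h * w)
  remap[fg] <- seq_along(fg)
  edges <- rbind(e1, e2)
  g <- igraph::graph_from_edgelist(cbind(remap[edges[, 1]], remap[edges[, 2]]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  n <- max(lab)
  u <- unique(lab[fg] + n * (memb - 1))     # (label, component) pairs
  list(pixel = fg, label = lab[fg], membership = memb,
       n_components = tabulate((u - 1) %% n + 1, n))
}

label_components4 <- function(lab) pixel_components4(lab)

#' Generate a synthetic epithelial mosaic
#'
#' Produces a confluent polygonal tessellation as an integer label image:
#' seed points are hardcore-sampled, Lloyd-relaxed `lloyd_iterations` times,
#' optionally interpolated toward a more/less relaxed configuration
#' (`polygon_shift`), and every pixel is assigned to its nearest seed.
#' Regions are separated by 1-px background boundaries (label 0) and the
#' frame border is background. The ROI is the set of cells that do not touch
#' the image border; border cells are kept so that ROI cells have a full
#' neighbourhood.
#'
#' @param spec a [mosaic_spec()].
#' @param points optional n x 2 matrix of (row, col) seed points overriding
#'   the random placement (e.g. a hexagonal lattice for ground-truth tests);
#'   Lloyd relaxation and shift are skipped when given.
#' @param condition optional condition tag ("A"/"B", ...) stored on the image.
#' @return an object of class `label_image`: a list with `labels` (h x w
#'   integer matrix, 0 = background), `roi_mask` (logical matrix, pixels of
#'   in-ROI cells), `condition`, `seeds` (the generator points, ground
#'   truth), and `spec`.
#' @export
generate_mosaic <- function(spec, points = NULL, condition = NA_character_) {
  stopifnot(inherits(spec, "mosaic_spec"))
  w <- spec$image_size[1]; h <- spec$image_size[2]
  n <- spec$n_cells
  if (9L * n > (w - 2L) * (h - 2L))
    stop("overcrowded: ", n, " cells do not fit in a ", w, "x", h,
         " frame (need >= 9 px per cell)", call. = FALSE)
  for (attempt in 0:4) {
    if (is.null(points)) {
      set.seed(spec$seed + 1000003L * attempt)
      pts <- sample_hardcore(n, w, h)
      pts <- lloyd_relax(pts, w, h, spec$lloyd_iterations)
      s <- spec$polygon_shift
      if (s > 0) {
        relaxed <- lloyd_relax(pts, w, h, 4L)
        pts <- (1 - s) * pts + s * relaxed
      } else if (s < 0) {
        rough <- cbind(runif(n, 1, h - 1), runif(n, 1, w - 1))
        pts <- (1 + s) * pts + (-s) * rough
      }
    } else {
      stopifnot(nrow(points) == n, ncol(points) == 2)
      pts <- points
    }
    assign <- assign_nearest(pts, w, h)
    lab <- repair_minor_components(draw_boundaries(assign))
    img <- structure(list(labels = lab,
                          roi_mask = NULL,
                          condition = condition,
                          seeds = pts,
                          spec = spec),
                     class = "label_image")
    ok <- tryCatch({ validate_label_image(img); TRUE },
                   error = function(e) FALSE)
    if (ok || !is.null(points)) {
      roi_cells <- setdiff(seq_len(n), border_labels(assign))
      img$roi_mask <- matrix(lab %in% roi_cells, nrow(lab), ncol(lab))
      attr(img, "roi_cells") <- roi_cells
      if (!ok)
        warning("user-supplied points produced a degenerate tessellation",
                call. = FALSE)
      return(img)
    }
  }
  stop("overcrowded: could not produce a valid tessellation for this spec",
       call. = FALSE)
}

#' @export
print.label_image <- function(x, ...) {
  n <- max(x$labels)
  cat(sprintf("<label_image> %dx%d px, %d cells (%d in ROI)%s\n",
              ncol(x$labels), nrow(x$labels), n, length(attr(x, "roi_cells")),
              if (is.na(x$condition)) "" else paste0(", condition ", x$condition)))
  invisible(x)
}

#' @export
plot.label_image <- function(x, ...) {
  graphics::image(t(x$labels)[, nrow(x$labels):1], col = c("black",
                  grDevices::hcl.colors(max(x$labels), "Spectral")),
                  axes = FALSE, asp = nrow(x$labels) / ncol(x$labels), ...)
  invisible(x)
}

#' Generate a two-condition set of synthetic mosaics
#'
#' Emulates a two-stage study design: `n_images_A` images drawn from
#' `specA` (condition "A") and `n_images_B` from `specB` (condition "B"),
#' with per-image seeds derived deterministically from `seed`. With equal
#' specs (`polygon_shift` difference 0) the two groups are exchangeable.
#'
#' @param specA,specB [mosaic_spec()] for each condition (their `seed`
#'   fields are replaced by derived per-image seeds).
#' @param n_images_A,n_images_B number of images per condition (>= 2).
#' @param seed integer master seed.
#' @return list of `label_image`, conditions "A" then "B".
#' @export
generate_condition_pair <- function(specA, specB, n_images_A = 15L,
                                    n_images_B = 16L, seed = 1L) {
  stopifnot(n_images_A >= 2, n_images_B >= 2)
  set.seed(seed)
  sub <- sample.int(2147480000L, n_images_A + n_images_B)
  imgs <- vector("list", n_images_A + n_images_B)
  for (i in seq_len(n_images_A)) {
    sp <- specA; sp$seed <- sub[i]
    imgs[[i]] <- generate_mosaic(sp, condition = "A")
  }
  for (j in seq_len(n_images_B)) {
    sp <- specB; sp$seed <- sub[n_images_A + j]
    imgs[[n_images_A + j]] <- generate_mosaic(sp, condition = "B")
  }
  imgs
}

#' Points of a hexagonal lattice filling a frame
#'
#' Utility for ground-truth tests: returns (row, col) points of a triangular
#' lattice with the given spacing, whose Voronoi tessellation is a honeycomb.
#'
#' @param w,h frame size in pixels.
#' @param spacing centre-to-centre distance in px.
#' @return matrix with columns (row, col).
#' @export
hexagonal_lattice <- function(w, h, spacing = 24) {
  dy <- spacing * sqrt(3) / 2
  rows <- seq(2, h - 2, by = dy)
  pts <- lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    cols <- seq(2 + off, w - 2, by = spacing)
    cbind(rows[i], cols)
  })
  do.call(rbind, pts)
}

#' Write / read a label image
#'
#' Writes `<prefix>_labels.tif` (16-bit single-channel TIFF, label =
#' intensity), `<prefix>_roi.tif` (binary mask) and `<prefix>.json` (spec,
#' seed, condition). `read_label_image()` restores the `label_image`
#' (without ground-truth seed points, which live only in memory). A missing
#' ROI file defaults the ROI to non-border cells.
#'
#' @param image a `label_image`.
#' @param prefix path prefix for the three files.
#' @return `prefix`, invisibly; `read_label_image()` returns a `label_image`.
#' @export
write_label_image <- function(image, prefix) {
  if (max(image$labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(image$labels / 65535, paste0(prefix, "_labels.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(image$roi_mask * 1.0, paste0(prefix, "_roi.tif"),
                  bits.per.sample = 8L)
  side <- list(condition = image$condition,
               spec = if (!is.null(image$spec)) unclass(image$spec))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(prefix) {
  lab <- round(tiff::readTIFF(paste0(prefix, "_labels.tif")) * 65535)
  storage.mode(lab) <- "integer"
  roi_path <- paste0(prefix, "_roi.tif")
  roi_defaulted <- !file.exists(roi_path)
  roi <- if (roi_defaulted) {
    ## no ROI mask deposited: default to cells not touching the border
    h <- nrow(lab); w <- ncol(lab)
    near <- unique(c(lab[1:2, ], lab[(h - 1):h, ], lab[, 1:2],
                     lab[, (w - 1):w]))
    matrix(!(lab %in% near) & lab > 0L, h, w)
  } else tiff::readTIFF(roi_path) > 0.5
  side <- jsonlite::read_json(paste0(prefix, ".json"))
  spec <- if (!is.null(side$spec))
    do.call(mosaic_spec, side$spec[c("n_cells", "image_size",
                                     "lloyd_iterations", "polygon_shift",
                                     "seed")])
  roi_cells <- sort(unique(lab[roi & lab > 0L]))
  structure(list(labels = lab, roi_mask = roi,
                 condition = if (is.null(side$condition)) NA_character_
                             else side$condition,
                 seeds = NULL, spec = spec),
            class = "label_image", roi_cells = roi_cells,
            roi_defaulted = roi_defaulted)
}
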