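## Polygon (cell-side) distribution and the two-group MANOVA comparison.

#' Polygon distribution of a contact graph
#'
#' Per-class frequencies of the number of sides (contact-graph neighbours)
#' over in-ROI cells only. Side classes 3..10 are always reported; classes
#' observed outside that range are appended so that frequencies sum to 1.
#'
#' @param graph a `contact_graph`.
#' @param image_id,condition identifiers carried on the result.
#' @return object of class `polygon_distribution`: list with `counts`
#'   (named integer vector by side class), `frequencies`, `n_cells`,
#'   `image_id`, `condition`.
#' @export
polygon_distribution <- function(graph, image_id = NA_character_,
                                 condition = NA_character_) {
  roi <- which(igraph::V(graph$graph)$in_roi)
  if (!length(roi)) stop("no in-ROI cells", call. = FALSE)
  deg <- polygon_class(graph)[roi]
  classes <- sort(unique(c(3:10, deg)))
  counts <- vapply(classes, function(k) sum(deg == k), integer(1))
  names(counts) <- classes
  structure(list(counts = counts,
                 frequencies = counts / length(deg),
                 n_cells = length(deg),
                 image_id = image_id, condition = condition),
            class = "polygon_distribution")
}

#' @export
print.polygon_distribution <- function(x, ...) {
  cat(sprintf("<polygon_distribution> %d in-ROI cells%s\n", x$n_cells,
              if (is.na(x$condition)) "" else paste0(" (", x$condition, ")")))
  print(round(x$frequencies, 3))
  invisible(x)
}

#' @export
plot.polygon_distribution <- function(x, ...) {
  graphics::barplot(x$frequencies, xlab = "number of sides",
                    ylab = "frequency", ...)
  invisible(x)
}

## n x 5 response matrix of class 4..8 frequencies
polygon_response_matrix <- function(dists) {
  t(vapply(dists, function(d) {
    f <- d$frequencies[as.character(4:8)]
    f[is.na(f)] <- 0
    unname(f)
  }, numeric(5)))
}

#' Two-group MANOVA on polygon distributions
#'
#' One-way two-group MANOVA on the 5-vector of class-4..8 frequencies
#' (classes 3, 9 and 10 are discarded as not present in all images).
#' Reports Wilks' lambda with Rao's F approximation (exact for two groups);
#' the groups are declared different when p < 0.05. With two groups all
#' four classic MANOVA statistics are equivalent.
#'
#' @param groupA,groupB lists of `polygon_distribution`.
#' @return object of class `manova_polygons`: list with `wilks_lambda`,
#'   `F`, `df` (num, den), `p`, `different`.
#' @export
manova_polygons <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 6L || nB < 6L)
    stop("each group needs >= 6 images for 5 response classes",
         call. = FALSE)
  Y <- rbind(polygon_response_matrix(groupA), polygon_response_matrix(groupB))
  g <- factor(rep(c("A", "B"), c(nA, nB)))
  res <- Y - rbind(matrix(colMeans(Y[1:nA, , drop = FALSE]), nA, 5,
                          byrow = TRUE),
                   matrix(colMeans(Y[-(1:nA), , drop = FALSE]), nB, 5,
                          byrow = TRUE))
  if (qr(res)$rank < 5L)
    stop("singular within-group covariance; pool polygon classes",
         call. = FALSE)
  fit <- stats::manova(Y ~ g)
  st <- summary(fit, test = "Wilks")$stats
  out <- list(wilks_lambda = unname(st[1, "Wilks"]),
              F = unname(st[1, "approx F"]),
              df = unname(c(st[1, "num Df"], st[1, "den Df"])),
              p = unname(st[1, "Pr(>F)"]))
  out$different <- is.finite(out$p) && out$p < 0.05
  class(out) <- "manova_polygons"
  out
}

#' @export
print.manova_polygons <- function(x, ...) {
  cat(sprintf("Polygon-distribution MANOVA (classes 4-8): Wilks = %.4f, F(%g, %g) = %.3f, p = %.4g%s\n",
              x$wilks_lambda, x$df[1], x$df[2], x$F, x$p,
              if (x$different) "  [groups differ]" else ""))
  invisible(x)
}

#' Write per-image polygon distributions as CSV
#'
#' One row per image: image_id, condition, n_cells, then one column per
#' side class.
#'
#' @param dists list of `polygon_distribution`.
#' @param path file path.
#' @export
write_polygon_distributions <- function(dists, path) {
  classes <- sort(unique(unlist(lapply(dists, function(d)
    as.integer(names(d$counts))))))
  rows <- lapply(dists, function(d) {
    f <- d$frequencies[as.character(classes)]
    f[is.na(f)] <- 0
    as.data.frame(c(list(image_id = d$image_id, condition = d$condition,
                         n_cells = d$n_cells),
                    stats::setNames(as.list(unname(f)),
                                    paste0("class_", classes))))
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a MANOVA report as JSON
#' @param m a `manova_polygons` result.
#' @param path file path.
#' @export
write_manova_report <- function(m, path) {
  jsonlite::write_json(list(wilks_lambda = m$wilks_lambda, F = m$F,
                            df1 = m$df[1], df2 = m$df[2], p = m$p,
                            different = m$different),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
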