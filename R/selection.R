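## Normalization, PCA projection, the separation descriptor, the beam-search
## feature selection and the group-label randomization null.

#' Construct an image feature table
#'
#' Images x characteristics matrix with condition labels for two groups.
#'
#' @param mat numeric matrix (images x features), finite entries.
#' @param image_ids character vector of image identifiers.
#' @param conditions condition label per image (two groups for the
#'   comparison operations).
#' @param normalized whether `mat` is already min-max normalized.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(mat, image_ids = rownames(mat), conditions,
                          normalized = FALSE) {
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) stop("non-finite entries", call. = FALSE)
  if (is.null(image_ids)) image_ids <- sprintf("img%03d", seq_len(nrow(mat)))
  stopifnot(length(image_ids) == nrow(mat),
            length(conditions) == nrow(mat))
  if (is.null(colnames(mat)) && ncol(mat) == 40)
    colnames(mat) <- image_feature_names
  structure(list(matrix = mat, image_ids = as.character(image_ids),
                 conditions = as.character(conditions),
                 normalized = isTRUE(normalized)),
            class = "feature_table")
}

#' Combine per-image feature vectors into a feature table
#' @param features list of `image_features` vectors.
#' @return a `feature_table` (unnormalized).
#' @export
feature_table_from_images <- function(features) {
  mat <- do.call(rbind, lapply(features, as.numeric))
  colnames(mat) <- image_feature_names
  feature_table(mat,
                image_ids = vapply(features, attr, "", "image_id"),
                conditions = vapply(features, attr, "", "condition"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d images x %d characteristics (%s), groups: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$normalized) "normalized" else "raw",
              paste(sprintf("%s=%d", names(table(x$conditions)),
                            table(x$conditions)), collapse = ", ")))
  invisible(x)
}

#' Min-max normalize a feature table
#'
#' Per-column rescaling to `[0, 1]` (see [normalize_minmax()]); idempotent.
#'
#' @param table a `feature_table`.
#' @return the normalized `feature_table`.
#' @export
normalize_features <- function(table) {
  if (table$normalized) return(table)
  table$matrix <- normalize_minmax(table$matrix)
  table$normalized <- TRUE
  table
}

#' Project images on the two leading principal components
#'
#' Column-centred data projected on the top-2 eigenvectors of the covariance
#' matrix of the chosen features. Sign convention: in each component the
#' largest-magnitude loading is positive.
#'
#' @param table a normalized `feature_table`.
#' @param features integer indices of the features to use (>= 2).
#' @return images x 2 score matrix with attributes `loadings` and `sdev`.
#' @export
pca_project <- function(table, features) {
  stopifnot(length(features) >= 2)
  X <- table$matrix[, features, drop = FALSE]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (qr(Xc)$rank < 2L) stop("selected features have rank < 2", call. = FALSE)
  e <- eigen(stats::cov(X), symmetric = TRUE)
  V <- e$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  scores <- Xc %*% V
  colnames(scores) <- c("PC1", "PC2")
  rownames(scores) <- table$image_ids
  attr(scores, "loadings") <- V
  attr(scores, "sdev") <- sqrt(pmax(e$values[1:2], 0))
  scores
}

#' Group-separation descriptor on a 2D projection
#'
#' Calinski-Harabasz style ratio on the two-dimensional PC scores: with
#' group centroids c_k, overall centroid c and group sizes N_k,
#' `B = sum_k N_k (c_k - c)(c_k - c)'` and
#' `W = sum_k sum_i (x_ik - c_k)(x_ik - c_k)'`; the descriptor is
#' `trace(B) / trace(W)` (no degrees-of-freedom factor). B and W add up to
#' the total scatter of the scores. Larger values mean compact, separated
#' groups.
#'
#' @param scores images x 2 matrix (from [pca_project()]).
#' @param labels group label per image (two groups, each >= 2 images).
#' @return object of class `descriptor_result`: list with `W`, `B`,
#'   `descriptor`, `pc_scores`.
#' @export
pca_descriptor <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels), ncol(scores) == 2)
  lev <- unique(labels)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  if (any(table(labels) < 2L)) stop("each group needs >= 2 images",
                                    call. = FALSE)
  c_all <- colMeans(scores)
  B <- matrix(0, 2, 2); W <- matrix(0, 2, 2)
  for (l in lev) {
    xk <- scores[labels == l, , drop = FALSE]
    ck <- colMeans(xk)
    B <- B + nrow(xk) * tcrossprod(ck - c_all)
    dev <- sweep(xk, 2, ck)
    W <- W + crossprod(dev)
  }
  trW <- sum(diag(W))
  if (trW <= 0)
    stop("zero within-group scatter: all points per group coincide",
         call. = FALSE)
  structure(list(W = W, B = B, descriptor = sum(diag(B)) / trW,
                 pc_scores = scores),
            class = "descriptor_result")
}

#' @export
print.descriptor_result <- function(x, ...) {
  cat(sprintf("<descriptor_result> trace(B)/trace(W) = %.4f\n", x$descriptor))
  invisible(x)
}

## shared setup for the fast descriptor path
descriptor_context <- function(X, labels) {
  lev <- unique(labels)
  gA <- labels == lev[1]
  nA <- sum(gA); nB <- sum(!gA); N <- nA + nB
  list(S = stats::cov(X),
       d = colMeans(X[gA, , drop = FALSE]) - colMeans(X[!gA, , drop = FALSE]),
       cab = nA * nB / N, nm1 = N - 1)
}

eval_subsets <- function(ctx, subsets) {
  .eval_descriptors(ctx$S, ctx$d, subsets, ctx$cab, ctx$nm1)
}

## deterministic ranking: by descending descriptor, ties by lexicographic
## feature-index order
rank_candidates <- function(desc, subsets) {
  key <- vapply(subsets, function(s) paste(sprintf("%02d", sort(s)),
                                           collapse = ""), "")
  order(-desc, key)
}

#' Beam-search feature selection by separation descriptor
#'
#' Iterative wrapper search over feature subsets maximizing the 2-PC
#' separation descriptor. Iteration 1 evaluates every pair of features and
#' keeps the 10 best; iteration 2 extends each kept pair by every unused
#' feature and keeps the 5 best extensions per pair (50 trios); iteration 3
#' keeps the 2 best per trio (100 quartets); later iterations add one
#' feature per candidate. A branch stops when its descriptor would decrease,
#' and the whole search stops at subsets of 7 features. The result is the
#' best-scoring subset over everything evaluated.
#'
#' @param table a `feature_table` (normalized internally if needed).
#' @param labels group label per image; defaults to `table$conditions`.
#' @param max_size largest subset size (default 7).
#' @return object of class `selection_result`: `selected` (feature indices
#'   in order of addition), `descriptor`, `trace` (per-iteration kept
#'   candidates and scores), `n_evaluated`.
#' @export
select_features <- function(table, labels = NULL, max_size = 7L) {
  table <- normalize_features(table)
  if (is.null(labels)) labels <- table$conditions
  X <- table$matrix
  p <- ncol(X)
  if (p < 2L) stop("fewer than 2 features", call. = FALSE)
  ## zero-variance characteristics carry no information and would make the
  ## projection rank-deficient; they never enter the candidate pool
  eligible <- which(apply(X, 2L, stats::var) > 0)
  if (length(eligible) < 2L)
    stop("fewer than 2 non-constant features", call. = FALSE)
  ctx <- descriptor_context(X, labels)
  keep_per <- c(5L, 2L, rep(1L, max(0L, max_size - 4L)))

  pairs <- combn(eligible, 2L, simplify = FALSE)
  desc <- eval_subsets(ctx, pairs)
  n_eval <- length(pairs)
  ord <- rank_candidates(desc, pairs)[seq_len(min(10L, length(pairs)))]
  branches <- lapply(ord, function(i) list(f = pairs[[i]], d = desc[i]))
  best <- branches[[1L]]
  trace <- list(list(size = 2L,
                     kept = lapply(branches, `[[`, "f"),
                     descriptor = vapply(branches, `[[`, 0, "d")))

  it <- 1L
  while (length(branches) && length(branches[[1L]]$f) < max_size) {
    kp <- if (it <= length(keep_per)) keep_per[it] else 1L
    cand <- list(); parent <- integer(0)
    for (bi in seq_along(branches)) {
      ext <- setdiff(eligible, branches[[bi]]$f)
      cand <- c(cand, lapply(ext, function(e) c(branches[[bi]]$f, e)))
      parent <- c(parent, rep(bi, length(ext)))
    }
    if (!length(cand)) break
    desc <- eval_subsets(ctx, cand)
    n_eval <- n_eval + length(cand)
    new_size <- length(branches[[1L]]$f) + 1L
    new_branches <- list()
    for (bi in seq_along(branches)) {
      ci <- which(parent == bi)
      keep <- ci[rank_candidates(desc[ci], cand[ci])[seq_len(min(kp, length(ci)))]]
      ## full quotas through the quartet stage (10 pairs -> 50 trios ->
      ## 100 quartets); from the one-at-a-time phase on, a branch whose
      ## descriptor decreases is stopped
      if (new_size > 4L)
        keep <- keep[desc[keep] >= branches[[bi]]$d]
      for (k in keep)
        new_branches[[length(new_branches) + 1L]] <-
          list(f = cand[[k]], d = desc[k])
    }
    if (max(desc) > best$d) {
      k <- which.max(desc)
      best <- list(f = cand[[k]], d = desc[k])
    }
    branches <- new_branches
    if (length(branches))
      trace[[length(trace) + 1L]] <-
        list(size = length(branches[[1L]]$f),
             kept = lapply(branches, `[[`, "f"),
             descriptor = vapply(branches, `[[`, 0, "d"))
    it <- it + 1L
  }
  res <- structure(list(selected = best$f, descriptor = best$d,
                        trace = trace, n_evaluated = n_eval,
                        labels = labels, table = table),
                   class = "selection_result")
  ## self-check: fast path must agree with the direct scatter computation
  direct <- pca_descriptor(pca_project(table, best$f), labels)$descriptor
  stopifnot(abs(direct - best$d) < 1e-8 * max(1, abs(direct)))
  res
}

#' @export
print.selection_result <- function(x, ...) {
  nm <- colnames(x$table$matrix)[x$selected]
  cat(sprintf("<selection_result> %d features, descriptor = %.4f\n",
              length(x$selected), x$descriptor))
  cat("  selected (in order of addition): ",
      paste(sprintf("%d (%s)", x$selected, nm), collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  %d candidate subsets evaluated over %d iterations\n",
              x$n_evaluated, length(x$trace)))
  invisible(x)
}

#' @export
summary.selection_result <- function(object, ...) {
  sizes <- vapply(object$trace, `[[`, 0L, "size")
  pool <- vapply(object$trace, function(t) length(t$kept), 0L)
  best <- vapply(object$trace, function(t) max(t$descriptor), 0)
  data.frame(size = sizes, pool = pool, best_descriptor = best)
}

#' @export
plot.selection_result <- function(x, ...) {
  sc <- pca_project(x$table, x$selected)
  grp <- factor(x$labels)
  graphics::plot(sc, col = as.integer(grp) + 1L, pch = 19,
                 xlab = "PC1", ylab = "PC2", ...)
  graphics::legend("topright", legend = levels(grp),
                   col = seq_along(levels(grp)) + 1L, pch = 19)
  invisible(x)
}

## mixA/mixB design: half of each condition (rounded up) goes to mixA
randomization_design <- function(conditions) {
  lev <- unique(conditions)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  idxA <- which(conditions == lev[1]); idxB <- which(conditions == lev[2])
  if (length(idxA) < 2L || length(idxB) < 2L)
    stop("randomization needs >= 2 images per condition; got ",
         length(idxA), " and ", length(idxB), call. = FALSE)
  list(idxA = idxA, idxB = idxB,
       takeA = as.integer(ceiling(length(idxA) / 2)),
       takeB = as.integer(ceiling(length(idxB) / 2)))
}

#' Group-label randomization null
#'
#' Repeatedly reshuffles the images into two arbitrary groups mixA / mixB
#' (mixA takes half of each condition, rounded up -- for the 15+16 design
#' this is the classic 8+8 versus 8+7 split), re-runs the beam-search
#' feature selection and the polygon MANOVA for every reshuffle, and
#' reports both series together with the real-label values and their
#' percentile ranks.
#'
#' @param table a `feature_table` with two conditions.
#' @param dists list of `polygon_distribution` aligned with the table rows
#'   (omit to skip the MANOVA series).
#' @param n_loops number of randomization loops (0 = only real-label values).
#' @param seed RNG seed.
#' @return object of class `randomization_result`: data.frame `loops`
#'   (descriptor, manova_p per loop), `real_descriptor`, `real_p`,
#'   `descriptor_percentile`, `p_percentile`.
#' @export
randomize_groups <- function(table, dists = NULL, n_loops = 4000L,
                             seed = 1L) {
  table <- normalize_features(table)
  des <- randomization_design(table$conditions)
  Y <- if (!is.null(dists)) {
    stopifnot(length(dists) == nrow(table$matrix))
    polygon_response_matrix(dists)
  }
  wilks_p <- function(groups) {
    g <- factor(groups)
    st <- summary(stats::manova(Y ~ g), test = "Wilks")$stats
    unname(st[1, "Pr(>F)"])
  }
  real <- select_features(table)
  real_p <- if (!is.null(Y)) wilks_p(table$conditions) else NA_real_
  loops <- data.frame(loop = integer(0), descriptor = numeric(0),
                      manova_p = numeric(0))
  if (n_loops > 0) {
    set.seed(seed)
    n <- nrow(table$matrix)
    desc <- numeric(n_loops); pv <- rep(NA_real_, n_loops)
    for (i in seq_len(n_loops)) {
      mixA <- c(sample(des$idxA, des$takeA), sample(des$idxB, des$takeB))
      lab <- rep("mixB", n); lab[mixA] <- "mixA"
      desc[i] <- select_features(table, labels = lab)$descriptor
      if (!is.null(Y)) pv[i] <- wilks_p(lab)
    }
    loops <- data.frame(loop = seq_len(n_loops), descriptor = desc,
                        manova_p = pv)
  }
  structure(list(loops = loops,
                 real_descriptor = real$descriptor,
                 real_selected = real$selected,
                 real_p = real_p,
                 descriptor_percentile =
                   if (n_loops > 0) 100 * mean(loops$descriptor <
                                                 real$descriptor) else NA_real_,
                 p_percentile =
                   if (n_loops > 0 && !is.null(Y))
                     100 * mean(loops$manova_p > real_p) else NA_real_),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("<randomization_result> %d loops\n", nrow(x$loops)))
  cat(sprintf("  real-label descriptor %.4f (above %.1f%% of loops)\n",
              x$real_descriptor, x$descriptor_percentile))
  if (!is.na(x$real_p))
    cat(sprintf("  real-label MANOVA p %.4g (below %.1f%% of loops)\n",
                x$real_p, x$p_percentile))
  invisible(x)
}

#' Descriptor / MANOVA independence report
#'
#' Pairs each randomization loop's MANOVA p-value with its descriptor, adds
#' the real-label pair (flagged exactly once), and counts how the loops
#' compare with the real labels on each axis and against the p < 0.05 line.
#'
#' @param rr a `randomization_result`.
#' @return object of class `independence_report`: `points` (data.frame
#'   manova_p, descriptor, is_real), `n_loops`, `n_above_real_descriptor`,
#'   `n_below_real_p`, `n_significant` (loops with p < 0.05),
#'   `max_descriptor_significant` (largest descriptor among them),
#'   `correlation` (Pearson, p vs descriptor over loops).
#' @export
independence_report <- function(rr) {
  lp <- rr$loops
  if (nrow(lp) > 0 && nrow(lp) < 100L)
    warning("fewer than 100 loops; the report is unstable", call. = FALSE)
  pts <- rbind(
    if (nrow(lp)) data.frame(manova_p = lp$manova_p,
                             descriptor = lp$descriptor, is_real = FALSE),
    data.frame(manova_p = rr$real_p, descriptor = rr$real_descriptor,
               is_real = TRUE))
  sig <- !is.na(lp$manova_p) & lp$manova_p < 0.05
  structure(list(points = pts,
                 n_loops = nrow(lp),
                 n_above_real_descriptor =
                   sum(lp$descriptor > rr$real_descriptor),
                 n_below_real_p = sum(!is.na(lp$manova_p) &
                                        lp$manova_p < rr$real_p),
                 n_significant = sum(sig),
                 max_descriptor_significant =
                   if (any(sig)) max(lp$descriptor[sig]) else NA_real_,
                 correlation = if (nrow(lp) >= 3 && !all(is.na(lp$manova_p)))
                   stats::cor(lp$manova_p, lp$descriptor,
                              use = "complete.obs") else NA_real_),
            class = "independence_report")
}

#' @export
print.independence_report <- function(x, ...) {
  cat(sprintf("<independence_report> %d loops\n", x$n_loops))
  cat(sprintf("  loops beating the real descriptor: %d; loops with smaller p: %d\n",
              x$n_above_real_descriptor, x$n_below_real_p))
  cat(sprintf("  loops with p < 0.05: %d (max descriptor among them: %s)\n",
              x$n_significant,
              ifelse(is.na(x$max_descriptor_significant), "-",
                     sprintf("%.3f", x$max_descriptor_significant))))
  cat(sprintf("  p-descriptor correlation over loops: %s\n",
              ifelse(is.na(x$correlation), "-",
                     sprintf("%.3f", x$correlation))))
  invisible(x)
}

#' @export
plot.independence_report <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$manova_p[!pts$is_real], pts$descriptor[!pts$is_real],
                 pch = 20, col = "steelblue", xlab = "MANOVA p",
                 ylab = "descriptor", ...)
  graphics::abline(v = 0.05, col = "red")
  with(pts[pts$is_real, ], graphics::points(manova_p, descriptor,
                                            pch = 21, bg = "yellow",
                                            cex = 1.6))
  invisible(x)
}

#' Write / read a feature table as CSV
#'
#' Columns: `image_id`, `condition`, then one column per characteristic.
#' `read_feature_table_blocks()` reads a two-block export (a `block` column
#' distinguishing `real` and `normalized` rows, mirroring spreadsheet
#' exports that carry both).
#'
#' @param table a `feature_table`.
#' @param path file path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(image_id = table$image_ids,
                   condition = table$conditions,
                   table$matrix, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param normalized whether the stored values are normalized.
#' @export
read_feature_table <- function(path, normalized = FALSE) {
  df <- read.csv(path, check.names = FALSE)
  feature_table(as.matrix(df[, -(1:2), drop = FALSE]),
                image_ids = df$image_id, conditions = df$condition,
                normalized = normalized)
}

#' @rdname write_feature_table
#' @param block which block to read: `"real"` or `"normalized"`.
#' @export
read_feature_table_blocks <- function(path, block = c("real", "normalized")) {
  block <- match.arg(block)
  df <- read.csv(path, check.names = FALSE)
  if (!"block" %in% names(df))
    stop("no 'block' column; use read_feature_table()", call. = FALSE)
  df <- df[df$block == block, ]
  feature_table(as.matrix(df[, setdiff(names(df),
                                       c("block", "image_id", "condition")),
                             drop = FALSE]),
                image_ids = df$image_id, conditions = df$condition,
                normalized = block == "normalized")
}

#' Write a selection result (with full trace) as JSON
#' @param sel a `selection_result`.
#' @param path file path.
#' @export
write_selection_result <- function(sel, path) {
  tr <- lapply(sel$trace, function(t)
    list(size = t$size,
         kept = lapply(t$kept, identity),
         descriptor = t$descriptor))
  jsonlite::write_json(list(selected = sel$selected,
                            descriptor = sel$descriptor,
                            n_evaluated = sel$n_evaluated,
                            trace = tr),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
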