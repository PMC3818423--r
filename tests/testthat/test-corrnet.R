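test_that("the cell correlation has the Pearson properties", {
  set.seed(1)
  v <- runif(14)
  expect_equal(corr_cells(v, v), 1)
  for (i in 1:20) {
    a <- runif(14); b <- runif(14)
    expect_lte(corr_cells(a, b), 1 + 1e-12)
    expect_equal(corr_cells(a, b), corr_cells(b, a))
    ## invariance under positive affine maps; sign flip under negative slope
    expect_equal(corr_cells(a, 2.5 * b + 3), corr_cells(a, b),
                 tolerance = 1e-12)
  }
  base <- rep(c(0.1, 0.5, 0.9), length.out = 14)
  expect_equal(corr_cells(base, 2 * base + 1), 1, tolerance = 1e-12)
  expect_equal(corr_cells(base, -0.5 * base + 1), -1, tolerance = 1e-12)
  expect_error(corr_cells(rep(1, 14), base), "degenerate")
})

test_that("threshold bounds give the empty and complete graphs", {
  set.seed(2)
  m <- matrix(runif(30 * 14), 30, 14)
  g_hi <- build_correlation_network(m, threshold = 1.000001)
  expect_equal(igraph::ecount(g_hi$graph), 0)
  g_lo <- build_correlation_network(m, threshold = -1)
  expect_equal(igraph::ecount(g_lo$graph), choose(30, 2))
})

test_that("edge counts equal a brute-force double loop", {
  img <- generate_mosaic(mid_spec(seed = 41))
  res <- compute_image_features(img)
  cm <- cell_feature_matrix(res$cells)
  cmn <- normalize_minmax(cm)
  C <- cor(t(cmn))
  thr <- unname(quantile(C[upper.tri(C)], 0.99))
  cg <- build_correlation_network(cm, thr)
  cnt <- 0L
  for (i in 1:(nrow(cmn) - 1))
    for (j in (i + 1):nrow(cmn))
      if (corr_cells(cmn[i, ], cmn[j, ]) >= thr) cnt <- cnt + 1L
  expect_equal(igraph::ecount(cg$graph), cnt)
})

test_that("largest component size decreases with the threshold and the
           sweep hits a requested window", {
  img <- generate_mosaic(mid_spec(seed = 42))
  res <- compute_image_features(img)
  cm <- cell_feature_matrix(res$cells)
  sizes <- vapply(c(0.9, 0.95, 0.99, 0.999), function(t)
    length(build_correlation_network(cm, t)$largest_component), 0)
  expect_true(all(diff(sizes) <= 0))
  n_roi <- nrow(cm)
  sw <- threshold_sweep(cm, target = c(2, n_roi), range = c(0.5, 0.9999))
  expect_gte(sw$component_size, 2)
  tgt <- c(round(n_roi / 4), round(n_roi / 2))
  sw2 <- threshold_sweep(cm, target = tgt, range = c(0.5, 0.9999))
  expect_gte(sw2$component_size, tgt[1])
  expect_lte(sw2$component_size, tgt[2])
  expect_error(threshold_sweep(cm, target = c(10 * n_roi, 20 * n_roi)),
               "unattainable")
})

test_that("same-class link fraction matches a naive scan and is extreme for
           single-class graphs", {
  img <- generate_mosaic(mid_spec(seed = 43))
  res <- compute_image_features(img)
  cm <- cell_feature_matrix(res$cells)
  roi <- res$cells[res$cells$in_roi, ]
  meta <- data.frame(n_sides = roi$n_sides)
  sw <- threshold_sweep(cm, target = c(30, 100), range = c(0.5, 0.9999))
  cg <- build_correlation_network(cm, sw$threshold, meta = meta)
  pa <- polygon_assortment(cg, n_perm = 500, seed = 7)
  el <- igraph::as_edgelist(cg$graph, names = FALSE)
  frac <- mean(meta$n_sides[el[, 1]] == meta$n_sides[el[, 2]])
  expect_equal(pa$same_class_edge_fraction, frac)
  ## correlating cells share their polygon class
  expect_lt(pa$permutation_p, 0.05)
  ## degenerate one-class graph
  cg1 <- build_correlation_network(cm, -1,
                                   meta = data.frame(n_sides =
                                                       rep(6, nrow(cm))))
  pa1 <- polygon_assortment(cg1)
  expect_equal(pa1$same_class_edge_fraction, 1)
  expect_equal(pa1$permutation_p, 1)
})

test_that("random classes give an unremarkable permutation p", {
  img <- generate_mosaic(mid_spec(seed = 44))
  res <- compute_image_features(img)
  cm <- cell_feature_matrix(res$cells)
  sw <- threshold_sweep(cm, target = c(30, 100), range = c(0.5, 0.9999))
  set.seed(11)
  ps <- vapply(1:20, function(i) {
    meta <- data.frame(n_sides = sample(4:8, nrow(cm), replace = TRUE))
    cg <- build_correlation_network(cm, sw$threshold, meta = meta)
    polygon_assortment(cg, n_perm = 400, seed = i)$permutation_p
  }, 0)
  ## roughly uniform: mean near 0.5, spread over the unit interval
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.8)
})

test_that("with no distribution shift the components mix both conditions", {
  imgs <- generate_condition_pair(mid_spec(), mid_spec(), 3, 3, seed = 61)
  per <- lapply(seq_along(imgs), function(i)
    compute_image_features(imgs[[i]]))
  cm <- do.call(rbind, lapply(per, function(p) cell_feature_matrix(p$cells)))
  cond <- unlist(lapply(seq_along(per), function(i) {
    roi <- per[[i]]$cells[per[[i]]$cells$in_roi, ]
    rep(imgs[[i]]$condition, nrow(roi))
  }))
  sw <- threshold_sweep(cm, target = c(50, 200), range = c(0.5, 0.9999))
  cg <- build_correlation_network(cm, sw$threshold,
                                  meta = data.frame(condition = cond))
  mix <- polygon_assortment(cg, n_perm = 500, seed = 3,
                            attribute = "condition")
  ## no condition purity beyond the permutation null
  expect_gt(mix$permutation_p, 0.05)
})
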