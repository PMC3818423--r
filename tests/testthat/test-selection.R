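test_that("min-max normalization has the contract properties", {
  m <- cbind(c(2, 4, 6), c(1, 1, 1), c(9, 3, 6))
  expect_warning(out <- normalize_minmax(m), "constant")
  expect_equal(out[, 1], c(0, 0.5, 1))
  expect_equal(out[, 2], c(0, 0, 0))
  expect_equal(order(out[, 3]), order(m[, 3]))
  expect_equal(suppressWarnings(normalize_minmax(out)), out)
  expect_error(normalize_minmax(cbind(c(1, NA, 2))), "non-finite")
  ft <- random_table(5, 5, 8, seed = 3)
  n1 <- normalize_features(ft)
  expect_true(all(n1$matrix >= 0 & n1$matrix <= 1))
  expect_identical(normalize_features(n1)$matrix, n1$matrix)
})

test_that("PCA projection reproduces 2-D data and orders variance", {
  set.seed(4)
  x1 <- rnorm(20, sd = 3)
  x2 <- rnorm(20)
  x2 <- residuals(lm(x2 ~ x1))           # exactly uncorrelated sample
  X <- cbind(x1, x2 / sd(x2))
  ft <- feature_table(X, conditions = rep(c("A", "B"), 10),
                      normalized = TRUE)
  sc <- pca_project(ft, 1:2)
  Xc <- scale(X, scale = FALSE)
  ## same up to axis sign
  expect_equal(abs(sc), abs(Xc[, 1:2]), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_gte(var(sc[, 1]), var(sc[, 2]))
  ## with |features| = 2 the projection preserves total variance
  expect_equal(sum(apply(sc, 2, var)), sum(apply(X, 2, var)),
               tolerance = 1e-10)
  ft8 <- random_table(10, 10, 8, seed = 5)
  sc8 <- pca_project(normalize_features(ft8), 1:8)
  expect_lte(sum(apply(sc8, 2, var)),
             sum(apply(normalize_features(ft8)$matrix, 2, var)) + 1e-12)
  ## eigen oracle: PC variances are the top-2 covariance eigenvalues
  ev <- eigen(cov(normalize_features(ft8)$matrix), symmetric = TRUE)$values
  expect_equal(unname(apply(sc8, 2, var)), ev[1:2], tolerance = 1e-10)
  const <- feature_table(matrix(1, 10, 3), conditions = rep(c("A", "B"), 5),
                         normalized = TRUE)
  expect_error(pca_project(const, 1:3), "rank")
})

test_that("the descriptor matches hand-computed scatter matrices", {
  sc <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- c("g1", "g1", "g2", "g2")
  d <- pca_descriptor(sc, lab)
  ## by hand: tr(B) = 2*25 + 2*25 = 100, tr(W) = 4 * 0.25 = 1
  expect_equal(sum(diag(d$B)), 100)
  expect_equal(sum(diag(d$W)), 1)
  expect_equal(d$descriptor, 100)
  ## additive decomposition: B + W equals the total scatter
  tot <- crossprod(scale(sc, scale = FALSE))
  expect_equal(d$B + d$W, tot, tolerance = 1e-8, ignore_attr = TRUE)
  ## coincident centroids give zero
  sc0 <- rbind(c(0, 0), c(2, 2), c(0, 2), c(2, 0))
  expect_equal(pca_descriptor(sc0, c("a", "a", "b", "b"))$descriptor, 0)
  expect_error(pca_descriptor(rbind(c(1, 1), c(1, 1), c(2, 2), c(2, 2)),
                              c("a", "a", "b", "b")), "zero within-group")
})

test_that("the descriptor is invariant under rigid motions of the scores", {
  set.seed(6)
  sc <- matrix(rnorm(40), 20, 2)
  lab <- rep(c("A", "B"), 10)
  d0 <- pca_descriptor(sc, lab)$descriptor
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  d1 <- pca_descriptor(sc %*% R, lab)$descriptor
  d2 <- pca_descriptor(sweep(sc, 2, c(5, -3), "+"), lab)$descriptor
  expect_equal(d1, d0, tolerance = 1e-9)
  expect_equal(d2, d0, tolerance = 1e-9)
})

test_that("the fast search path equals the direct scatter computation", {
  ft <- normalize_features(random_table(15, 16, 12, planted = 1:2,
                                        delta = 0.4, seed = 7))
  ctx <- epitopo:::descriptor_context(ft$matrix, ft$conditions)
  set.seed(8)
  for (k in c(2, 3, 5, 7)) {
    subs <- replicate(5, sort(sample(12, k)), simplify = FALSE)
    fast <- epitopo:::eval_subsets(ctx, subs)
    direct <- vapply(subs, function(s)
      pca_descriptor(pca_project(ft, s), ft$conditions)$descriptor, 0)
    expect_equal(fast, direct, tolerance = 1e-9)
  }
})

test_that("the beam search follows the 10/50/100 bookkeeping and returns a
           recomputable optimum", {
  ft <- normalize_features(random_table(15, 16, 40, planted = c(7, 31),
                                        delta = 0.35, seed = 9))
  sel <- select_features(ft)
  pool <- vapply(sel$trace, function(t) length(t$kept), 0L)
  expect_equal(pool[1:3], c(10L, 50L, 100L))
  sizes <- vapply(sel$trace, `[[`, 0L, "size")
  expect_equal(sizes[1:3], 2:4)
  expect_gte(length(sel$selected), 2)
  expect_lte(length(sel$selected), 7)
  direct <- pca_descriptor(pca_project(ft, sel$selected),
                           ft$conditions)$descriptor
  expect_equal(sel$descriptor, direct, tolerance = 1e-9)
  ## determinism including tie handling
  sel2 <- select_features(ft)
  expect_identical(sel$selected, sel2$selected)
  ## the planted separating features are recovered
  expect_true(all(c(7, 31) %in% sel$selected))
})

test_that("the beam search matches exhaustive enumeration on small tables", {
  hits <- 0L
  n_tab <- 20L
  for (s in seq_len(n_tab)) {
    ft <- normalize_features(random_table(8, 8, 8, seed = 100 + s))
    sel <- select_features(ft)
    subs <- unlist(lapply(2:7, function(k)
      combn(8, k, simplify = FALSE)), recursive = FALSE)
    best <- max(vapply(subs, function(ss)
      pca_descriptor(pca_project(ft, ss), ft$conditions)$descriptor, 0))
    expect_lte(sel$descriptor, best + 1e-9)
    if (sel$descriptor >= best - 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / n_tab, 0.9)
})

test_that("randomization respects the half-split design and reports
           percentiles", {
  ft <- random_table(15, 16, 10, planted = 1:2, delta = 0.5, seed = 11)
  des <- epitopo:::randomization_design(ft$conditions)
  expect_equal(des$takeA, 8L)
  expect_equal(des$takeB, 8L)
  expect_error(epitopo:::randomization_design(rep(c("A", "B"), c(1, 30))),
               ">= 2")
  r0 <- randomize_groups(ft, n_loops = 0)
  expect_equal(nrow(r0$loops), 0)
  expect_true(is.finite(r0$real_descriptor))
  r1 <- randomize_groups(ft, n_loops = 25, seed = 12)
  r2 <- randomize_groups(ft, n_loops = 25, seed = 12)
  expect_identical(r1$loops, r2$loops)
  expect_gte(r1$descriptor_percentile, 0)
  expect_lte(r1$descriptor_percentile, 100)
  ## mixA always holds 16 images: 8 from each condition by construction
  ## (checked indirectly: loops differ from the real labels)
  expect_true(any(r1$loops$descriptor != r1$real_descriptor))
})

test_that("the independence report counts match naive scans", {
  set.seed(13)
  ft <- random_table(15, 16, 10, planted = 1:2, delta = 0.4, seed = 14)
  dists <- lapply(seq_len(31), function(i) random_dist())
  rr <- randomize_groups(ft, dists, n_loops = 120, seed = 15)
  rep <- independence_report(rr)
  expect_equal(rep$n_loops, 120)
  expect_equal(rep$n_above_real_descriptor,
               sum(rr$loops$descriptor > rr$real_descriptor))
  expect_equal(rep$n_below_real_p, sum(rr$loops$manova_p < rr$real_p))
  expect_equal(rep$n_significant, sum(rr$loops$manova_p < 0.05))
  expect_equal(sum(rep$points$is_real), 1)
  ## empty input
  rep0 <- independence_report(randomize_groups(ft, n_loops = 0))
  expect_equal(rep0$n_loops, 0)
})

test_that("feature tables and selection results round-trip through disk", {
  ft <- random_table(4, 4, 6, seed = 16)
  p <- tempfile(fileext = ".csv")
  write_feature_table(ft, p)
  back <- read_feature_table(p)
  expect_equal(back$matrix, ft$matrix, ignore_attr = TRUE)
  expect_equal(back$conditions, ft$conditions)
  ## two-block export
  df <- rbind(data.frame(block = "real", image_id = ft$image_ids,
                         condition = ft$conditions, ft$matrix),
              data.frame(block = "normalized", image_id = ft$image_ids,
                         condition = ft$conditions,
                         suppressWarnings(normalize_minmax(ft$matrix))))
  p2 <- tempfile(fileext = ".csv")
  write.csv(df, p2, row.names = FALSE)
  norm <- read_feature_table_blocks(p2, "normalized")
  expect_true(norm$normalized)
  expect_true(all(norm$matrix >= 0 & norm$matrix <= 1))
  raw <- read_feature_table_blocks(p2, "real")
  expect_equal(raw$matrix, ft$matrix, ignore_attr = TRUE)
  sel <- select_features(random_table(8, 8, 8, planted = 1:2, delta = 0.5,
                                      seed = 17))
  p3 <- tempfile(fileext = ".json")
  write_selection_result(sel, p3)
  js <- jsonlite::read_json(p3)
  expect_equal(unlist(js$selected), sel$selected)
  expect_equal(js$descriptor, sel$descriptor, tolerance = 1e-12)
})
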