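test_that("the radius rule bridges small gaps and nothing more", {
  lab <- matrix(0L, 30, 40)
  lab[10:19, 5:14] <- 1L
  lab[10:19, 18:27] <- 2L     # 3-px gap
  g <- build_contact_graph(label_image(lab,
                                       roi_mask = matrix(TRUE, 30, 40)),
                           r = 4)
  expect_equal(igraph::ecount(g$graph), 1)
  lab2 <- matrix(0L, 30, 40)
  lab2[10:19, 5:14] <- 1L
  lab2[10:19, 25:34] <- 2L    # 10-px gap
  g2 <- suppressWarnings(
    build_contact_graph(label_image(lab2, roi_mask = matrix(TRUE, 30, 40)),
                        r = 4))
  expect_equal(igraph::ecount(g2$graph), 0)
})

test_that("a corner cell of a 2x2 square block has three neighbours", {
  lab <- square_grid_labels(2, 10)
  img <- label_image(lab, roi_mask = matrix(TRUE, nrow(lab), ncol(lab)))
  g <- build_contact_graph(img, r = 4)
  ## two side neighbours plus the diagonal across the 4-corner
  expect_equal(polygon_class(g, 1), 3L)
  expect_equal(polygon_class(g), rep(3L, 4))
  expect_error(polygon_class(g, 9), "out of graph")
})

test_that("node metrics match closed forms on canonical graphs", {
  tri <- as_contact_graph(igraph::make_full_graph(3))
  m <- node_metrics(tri)
  expect_equal(m$clustering, rep(1, 3))
  expect_equal(m$betweenness, rep(0, 3))
  path3 <- as_contact_graph(igraph::make_graph(~ 1 - 2, 2 - 3))
  mp <- node_metrics(path3)
  expect_equal(mp$betweenness[2], 1)   # the single non-adjacent pair
  expect_equal(mp$eccentricity, c(2, 1, 2))
  expect_error(node_metrics(as_contact_graph(igraph::make_full_graph(2))),
               "fewer than 3")
})

test_that("global metrics match closed forms on K4 and a 3-path", {
  k4 <- as_contact_graph(igraph::make_full_graph(4))
  gm <- global_metrics(k4)
  expect_equal(unname(gm[c("density", "diameter", "efficiency",
                           "transitivity")]), c(1, 1, 1, 1))
  expect_equal(unname(gm["s_metric"]), 6 * 9)
  path3 <- as_contact_graph(igraph::make_graph(~ 1 - 2, 2 - 3))
  gp <- global_metrics(path3)
  ## Laplacian spectrum of P3 is {0, 1, 3}
  expect_equal(unname(gp["algebraic_connectivity"]), 1, tolerance = 1e-10)
  expect_equal(unname(gp["radius"]), 1)
  expect_equal(unname(gp["avg_path_length"]), 4 / 3)
})

test_that("betweenness agrees with exhaustive BFS path counting", {
  img <- generate_mosaic(tiny_spec(seed = 31))
  g <- build_contact_graph(img, weighted = FALSE)
  m <- node_metrics(g)
  adj <- lapply(igraph::as_adj_list(g$graph, mode = "all"), as.integer)
  n <- length(adj)
  expect_equal(m$betweenness, bfs_betweenness(adj) / ((n - 1) * (n - 2) / 2),
               tolerance = 1e-10)
})

test_that("fast-greedy modularity attains the exhaustive-partition optimum
           on two cliques joined by an edge", {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  g <- igraph::add_edges(g, c(4, 5))
  cg <- as_contact_graph(g)
  gm <- global_metrics(cg)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  ## hand partition: one clique per community
  q_split <- newman_q(A, rep(1:2, each = 4))
  best <- max(vapply(all_partitions(8), function(p) newman_q(A, p), 0))
  expect_equal(q_split, best, tolerance = 1e-12)
  expect_equal(unname(gm["modularity"]), best, tolerance = 1e-12)
})

test_that("strengths satisfy the handshake identity", {
  img <- generate_mosaic(tiny_spec(seed = 12))
  g <- build_contact_graph(img, weighted = TRUE)
  m <- node_metrics(g)
  expect_equal(sum(m$strength), 2 * sum(igraph::E(g$graph)$weight))
})

test_that("degree assortativity equals the degree-degree Pearson correlation", {
  img <- generate_mosaic(tiny_spec(seed = 13))
  gm <- global_metrics(build_contact_graph(img, weighted = FALSE))
  expect_equal(unname(gm["assortativity"]),
               unname(gm["pearson_correlation"]), tolerance = 1e-10)
})

test_that("image features are invariant under relabelling of cells", {
  img <- generate_mosaic(tiny_spec(seed = 14))
  f1 <- compute_image_features(img)$features
  set.seed(99)
  perm <- sample(64)
  lab2 <- img$labels
  lab2[lab2 > 0] <- perm[lab2[lab2 > 0]]
  img2 <- label_image(lab2, roi_mask = img$roi_mask)
  f2 <- compute_image_features(img2)$features
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-10)
})

test_that("feature vectors have the documented lengths and aggregate means", {
  img <- generate_mosaic(tiny_spec(seed = 15))
  res <- compute_image_features(img)
  expect_length(res$features, 40)
  expect_length(cell_feature_names, 14)
  cm <- cell_feature_matrix(res$cells)
  expect_equal(ncol(cm), 14)
  ## independent re-aggregation of means and sds
  roi <- res$cells[res$cells$in_roi, ]
  expect_equal(unname(res$features["avg_area"]), mean(roi$area))
  expect_equal(unname(res$features["sd_betweenness"]), sd(roi$betweenness))
  expect_equal(unname(res$features["avg_neighbours"]), mean(roi$n_sides))
})

test_that("a honeycomb interior is homogeneous in geometry and relations", {
  pts <- hexagonal_lattice(300, 300, spacing = 26)
  sp <- mosaic_spec(n_cells = nrow(pts), image_size = c(300, 300))
  img <- generate_mosaic(sp, points = pts)
  ## deep ROI: keep cells whose full neighbourhood is also interior
  cents <- extract_cells(img)
  deep <- cents$row > 60 & cents$row < 240 & cents$col > 60 & cents$col < 240
  mask <- matrix(img$labels %in% which(deep), 300, 300)
  img2 <- label_image(img$labels, roi_mask = mask)
  res <- compute_image_features(img2, r = 3)
  f <- res$features
  for (nm in c("sd_area", "sd_relation_axis", "sd_convex_hull",
               "sd_neighbours", "sd_rel_neigh_area",
               "sd_rel_neigh_convex_hull", "sd_clustering"))
    expect_lt(unname(f[nm]) / max(abs(unname(f[sub("^sd", "avg", nm)])), 1),
              0.01)
  roi <- res$cells[res$cells$in_roi, ]
  ## unity up to pixel discretization of the hexagons
  expect_equal(roi$rel_neigh_area, rep(1, nrow(roi)), tolerance = 0.01)
})

test_that("contact graphs round-trip through GraphML", {
  img <- generate_mosaic(tiny_spec(seed = 16))
  g <- build_contact_graph(img)
  p <- tempfile(fileext = ".graphml")
  write_contact_graph(g, p)
  back <- read_contact_graph(p)
  expect_equal(back$n_cells, g$n_cells)
  expect_equal(igraph::ecount(back$graph), igraph::ecount(g$graph))
  expect_equal(sort(igraph::E(back$graph)$weight),
               sort(igraph::E(g$graph)$weight))
  expect_equal(igraph::vertex_attr(back$graph, "n_sides"),
               as.numeric(polygon_class(g)))
})
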