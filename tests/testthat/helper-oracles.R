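## Independent brute-force oracles and shared fixtures. Everything here is
## deliberately naive and separate from the package's code paths.

tiny_spec <- function(seed = 1, shift = 0)
  mosaic_spec(n_cells = 64, image_size = c(80, 80), polygon_shift = shift,
              seed = seed)

mid_spec <- function(seed = 1, shift = 0)
  mosaic_spec(n_cells = 150, image_size = c(192, 192), polygon_shift = shift,
              seed = seed)

## wrap a bare igraph as a contact_graph (for closed-form graph fixtures)
as_contact_graph <- function(g, in_roi = rep(TRUE, igraph::vcount(g))) {
  if (is.null(igraph::vertex_attr(g, "weight")) &&
      is.null(igraph::edge_attr(g, "weight")))
    g <- igraph::set_edge_attr(g, "weight", value = rep(1, igraph::ecount(g)))
  g <- igraph::set_vertex_attr(g, "in_roi", value = in_roi)
  structure(list(graph = g, r = NA_real_, n_cells = igraph::vcount(g)),
            class = "contact_graph")
}

## betweenness from the definition: one BFS per source gives the distance
## matrix D and the geodesic-count matrix S; a node v lies on a shortest
## s-t path iff D[s,v] + D[v,t] == D[s,t], and the fraction of geodesics
## through it is S[s,v] * S[v,t] / S[s,t]
bfs_betweenness <- function(adj) {
  n <- length(adj)
  D <- matrix(Inf, n, n); S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (u in adj[[v]]) {
        if (is.infinite(dist[u])) { dist[u] <- dist[v] + 1; nxt <- c(nxt, u) }
        if (dist[u] == dist[v] + 1) sigma[u] <- sigma[u] + sigma[v]
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist; S[s, ] <- sigma
  }
  btw <- numeric(n)
  for (v in seq_len(n))
    for (s in 1:(n - 1))
      for (t in (s + 1):n) {
        if (s == v || t == v || is.infinite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t])
          btw[v] <- btw[v] + S[s, v] * S[v, t] / S[s, t]
      }
  btw
}

## Newman modularity of a partition, from the definition
newman_q <- function(adj_mat, membership) {
  m <- sum(adj_mat) / 2
  deg <- rowSums(adj_mat)
  q <- 0
  n <- nrow(adj_mat)
  for (i in 1:n) for (j in 1:n)
    if (membership[i] == membership[j])
      q <- q + adj_mat[i, j] - deg[i] * deg[j] / (2 * m)
  q / (2 * m)
}

## all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(code, maxc) {
    k <- length(code)
    if (k == n) { out[[length(out) + 1]] <<- code; return(invisible()) }
    for (c in seq_len(maxc + 1)) rec(c(code, c), max(maxc, c))
  }
  rec(1L, 1L)
  out
}

## brute-force Delaunay adjacency by the empty-circumcircle property
delaunay_pairs <- function(pts) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  spacing <- sqrt(prod(apply(pts, 2, function(x) diff(range(x)))) / n)
  out <- list()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] > 3 * spacing) next
      ks <- setdiff(order(D[i, ] + D[j, ]), c(i, j))
      ks <- ks[(D[i, ks] + D[j, ks]) < 6 * spacing]
      found <- FALSE
      for (k in ks) {
        ax <- pts[i, 1]; ay <- pts[i, 2]
        bx <- pts[j, 1]; by <- pts[j, 2]
        cx <- pts[k, 1]; cy <- pts[k, 2]
        d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
        if (abs(d) < 1e-9) next
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
        r2 <- (ax - ux)^2 + (ay - uy)^2
        dd <- (pts[, 1] - ux)^2 + (pts[, 2] - uy)^2
        dd[c(i, j, k)] <- Inf
        if (min(dd) >= r2 - 1e-9) { found <- TRUE; break }
      }
      if (found) out[[length(out) + 1]] <- c(i, j)
    }
  }
  do.call(rbind, out)
}

## hand-rolled polygon_distribution stand-in for MANOVA fixtures
fake_dist <- function(freqs, n_cells = 400, condition = NA_character_) {
  counts <- round(freqs * n_cells)
  structure(list(counts = counts, frequencies = freqs, n_cells = n_cells,
                 image_id = NA_character_, condition = condition),
            class = "polygon_distribution")
}

## realistic random distribution over classes 3..10 (classes 3, 9, 10 keep
## the 4..8 block away from exact simplex collinearity, as in real tissue)
random_dist <- function(hex_shift = 0, noise = 0.015) {
  f <- c(0.005, 0.03, 0.27 - hex_shift, 0.44 + hex_shift, 0.2, 0.04,
         0.01, 0.005) + abs(rnorm(8, 0, noise))
  fake_dist(stats::setNames(f / sum(f), 3:10))
}

## random two-group feature table with optional planted group separation
## in the chosen columns
random_table <- function(n_a, n_b, p, planted = integer(0), delta = 0,
                         seed = 1) {
  set.seed(seed)
  m <- matrix(runif((n_a + n_b) * p), n_a + n_b, p)
  if (length(planted))
    m[seq_len(n_a), planted] <- m[seq_len(n_a), planted] + delta
  feature_table(m, conditions = rep(c("A", "B"), c(n_a, n_b)))
}

## block label matrix of k x k squares of side s separated by gap px
square_grid_labels <- function(k, s, gap = 1, margin = 2) {
  step <- s + gap
  side <- 2 * margin + k * step - gap
  lab <- matrix(0L, side, side)
  id <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    id <- id + 1L
    r0 <- margin + (i - 1L) * step
    c0 <- margin + (j - 1L) * step
    lab[r0 + seq_len(s), c0 + seq_len(s)] <- id
  }
  lab
}
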