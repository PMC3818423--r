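## End-to-end orchestration: generate -> features -> networks -> statistics.

#' Configuration for a full pipeline run
#'
#' @param out_dir output directory (created if missing).
#' @param image_prefixes character vector of label-image path prefixes (see
#'   [read_label_image()]); omit to generate synthetic images.
#' @param specA,specB mosaic specs for synthetic generation.
#' @param n_images_A,n_images_B images per condition when generating.
#' @param r neighbour radius in px.
#' @param threshold correlation-network threshold, or `NULL` to sweep.
#' @param component_range target `(lo, hi)` largest-component size for the
#'   sweep when `threshold` is `NULL`.
#' @param corr_cells_max cap on the number of cells entering the
#'   correlation assay (cells are subsampled deterministically above it).
#' @param n_loops randomization loops.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       image_prefixes = NULL,
                       specA = mosaic_spec(polygon_shift = 0),
                       specB = mosaic_spec(polygon_shift = 0.3),
                       n_images_A = 15L, n_images_B = 16L,
                       r = 4, threshold = NULL,
                       component_range = c(150L, 400L),
                       corr_cells_max = 1500L,
                       n_loops = 4000L, seed = 1L) {
  structure(list(out_dir = out_dir, image_prefixes = image_prefixes,
                 specA = specA, specB = specB,
                 n_images_A = n_images_A, n_images_B = n_images_B,
                 r = r, threshold = threshold,
                 component_range = component_range,
                 corr_cells_max = corr_cells_max,
                 n_loops = n_loops, seed = seed),
            class = "run_config")
}

pipeline_log <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Stages: load or generate the two-condition image set; extract per-cell
#' and per-image features; build and export contact graphs; run the
#' cell-correlation network; compute polygon distributions and the
#' two-group MANOVA; run the beam-search feature selection; run the
#' group-label randomization. All numeric outputs are deterministic given
#' the config.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `table` (feature_table), `dists`,
#'   `manova`, `selection`, `randomization`, `assortment`, `paths`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "pipeline.log")
  con <- file(logf, open = "wt")
  on.exit(close(con))

  if (is.null(config$image_prefixes)) {
    pipeline_log(con, "generating ", config$n_images_A, "+",
                 config$n_images_B, " synthetic images (seed ",
                 config$seed, ")")
    imgs <- generate_condition_pair(config$specA, config$specB,
                                    config$n_images_A, config$n_images_B,
                                    seed = config$seed)
  } else {
    pipeline_log(con, "reading ", length(config$image_prefixes), " images")
    imgs <- lapply(config$image_prefixes, read_label_image)
    no_roi <- vapply(imgs, function(im) isTRUE(attr(im, "roi_defaulted")),
                     TRUE)
    if (any(no_roi))
      pipeline_log(con, "image(s) without ROI mask: ROI defaults to ",
                   "non-border cells (", sum(no_roi), " image(s))")
  }
  ids <- sprintf("img%03d", seq_along(imgs))

  pipeline_log(con, "extracting features (r = ", config$r, ")")
  per <- vector("list", length(imgs))
  for (i in seq_along(imgs))
    per[[i]] <- compute_image_features(imgs[[i]], r = config$r,
                                       image_id = ids[i])
  table <- feature_table_from_images(lapply(per, `[[`, "features"))
  write_feature_table(table, file.path(config$out_dir, "image_features.csv"))
  for (i in seq_along(per)) {
    write_cell_table(per[[i]]$cells,
                     file.path(config$out_dir, paste0(ids[i], "_cells.csv")))
    write_contact_graph(per[[i]]$graph,
                        file.path(config$out_dir,
                                  paste0(ids[i], "_contacts.graphml")))
  }

  pipeline_log(con, "correlation network")
  cellmat <- do.call(rbind, lapply(per, function(p)
    cell_feature_matrix(p$cells)))
  meta <- do.call(rbind, lapply(seq_along(per), function(i) {
    cl <- per[[i]]$cells
    roi <- cl[cl$in_roi, ]
    data.frame(condition = imgs[[i]]$condition, n_sides = roi$n_sides)
  }))
  if (nrow(cellmat) > config$corr_cells_max) {
    set.seed(config$seed + 1L)
    keep <- sort(sample.int(nrow(cellmat), config$corr_cells_max))
    cellmat <- cellmat[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    pipeline_log(con, "subsampled correlation assay to ",
                 config$corr_cells_max, " cells")
  }
  thr <- config$threshold
  if (is.null(thr)) {
    sw <- threshold_sweep(cellmat, config$component_range)
    thr <- sw$threshold
    pipeline_log(con, "threshold sweep -> ", signif(thr, 6),
                 " (largest component ", sw$component_size, " cells)")
  }
  cg <- build_correlation_network(cellmat, thr, meta = meta)
  write_correlation_network(cg, file.path(config$out_dir,
                                          "correlation_network.graphml"))
  assort <- polygon_assortment(cg, seed = config$seed + 2L)
  pipeline_log(con, "same-class link fraction ",
               signif(assort$same_class_edge_fraction, 4), " (p = ",
               signif(assort$permutation_p, 3), ")")

  pipeline_log(con, "polygon distributions + MANOVA")
  dists <- lapply(seq_along(per), function(i)
    polygon_distribution(per[[i]]$graph, image_id = ids[i],
                         condition = imgs[[i]]$condition))
  write_polygon_distributions(dists, file.path(config$out_dir,
                                               "polygon_distributions.csv"))
  grp <- vapply(imgs, `[[`, "", "condition")
  man <- manova_polygons(dists[grp == unique(grp)[1]],
                         dists[grp == unique(grp)[2]])
  write_manova_report(man, file.path(config$out_dir, "manova.json"))
  pipeline_log(con, "MANOVA p = ", signif(man$p, 4))

  pipeline_log(con, "feature selection")
  sel <- select_features(table)
  write_selection_result(sel, file.path(config$out_dir, "selection.json"))
  pipeline_log(con, "selected {",
               paste(sel$selected, collapse = ","),
               "}, descriptor = ", signif(sel$descriptor, 5))

  rand <- NULL
  if (config$n_loops > 0) {
    pipeline_log(con, "randomization (", config$n_loops, " loops)")
    rand <- randomize_groups(table, dists, n_loops = config$n_loops,
                             seed = config$seed + 3L)
    write.csv(rand$loops,
              file.path(config$out_dir, "randomization_series.csv"),
              row.names = FALSE)
    pipeline_log(con, "real descriptor above ",
                 signif(rand$descriptor_percentile, 4), "% of loops")
  }

  manifest <- list(config = list(r = config$r, threshold = thr,
                                 n_loops = config$n_loops,
                                 seed = config$seed,
                                 n_images_A = config$n_images_A,
                                 n_images_B = config$n_images_B,
                                 specA = unclass(config$specA),
                                 specB = unclass(config$specB)),
                   selected = sel$selected,
                   descriptor = sel$descriptor,
                   manova_p = man$p)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(table = table, dists = dists, manova = man,
                 selection = sel, randomization = rand,
                 assortment = assort,
                 paths = list(out_dir = config$out_dir, log = logf)))
}
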