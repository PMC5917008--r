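# End-to-end orchestration: quality control -> segmentation -> skeleton ->
# cells -> features per stack; ROC screening and the PCA compound score per
# experiment. Fully deterministic given config (the pipeline itself draws no
# random numbers).

#' Build a pipeline configuration
#'
#' Defaults follow the published protocol wherever it states a value: QC
#' correlation threshold 0.78, smoothing sigma 0.3 um, exclusion margins
#' 15 um (X/Y) and 8 um (Z), soma separation 15 um, AUC cutoff 0.85. The
#' remaining knobs are documented reconstructions with conservative defaults.
#'
#' @param inputs character vector of stack paths, or a list of in-memory
#'   [image_stack()] objects (optionally `list(stack, group)` pairs from the
#'   phantom generator).
#' @param groups optional per-stack group labels (e.g. peri / contra).
#' @param qc_threshold inter-slice correlation cut-off, default 0.78.
#' @param smooth_sigma_um Gaussian pre-smoothing sigma, default 0.3.
#' @param min_cluster_volume_um3 mask refinement cut-off, default 5.
#' @param soma_core_distance_um soma core thickness, default 1.2.
#' @param marker_min_separation_um watershed marker separation, default 0.6.
#' @param min_segment_volume_um3 skeleton refinement cut-off, default 0.2.
#' @param max_spur_length_um spur pruning cut-off, default 0.5.
#' @param margin_xy_um,margin_z_um border exclusion margins, 15 and 8.
#' @param soma_min_separation_um proximity exclusion cut-off, default 15.
#' @param require_nucleus exclude cells without a nucleus, default TRUE.
#' @param auc_cutoff feature selection cut-off, default 0.85.
#' @param voxel_size_override optional `(dz, dy, dx)` for file inputs.
#' @param output_dir optional directory for the output bundle.
#' @param seed recorded for provenance (the pipeline is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(inputs, groups = NULL,
                            qc_threshold = 0.78,
                            smooth_sigma_um = 0.3,
                            min_cluster_volume_um3 = 5,
                            soma_core_distance_um = 1.2,
                            marker_min_separation_um = 0.6,
                            min_segment_volume_um3 = 0.2,
                            max_spur_length_um = 0.5,
                            margin_xy_um = 15,
                            margin_z_um = 8,
                            soma_min_separation_um = 15,
                            require_nucleus = TRUE,
                            auc_cutoff = 0.85,
                            voxel_size_override = NULL,
                            output_dir = NULL,
                            seed = 1L) {
  if (is.character(inputs)) {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing)) {
      stop("input path(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(groups) && length(groups) != length(inputs)) {
    stop("groups must match inputs in length", call. = FALSE)
  }
  structure(
    list(inputs = inputs, groups = groups,
         qc_threshold = qc_threshold,
         smooth_sigma_um = smooth_sigma_um,
         min_cluster_volume_um3 = min_cluster_volume_um3,
         soma_core_distance_um = soma_core_distance_um,
         marker_min_separation_um = marker_min_separation_um,
         min_segment_volume_um3 = min_segment_volume_um3,
         max_spur_length_um = max_spur_length_um,
         margin_xy_um = margin_xy_um,
         margin_z_um = margin_z_um,
         soma_min_separation_um = soma_min_separation_um,
         require_nucleus = require_nucleus,
         auc_cutoff = auc_cutoff,
         voxel_size_override = voxel_size_override,
         output_dir = output_dir,
         seed = as.integer(seed),
         roster_hash = roster_hash()),
    class = "pipeline_config")
}

#' Process a single stack through QC, segmentation, skeleton, and features
#'
#' @param stack an [image_stack()].
#' @param config a [pipeline_config()].
#' @param stack_id identifier used in outputs.
#' @return A `stack_result`: `qc`, `masks`, `thresholds`, `graph` (refined),
#'   `cells` (flagged), `feature_maps` (included cells), `features`
#'   (assembled `feature_table`), `source`, `timings`.
#' @export
process_stack <- function(stack, config = pipeline_config(list(stack)),
                          stack_id = "stack1") {
  t0 <- proc.time()[["elapsed"]]
  timings <- numeric(0)
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[stage] <<- t1 - t0
    t0 <<- t1
  }
  qc_res <- trim_low_quality_slices(stack, config$qc_threshold)
  stack <- qc_res$stack
  tick("qc")
  sm <- smooth_stack(stack, config$smooth_sigma_um)
  tick("smooth")
  seg <- segment_stack(sm, config$min_cluster_volume_um3,
                       config$soma_core_distance_um)
  tick("segment")
  if (!any(seg$masks$cell_mask)) {
    stop("segmentation produced an empty cell mask", call. = FALSE)
  }
  labels <- watershed_segments(seg$dmap, seg$masks$cell_mask,
                               config$marker_min_separation_um)
  graph <- build_skeleton_graph(labels, seg$masks, stack$voxel_size)
  graph <- refine_skeleton(graph, config$min_segment_volume_um3,
                           config$max_spur_length_um)
  tick("skeleton")
  centers <- soma_center_nodes(graph, seg$masks, seg$dmap)
  cells <- segregate_cells(graph, centers)
  cells <- apply_exclusion_rules(
    cells, graph,
    margin_xy_um = config$margin_xy_um,
    margin_z_um = config$margin_z_um,
    soma_min_separation_um = config$soma_min_separation_um,
    require_nucleus = config$require_nucleus)
  tick("cells")
  inc <- cells[cells$included, ]
  fmaps <- lapply(seq_len(nrow(inc)), function(i) {
    cell_features(graph, inc[i, ], seg$masks)
  })
  features <- assemble_feature_table(
    cells, fmaps,
    metadata = if (nrow(inc) > 0L) {
      tibble::tibble(stack_id = rep(stack_id, nrow(inc)))
    } else {
      NULL
    })
  tick("features")
  structure(
    list(qc = qc_res$qc, masks = seg$masks,
         thresholds = seg$per_slice_thresholds,
         graph = graph, cells = cells,
         feature_maps = fmaps, features = features,
         source = stack$source, stack_id = stack_id,
         timings = timings),
    class = "stack_result")
}

#' Run the full pipeline over an experiment
#'
#' Per stack: QC report, compartment masks, refined skeleton graph, flagged
#' cell table, and the 59-feature table. Per experiment (when two group
#' labels are present): ROC screen, feature selection, and the PCA compound
#' score. A stage error in one stack is logged and the remaining stacks
#' continue. When `config$output_dir` is set the bundle is also written to
#' disk (CSV/JSON/TIFF) together with the resolved config and roster hash.
#'
#' @param config a [pipeline_config()].
#' @return An `mglia_run`: `stacks` (list of `stack_result`), `features`
#'   (combined table), `roc`, `selected_features`, `pca`, `log`, `config`.
#' @export
run_pipeline <- function(config) {
  inputs <- config$inputs
  n <- length(inputs)
  results <- vector("list", n)
  log <- list()
  groups <- config$groups
  for (i in seq_len(n)) {
    id <- sprintf("stack%03d", i)
    inp <- inputs[[i]]
    res <- tryCatch({
      stk <- if (is.character(inp)) {
        read_stack(inp, config$voxel_size_override)
      } else if (inherits(inp, "image_stack")) {
        inp
      } else if (is.list(inp) && inherits(inp$stack, "image_stack")) {
        if (is.null(groups)) groups <- rep(NA_character_, n)
        if (is.na(groups[i]) && !is.null(inp$group)) groups[i] <- inp$group
        inp$stack
      } else {
        stop("unsupported input type", call. = FALSE)
      }
      process_stack(stk, config, stack_id = id)
    }, error = function(e) {
      structure(list(stack_id = id, error = conditionMessage(e)),
                class = "stack_error")
    })
    if (inherits(res, "stack_error")) {
      log[[length(log) + 1L]] <- list(stack = id, status = "error",
                                      message = res$error)
    } else {
      log[[length(log) + 1L]] <- list(
        stack = id, status = "ok",
        n_cells = nrow(res$cells),
        n_included = sum(res$cells$included),
        timings = as.list(res$timings))
    }
    results[[i]] <- res
  }
  ok <- !vapply(results, inherits, logical(1), "stack_error")
  feats <- dplyr::bind_rows(lapply(which(ok), function(i) {
    f <- results[[i]]$features
    if (!is.null(groups) && nrow(f) > 0L) f$group <- groups[i]
    f
  }))
  if (nrow(feats) > 0L) {
    class(feats) <- c("feature_table", class(feats))
    attr(feats, "roster") <- feature_roster()
    attr(feats, "roster_hash") <- roster_hash()
  }
  roc <- NULL
  selected <- NULL
  pca <- NULL
  if (!is.null(groups) &&
      nrow(feats) >= 6L &&
      length(unique(stats::na.omit(feats$group))) == 2L) {
    roc <- roc_screen(feats)
    selected <- select_features(roc, config$auc_cutoff)
    if (length(selected) >= 2L) {
      pca <- pca_compound_score(feats, selected)
    }
  }
  run <- structure(
    list(stacks = results, features = feats, roc = roc,
         selected_features = selected, pca = pca,
         log = log, config = config),
    class = "mglia_run")
  if (!is.null(config$output_dir)) write_bundle(run, config$output_dir)
  run
}

#' @export
print.mglia_run <- function(x, ...) {
  ok <- sum(!vapply(x$stacks, inherits, logical(1), "stack_error"))
  cat(sprintf("<mglia_run> %d/%d stacks processed, %d cells (%d included)\n",
              ok, length(x$stacks),
              sum(vapply(x$stacks, function(s) {
                if (inherits(s, "stack_error")) 0L else nrow(s$cells)
              }, integer(1))),
              nrow(x$features)))
  if (!is.null(x$pca)) {
    cat(sprintf("  PC1 explains %.1f%% of variance over %d features\n",
                100 * x$pca$explained_variance_fraction[1],
                length(x$pca$selected_features)))
  }
  invisible(x)
}

# Write the output bundle: per-stack artifacts + experiment-level tables +
# resolved config. Everything is plain CSV/JSON/TIFF.
write_bundle <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  cfg$inputs <- if (is.character(cfg$inputs)) {
    cfg$inputs
  } else {
    sprintf("<in-memory stack %d>", seq_along(cfg$inputs))
  }
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  for (s in run$stacks) {
    if (inherits(s, "stack_error")) next
    id <- s$stack_id
    jsonlite::write_json(qc_report_json(s$qc),
                         file.path(dir, paste0(id, "_qc.json")),
                         auto_unbox = TRUE, digits = NA)
    write_mask_tiff(s$masks, file.path(dir, paste0(id, "_labels.tif")))
    write_skeleton_csv(s$graph,
                       file.path(dir, paste0(id, "_nodes.csv")),
                       file.path(dir, paste0(id, "_edges.csv")))
    cells_flat <- s$cells
    cells_flat$n_nodes <- vapply(cells_flat$node_ids, length, integer(1))
    cells_flat$node_ids <- NULL
    utils::write.csv(cells_flat, file.path(dir, paste0(id, "_cells.csv")),
                     row.names = FALSE)
  }
  if (nrow(run$features) > 0L) {
    utils::write.csv(run$features, file.path(dir, "features.csv"),
                     row.names = FALSE)
    roster <- feature_roster()
    jsonlite::write_json(roster, file.path(dir, "features_schema.json"),
                         digits = NA)
  }
  if (!is.null(run$roc)) {
    utils::write.csv(run$roc, file.path(dir, "roc.csv"), row.names = FALSE)
  }
  if (!is.null(run$pca)) {
    jsonlite::write_json(
      list(selected_features = run$pca$selected_features,
           loadings = as.data.frame(run$pca$loadings),
           explained_variance_fraction =
             run$pca$explained_variance_fraction,
           orientation_sign = run$pca$orientation_sign),
      file.path(dir, "pca.json"), digits = NA)
    utils::write.csv(run$pca$scores, file.path(dir, "scores.csv"),
                     row.names = FALSE)
  }
  writeLines(vapply(run$log, jsonlite::toJSON, character(1),
                    auto_unbox = TRUE),
             file.path(dir, "log.jsonl"))
  invisible(dir)
}
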