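normalise_k <- function(clustering) {
  ks <- clustering$k %||% clustering$k_range
  if (is.null(ks)) abort("config must give `clustering$k` (a value or a range)")
  sort(unique(as.integer(unlist(ks))))
}

distances_requested <- function(config) {
  switch(config$distance, semantic = "semantic", gower = "gower",
         both = c("semantic", "gower"))
}

run_stage <- function(log_path, stage, params, fun) {
  log_line(log_path, stage, "start", params)
  out <- tryCatch(fun(), error = function(e) {
    log_line(log_path, stage, "error", conditionMessage(e))
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
  log_line(log_path, stage, "end", "")
  out
}

#' Compute and export all distance artifacts
#'
#' Stage 1 of the pipeline: builds one modality distance matrix per
#' qualitative variable, normalises them to the common 0-100 scale,
#' validates the dataset against the modality sets, computes the requested
#' individual distance matrices (semantic and/or Gower) and exports
#' everything (workbook + CSVs) under `output_dir`.
#'
#' @param config A [read_pipeline_config()] result.
#' @param output_dir Artifact directory (defaults to the config's).
#' @return Invisibly, the list of written files.
#' @export
stage_distances <- function(config, output_dir = config$output_dir) {
  log_path <- open_run_log(output_dir)
  run_stage(log_path, "distances",
            sprintf("distance=%s seed=%d", config$distance, config$seed), function() {
    built <- build_all_modality_matrices(config$specs)
    dataset <- read_trait_table(config$dataset, config$specs,
                                modalities = built$modalities)
    files <- export_matrices(
      c(lapply(built$raw, plain_matrix),
        setNames(lapply(built$normalised, plain_matrix),
                 paste0(names(built$normalised), "_normalised"))),
      workbook_path = file.path(output_dir, "modality_matrices.xml"),
      csv_dir = file.path(output_dir, "matrices"))
    for (d in distances_requested(config)) {
      idm <- if (d == "semantic") {
        semantic_distance_matrix(dataset, built$normalised)
      } else {
        gower_distance_matrix(dataset)
      }
      files <- c(files, export_matrices(
        setNames(list(idm$D, idm$cardinality + 0), paste0(d, c("_D", "_M"))),
        workbook_path = file.path(output_dir, paste0(d, "_distance.xml")),
        csv_dir = file.path(output_dir, "distances")))
    }
    readr::write_csv(tibble(id = dataset$id, n_missing = unname(missing_counts(dataset))),
                     file.path(output_dir, "missing_counts.csv"), progress = FALSE)
    invisible(files)
  })
}

#' Project the distance matrices into coordinate space
#'
#' Stage 2: reads the exported distance matrices, applies the
#' undefined-pair policy, embeds with the configured method and
#' dimensionality, and writes coordinates plus diagnostics (eigenvalue
#' scree for PCoA and Laplacian eigenmaps, a stress-1-by-dimension profile
#' for metric MDS).
#'
#' @inheritParams stage_distances
#' @return Invisibly, the embeddings (named by distance).
#' @export
stage_embed <- function(config, output_dir = config$output_dir) {
  log_path <- open_run_log(output_dir)
  red <- config$reduction
  run_stage(log_path, "embed",
            sprintf("method=%s n_dims=%d seed=%d", red$method, red$n_dims, config$seed),
            function() {
    out <- list()
    for (d in distances_requested(config)) {
      D <- read_matrix_csv(file.path(output_dir, "distances", paste0(d, "_D.csv")))
      D <- resolve_undefined(D, policy = red$undefined_policy)
      emb <- switch(red$method,
        pcoa = embed_pcoa(D, red$n_dims),
        mmds = embed_mmds(D, red$n_dims, seed = stage_seed(config$seed, paste0("embed-", d)),
                          n_init = red$n_init, max_iter = red$max_iter, tol = red$tol),
        laplacian = embed_laplacian(D, red$n_dims))
      readr::write_csv(tidy(emb),
                       file.path(output_dir, paste0("coordinates_", d, ".csv")),
                       progress = FALSE)
      if (length(emb$eigenvalues)) {
        readr::write_csv(tibble(component = seq_along(emb$eigenvalues),
                                eigenvalue = emb$eigenvalues),
                         file.path(output_dir, paste0("eigenvalues_", d, ".csv")),
                         progress = FALSE)
      }
      if (red$method == "mmds") {
        prof <- stress_profile(D, seq_len(red$n_dims),
                               seed = stage_seed(config$seed, paste0("profile-", d)),
                               n_init = red$n_init, max_iter = red$max_iter,
                               tol = red$tol)
        readr::write_csv(prof, file.path(output_dir, paste0("stress_by_k_", d, ".csv")),
                         progress = FALSE)
      }
      out[[d]] <- emb
    }
    invisible(out)
  })
}

read_coordinates <- function(output_dir, d) {
  df <- readr::read_csv(file.path(output_dir, paste0("coordinates_", d, ".csv")),
                        show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Cluster the embedded individuals
#'
#' Stage 3: runs every configured algorithm for every requested cluster
#' count on each distance's coordinates; writes the labels, per-individual
#' silhouettes, and concordance tables (each algorithm against the k-means
#' reference, and semantic against Gower when both distances run).
#'
#' @inheritParams stage_distances
#' @return Invisibly, the partitions (nested list distance/algorithm/k).
#' @export
stage_cluster <- function(config, output_dir = config$output_dir) {
  log_path <- open_run_log(output_dir)
  ks <- normalise_k(config$clustering)
  algs <- config$clustering$algorithms
  run_stage(log_path, "cluster",
            sprintf("algorithms=%s k=%s seed=%d", paste(algs, collapse = "+"),
                    paste(ks, collapse = "+"), config$seed), function() {
    labels_rows <- list(); sil_rows <- list(); parts <- list()
    for (d in distances_requested(config)) {
      coords <- read_coordinates(output_dir, d)
      n <- nrow(coords)
      for (alg in algs) for (k in ks) {
        part <- cluster_individuals(coords, alg, k, seed = config$seed)
        parts[[d]][[alg]][[as.character(k)]] <- part
        labels_rows[[length(labels_rows) + 1]] <-
          mutate(tidy(part), distance = d, .before = 1)
        if (k >= 2 && k <= n - 1) {
          sil <- silhouette_individuals(coords, part)
          sil_rows[[length(sil_rows) + 1]] <-
            mutate(sil, distance = d, algorithm = alg, k = k, .before = 1)
        }
      }
      if ("kmeans" %in% algs) {
        for (alg in setdiff(algs, "kmeans")) for (k in ks) {
          ct <- concordance(parts[[d]][["kmeans"]][[as.character(k)]],
                            parts[[d]][[alg]][[as.character(k)]])
          write_matrix_csv(matrix(as.numeric(ct), nrow(ct), ncol(ct),
                                  dimnames = dimnames(ct)),
                           file.path(output_dir,
                                     sprintf("concordance_kmeans_vs_%s_%s_k%d.csv",
                                             alg, d, k)))
        }
      }
    }
    if (config$distance == "both") {
      for (alg in algs) for (k in ks) {
        ct <- concordance(parts$semantic[[alg]][[as.character(k)]],
                          parts$gower[[alg]][[as.character(k)]])
        write_matrix_csv(matrix(as.numeric(ct), nrow(ct), ncol(ct),
                                dimnames = dimnames(ct)),
                         file.path(output_dir,
                                   sprintf("concordance_semantic_vs_gower_%s_k%d.csv",
                                           alg, k)))
      }
    }
    readr::write_csv(bind_rows(labels_rows), file.path(output_dir, "labels.csv"),
                     progress = FALSE)
    if (length(sil_rows)) {
      readr::write_csv(bind_rows(sil_rows), file.path(output_dir, "silhouettes.csv"),
                       progress = FALSE)
    }
    invisible(parts)
  })
}

read_partitions <- function(config, output_dir) {
  df <- readr::read_csv(file.path(output_dir, "labels.csv"),
                        show_col_types = FALSE, progress = FALSE)
  parts <- list()
  for (key in unique(paste(df$distance, df$algorithm, df$k))) {
    sub <- df[paste(df$distance, df$algorithm, df$k) == key, ]
    parts[[sub$distance[1]]][[sub$algorithm[1]]][[as.character(sub$k[1])]] <-
      new_partition(sub$id, sub$cluster, sub$algorithm[1], sub$k[1], config$seed)
  }
  parts
}

#' Select archetypes for every partition
#'
#' Stage 4: reads the stored labels and coordinates and selects, per
#' distance/algorithm/k, either the centroid-nearest individual per cluster
#' or a seeded 5% random sample per cluster.
#'
#' @inheritParams stage_distances
#' @return Invisibly, the archetype table written to `archetypes.csv`.
#' @export
stage_archetypes <- function(config, output_dir = config$output_dir) {
  log_path <- open_run_log(output_dir)
  run_stage(log_path, "archetypes",
            sprintf("mode=%s fraction=%g seed=%d", config$archetypes$mode,
                    config$archetypes$fraction, config$seed), function() {
    parts <- read_partitions(config, output_dir)
    rows <- list()
    for (d in names(parts)) {
      coords <- read_coordinates(output_dir, d)
      for (alg in names(parts[[d]])) for (k in names(parts[[d]][[alg]])) {
        part <- parts[[d]][[alg]][[k]]
        aset <- if (config$archetypes$mode == "single") {
          single_archetype(coords, part)
        } else {
          multiple_archetypes(part, fraction = config$archetypes$fraction,
                              seed = config$seed)
        }
        rows[[length(rows) + 1]] <- mutate(as_tibble(aset), distance = d,
                                           algorithm = alg, k = as.integer(k),
                                           .before = 1)
      }
    }
    out <- bind_rows(rows)
    readr::write_csv(out, file.path(output_dir, "archetypes.csv"), progress = FALSE)
    invisible(out)
  })
}

#' Render the run's figures
#'
#' Stage 5: distance-matrix heatmaps, the dual-triangle scatterplot matrix
#' (first configured algorithm and cluster count), and the silhouette plot
#' when silhouettes were computed.
#'
#' @inheritParams stage_distances
#' @return Invisibly, the figure paths.
#' @export
stage_plot <- function(config, output_dir = config$output_dir) {
  log_path <- open_run_log(output_dir)
  run_stage(log_path, "plot", sprintf("palette=%d colours", length(config$palette)),
            function() {
    figdir <- file.path(output_dir, "figures")
    style <- plot_style(palette = config$palette)
    parts <- read_partitions(config, output_dir)
    mc_df <- readr::read_csv(file.path(output_dir, "missing_counts.csv"),
                             show_col_types = FALSE, progress = FALSE)
    mc <- setNames(mc_df$n_missing, mc_df$id)
    arch <- readr::read_csv(file.path(output_dir, "archetypes.csv"),
                            show_col_types = FALSE, progress = FALSE)
    files <- character()
    alg1 <- config$clustering$algorithms[1]
    k1 <- as.character(normalise_k(config$clustering)[1])
    for (d in names(parts)) {
      D <- read_matrix_csv(file.path(output_dir, "distances", paste0(d, "_D.csv")))
      p <- file.path(figdir, paste0("heatmap_", d, ".png"))
      plot_heatmap(D, out_path = p, title = paste(d, "distance"))
      files <- c(files, p)
      coords <- read_coordinates(output_dir, d)
      if (ncol(coords) >= 2) {
        part <- parts[[d]][[alg1]][[k1]]
        sub <- arch[arch$distance == d & arch$algorithm == alg1 & arch$k == as.integer(k1), ]
        aset <- new_archetype_set(sub[, c("cluster", "id", "mode")],
                                  mode = config$archetypes$mode)
        p <- file.path(figdir, paste0("scatterplot_matrix_", d, ".png"))
        scatterplot_matrix(coords, part, aset, missing_counts = mc,
                           style = style, out_path = p)
        files <- c(files, p)
      }
    }
    sil_path <- file.path(output_dir, "silhouettes.csv")
    if (file.exists(sil_path)) {
      sil <- readr::read_csv(sil_path, show_col_types = FALSE, progress = FALSE)
      sub <- sil[sil$distance == sil$distance[1] & sil$algorithm == sil$algorithm[1] &
                   sil$k == sil$k[1], c("id", "cluster", "silhouette")]
      p <- file.path(figdir, "silhouettes.png")
      save_figure(plot_silhouettes(sub, style), p)
      files <- c(files, p)
    }
    invisible(files)
  })
}

#' Run the whole pipeline from a configuration
#'
#' Executes, in order: modality matrices and normalisation, individual
#' distances (semantic and/or Gower), undefined-pair resolution, dimension
#' reduction with diagnostics, clustering with silhouettes and
#' concordances, archetype selection, and figures. Every stage is logged
#' with its parameters and the seed to `run.log`; the config is echoed
#' next to the artifacts; re-running with the same config and seed
#' reproduces every numeric artifact exactly. A failing stage aborts with
#' a stage-named error and leaves earlier artifacts in place.
#'
#' @param config A [read_pipeline_config()] result or a YAML path.
#' @param output_dir Artifact directory (defaults to the config's).
#' @return Invisibly, a `run_artifacts` list of the files written.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  output_dir <- output_dir %||% config$output_dir
  log_path <- open_run_log(output_dir)
  log_line(log_path, "run", "start", sprintf("seed=%d", config$seed))
  echo <- config
  echo$specs <- NULL
  echo$output_dir <- output_dir
  yaml::write_yaml(unclass(echo), file.path(output_dir, "config_echo.yaml"))
  stage_distances(config, output_dir)
  stage_embed(config, output_dir)
  stage_cluster(config, output_dir)
  stage_archetypes(config, output_dir)
  stage_plot(config, output_dir)
  log_line(log_path, "run", "end", "")
  files <- list.files(output_dir, recursive = TRUE, full.names = TRUE)
  invisible(structure(list(output_dir = output_dir, files = files),
                      class = "run_artifacts"))
}
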