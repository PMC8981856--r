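#' Styling for the cluster scatterplot matrix
#'
#' @param palette Ordered colour vector (at least one colour per cluster);
#'   defaults to the colour-vision-deficiency-safe [default_palette()].
#' @param alpha Transparency of the full-population dots (occlusion
#'   relief in the lower triangle).
#' @param size_range Length-2 numeric: dot sizes mapped to the missing-value
#'   count. The map is strictly increasing — individuals with more missing
#'   variables get larger dots, flagging less reliable positions.
#' @return A `plot_style` list.
#' @export
plot_style <- function(palette = default_palette(), alpha = 0.4,
                       size_range = c(1, 4)) {
  if (length(size_range) != 2 || size_range[1] >= size_range[2]) {
    abort("`size_range` must be increasing (larger dots = more missing values)")
  }
  structure(list(palette = palette, alpha = alpha, size_range = size_range),
            class = "plot_style")
}

#' Dot size for a missing-value count
#'
#' Strictly increasing linear map from missing count to dot size over the
#' style's `size_range`.
#'
#' @param style A [plot_style()].
#' @param missing_count Integer vector of missing-variable counts.
#' @param max_missing Count mapped to the largest size.
#' @return Numeric sizes.
#' @export
size_map <- function(style, missing_count, max_missing = max(missing_count, 1)) {
  span <- style$size_range[2] - style$size_range[1]
  style$size_range[1] + span * missing_count / max(max_missing, 1)
}

#' Dual-triangle scatterplot matrix of an embedding
#'
#' One panel grid per pair of embedding dimensions. The lower triangle
#' shows the whole population, cluster-coloured, alpha-blended, with dot
#' sizes increasing with each individual's missing-value count. The upper
#' triangle shows only the archetypes plus per-cluster 2-D kernel density
#' contours, giving a decluttered estimate of the group envelopes. The
#' diagonal carries per-dimension density curves by cluster.
#'
#' @param embedding `trait_embedding` (at least 2 dimensions) or matrix.
#' @param partition A `trait_partition`.
#' @param archetypes An `archetype_set`.
#' @param missing_counts Named integer vector from [missing_counts()];
#'   defaults to all zeros.
#' @param style A [plot_style()].
#' @param out_path Optional figure path (`.png` or `.svg`).
#' @param width,height Device size in inches when writing a file.
#' @return The assembled patchwork object, invisibly.
#' @export
scatterplot_matrix <- function(embedding, partition, archetypes,
                               missing_counts = NULL, style = plot_style(),
                               out_path = NULL, width = 10, height = 10) {
  coords <- if (inherits(embedding, "trait_embedding")) embedding$coordinates else embedding
  kd <- ncol(coords)
  if (kd < 2) abort("the scatterplot matrix needs at least 2 embedding dimensions")
  ids <- rownames(coords) %||% as.character(seq_len(nrow(coords)))
  if (length(style$palette) < partition$k) {
    abort(sprintf("palette has %d colours for %d clusters", length(style$palette), partition$k))
  }
  mc <- missing_counts %||% setNames(rep(0L, length(ids)), ids)
  colnames(coords) <- paste0("dim", seq_len(kd))
  df <- as_tibble(coords)
  df$id <- ids
  df$cluster <- factor(partition$labels[match(ids, partition$ids)])
  df$n_missing <- as.integer(mc[ids])
  df$size <- size_map(style, df$n_missing)
  arch_df <- df[df$id %in% archetypes$id, , drop = FALSE]
  pal <- style$palette[seq_len(partition$k)]
  names(pal) <- levels(df$cluster)

  panel <- function(i, j) {
    xv <- paste0("dim", j); yv <- paste0("dim", i)
    if (i == j) {
      p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xv]], colour = .data$cluster)) +
        ggplot2::geom_density() +
        ggplot2::labs(x = xv, y = "density")
    } else if (i > j) {
      p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xv]], y = .data[[yv]],
                                            colour = .data$cluster)) +
        ggplot2::geom_point(ggplot2::aes(size = .data$n_missing),
                            alpha = style$alpha, show.legend = (i == kd && j == 1)) +
        ggplot2::scale_size_continuous(name = "NA variables",
                                       range = style$size_range) +
        ggplot2::labs(x = xv, y = yv)
    } else {
      p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xv]], y = .data[[yv]],
                                            colour = .data$cluster))
      for (cl in levels(df$cluster)) {
        sub <- df[df$cluster == cl, , drop = FALSE]
        if (nrow(sub) >= 3 && stats::sd(sub[[xv]]) > 0 && stats::sd(sub[[yv]]) > 0) {
          p <- p + ggplot2::geom_density_2d(data = sub, linewidth = 0.3,
                                            show.legend = FALSE)
        }
      }
      p <- p +
        ggplot2::geom_point(data = arch_df, shape = 17, size = 2.5,
                            show.legend = FALSE) +
        ggplot2::labs(x = xv, y = yv)
    }
    p + ggplot2::scale_colour_manual(values = pal, name = "cluster", drop = FALSE) +
      ggplot2::theme_minimal(base_size = 8)
  }
  panels <- list()
  for (i in seq_len(kd)) for (j in seq_len(kd)) {
    panels[[length(panels) + 1]] <- panel(i, j)
  }
  fig <- patchwork::wrap_plots(panels, ncol = kd, guides = "collect")
  if (!is.null(out_path)) save_figure(fig, out_path, width, height)
  invisible(fig)
}

#' Heatmap of a labelled matrix
#'
#' Colour-mapped image with axis labels, used for individual distance
#' matrices and concordance tables. Row order is preserved top-to-bottom.
#'
#' @param m Labelled numeric matrix (distance or concordance counts).
#' @param out_path Optional figure path (`.png`/`.svg`).
#' @param title Optional plot title.
#' @param width,height Device size in inches when writing a file.
#' @return The ggplot, invisibly.
#' @export
plot_heatmap <- function(m, out_path = NULL, title = NULL, width = 7, height = 6) {
  if (!length(m)) abort("cannot draw a heatmap of an empty matrix")
  m <- plain_matrix(m)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m)) - 1
  if (is.null(colnames(m))) colnames(m) <- seq_len(ncol(m)) - 1
  df <- as_tibble(as.table(m), .name_repair = ~c("row", "col", "value"))
  df$row <- factor(df$row, levels = rev(rownames(m)))
  df$col <- factor(df$col, levels = colnames(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(out_path)) save_figure(p, out_path, width, height)
  invisible(p)
}

save_figure <- function(p, path, width = 7, height = 6) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  dev <- if (grepl("\\.svg$", path, ignore.case = TRUE)) grDevices::svg else NULL
  ggplot2::ggsave(path, plot = p, width = width, height = height,
                  dpi = 120, device = dev)
  invisible(path)
}

#' @describeIn embed_pcoa Diagnostic plot: eigenvalue scree (pcoa,
#'   laplacian) or a stress-1 annotated first-plane scatter (mmds).
#' @param object A `trait_embedding`.
#' @export
autoplot.trait_embedding <- function(object, ...) {
  if (length(object$eigenvalues)) {
    df <- tibble(component = seq_along(object$eigenvalues),
                 eigenvalue = object$eigenvalues)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(title = sprintf("%s eigenvalue scree", object$method)) +
      ggplot2::theme_minimal()
  } else {
    df <- tidy(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(title = sprintf("%s embedding (stress1 = %.3f)",
                                    object$method, object$stress1)) +
      ggplot2::theme_minimal()
  }
}

#' @describeIn semantic_distance_matrix Heatmap of the distance matrix.
#' @param object An `individual_dist`.
#' @export
autoplot.individual_dist <- function(object, ...) {
  plot_heatmap(object$D, title = sprintf("%s distance matrix", object$method))
}

#' Silhouette diagnostic plot
#'
#' Horizontal per-individual silhouette bars grouped by cluster with the
#' mean silhouette as a dashed reference line.
#'
#' @param sil Tibble from [silhouette_individuals()].
#' @param style A [plot_style()].
#' @return A ggplot.
#' @export
plot_silhouettes <- function(sil, style = plot_style()) {
  sil$pos <- seq_len(nrow(sil))
  pal <- style$palette[seq_len(length(unique(sil$cluster)))]
  names(pal) <- sort(unique(sil$cluster))
  ggplot2::ggplot(sil, ggplot2::aes(x = .data$pos, y = .data$silhouette,
                                    fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = mean(sil$silhouette),
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_fill_manual(values = pal, name = "cluster") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "silhouette") +
    ggplot2::theme_minimal()
}
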