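#' Fold-change trajectory matrix
#'
#' One row per feature, one column per non-baseline stage, holding log2
#' fold-changes versus the baseline. Row order follows the input.
#'
#' @param de a `de_result` (all comparisons present by construction).
#' @return tibble: id column, then one `log2fc` column per comparison
#'   (named by stage).
#' @export
build_trajectories <- function(de) {
  stopifnot(inherits(de, "de_result"))
  wide <- de$table |>
    select(all_of(de$id_col), "stage", "log2fc") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "log2fc")
  if (anyNA(wide)) stop("missing comparison for some features", call. = FALSE)
  wide[match(de$counts[[de$id_col]], wide[[de$id_col]]), ]
}

#' Hierarchical clustering of fold-change trajectories
#'
#' Agglomerative clustering (default: average linkage, Euclidean metric)
#' of log2 fold-change trajectories, cut into `k` groups. Fold-changes are
#' already on a common scale, so rows are not standardized. Cluster labels
#' are canonical Roman numerals: clusters ordered by ascending mean
#' trajectory, ties by size, so permuting input rows yields identical
#' labels.
#'
#' @param traj output of [build_trajectories()] (id column first).
#' @param k number of clusters (default 8, the archetype count typical of
#'   staged grain-filling profiles).
#' @param linkage `"average"` (default) or `"complete"`.
#' @param metric distance metric, `"euclidean"`.
#' @return a `mirna_clusters` object; see [tidy.mirna_clusters()].
#' @export
cluster_trajectories <- function(traj, k = 8, linkage = c("average", "complete"),
                                 metric = "euclidean") {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  id_col <- names(traj)[1]
  m <- as.matrix(traj[, -1, drop = FALSE])
  rownames(m) <- traj[[id_col]]
  if (k < 1 || k > nrow(m)) stop("k must be in [1, rows]", call. = FALSE)
  tree <- hclust(dist(m, method = metric), method = linkage)
  raw <- cutree(tree, k = k)

  # canonical relabeling: ascending mean trajectory, then size
  means <- tapply(rowMeans(m), raw, mean)
  sizes <- tapply(raw, raw, length)
  ord <- order(means, sizes)
  relabel <- setNames(seq_along(ord), names(means)[ord])
  lab <- roman_labels(k)[relabel[as.character(raw)]]
  assignment <- tibble(!!id_col := rownames(m),
                       cluster = factor(lab, levels = roman_labels(k)))
  structure(
    list(assignment = assignment, tree = tree, k = k, traj = traj,
         id_col = id_col, linkage = linkage, metric = metric),
    class = "mirna_clusters"
  )
}

#' @export
print.mirna_clusters <- function(x, ...) {
  cat("Trajectory clustering: ", nrow(x$assignment), " features, k = ",
      x$k, " (", x$linkage, " linkage)\n", sep = "")
  print(table(x$assignment$cluster))
  invisible(x)
}

#' Tidy a trajectory clustering
#' @param x a `mirna_clusters`.
#' @param ... unused.
#' @return one row per feature: id, cluster label, trajectory columns.
#' @export
tidy.mirna_clusters <- function(x, ...) {
  left_join(x$assignment, x$traj, by = x$id_col)
}

#' Per-cluster archetype summary
#'
#' @param x a `mirna_clusters`.
#' @param ... unused.
#' @return one row per cluster: size, per-stage mean log2 fold-change and
#'   a monotonicity class (`up`, `down`, `transient_up`, `transient_down`,
#'   `flat`).
#' @export
glance.mirna_clusters <- function(x, ...) summarize_clusters(x)

#' @rdname glance.mirna_clusters
#' @param eps dead zone (log2 units) below which a mean fold-change counts
#'   as unchanged (default 0.25).
#' @export
summarize_clusters <- function(x, eps = 0.25) {
  stopifnot(inherits(x, "mirna_clusters"))
  td <- tidy(x)
  stages <- setdiff(names(x$traj), x$id_col)
  out <- td |>
    group_by(.data$cluster) |>
    summarise(size = dplyr::n(),
              across(all_of(stages), mean),
              .groups = "drop")
  m <- as.matrix(out[, stages, drop = FALSE])
  out$class <- apply(m, 1, function(v) {
    last <- v[length(v)]
    if (last > eps) {
      if (min(v) < -eps) "transient_down" else "up"
    } else if (last < -eps) {
      if (max(v) > eps) "transient_up" else "down"
    } else {
      if (max(v) > eps) "transient_up"
      else if (min(v) < -eps) "transient_down"
      else "flat"
    }
  })
  out
}

#' @export
autoplot.mirna_clusters <- function(object, ...) {
  td <- tidy(object)
  stages <- setdiff(names(object$traj), object$id_col)
  long <- td |>
    tidyr::pivot_longer(all_of(stages), names_to = "stage",
                        values_to = "log2fc") |>
    mutate(stage = factor(.data$stage, levels = stages))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$stage, y = .data$log2fc,
                               group = .data[[object$id_col]])) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "stage (vs baseline)", y = "log2 fold-change") +
    ggplot2::theme_minimal()
}

#' Export a clustering dendrogram as Newick
#'
#' @param x a `mirna_clusters`.
#' @param path output file.
#' @return `path`, invisibly. Requires the `ape` package.
#' @export
write_dendrogram <- function(x, path) {
  stopifnot(inherits(x, "mirna_clusters"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export", call. = FALSE)
  }
  ape::write.tree(ape::as.phylo(x$tree), file = path)
  invisible(path)
}
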