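#' Ward agglomerative clustering of importance maps
#'
#' Hierarchically clusters the per-patient 48-dimensional feature-importance
#' maps with the Ward criterion (minimum variance increase) on Euclidean
#' distances and cuts the tree at `k` clusters. Distances are computed on
#' the raw effect-size maps without standardisation, since all 48
#' coordinates already share the probability scale.
#'
#' @param maps A patients x 48 matrix of effect sizes.
#' @param k Number of clusters (default 2, the headline cut).
#' @return An object of class `cluster_result`: list with `hclust` (the
#'   linkage tree), `labels`, `k`, `mean_maps` (k x 48), `cluster_sizes`.
#' @export
ward_cluster <- function(maps, k = 2L) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (k > n) stop("k must not exceed the number of patients", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  hc <- stats::hclust(stats::dist(maps), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  res <- list(hclust = hc,
              labels = labels,
              k = as.integer(k),
              mean_maps = cluster_mean_maps(maps, labels),
              cluster_sizes = as.integer(table(labels)))
  class(res) <- "cluster_result"
  res
}

#' Per-cluster mean importance maps
#'
#' @param maps A patients x 48 matrix.
#' @param labels Cluster id per patient (a valid partition).
#' @return A k x 48 matrix of arithmetic means, item order preserved.
#' @export
cluster_mean_maps <- function(maps, labels) {
  maps <- as.matrix(maps)
  stopifnot(length(labels) == nrow(maps), !anyNA(labels))
  ks <- sort(unique(labels))
  out <- t(vapply(ks, function(g)
    colMeans(maps[labels == g, , drop = FALSE]), numeric(ncol(maps))))
  rownames(out) <- paste0("cluster", ks)
  colnames(out) <- colnames(maps)
  out
}

#' Identify the limited-effect cluster in a two-cluster solution
#'
#' Of the two clusters, the one whose mean importance map has the smaller
#' L1 norm is the "limited-effect" subgroup — the patients whose remission
#' probability the comorbidity items barely move. Exact ties break toward
#' the lower cluster id and are flagged.
#'
#' @param result A `cluster_result` with `k = 2`.
#' @return List with `limited_cluster`, `l1_norms`, `cluster_sizes`,
#'   `limited_fraction` and `tie`.
#' @export
near_zero_cluster_report <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  if (result$k != 2L)
    stop("the report is defined for the two-cluster solution", call. = FALSE)
  stopifnot(all(result$cluster_sizes > 0))   # cutree cannot emit empty clusters
  norms <- rowSums(abs(result$mean_maps))
  tie <- norms[1] == norms[2]
  limited <- if (tie) 1L else unname(which.min(norms))
  list(limited_cluster = limited,
       l1_norms = norms,
       cluster_sizes = result$cluster_sizes,
       limited_fraction = result$cluster_sizes[limited] /
         sum(result$cluster_sizes),
       tie = tie)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, sizes: %s\n", x$k,
              paste(x$cluster_sizes, collapse = "/")))
  invisible(x)
}
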