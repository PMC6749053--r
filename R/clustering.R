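#' k-means clustering of LCA rows
#'
#' Lloyd iterations (via [stats::kmeans()]) from k-means++ seeding, repeated
#' `restarts` times with the best run chosen by the within-cluster squared
#' Euclidean distance objective.  Deterministic for a fixed seed.  Besides
#' the squared-distance objective, the plain sum of Euclidean distances of
#' rows to their centers (`within_distance_sum`, the elbow-plot quantity)
#' and the mean silhouette width are reported.
#'
#' @param x An `slc_lca` tibble, a numeric matrix, or a data frame of
#'   numeric columns (rows are observations).
#' @param k Number of clusters (`1 <= k <=` number of distinct rows).
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts.
#' @return An object of class `slc_clustering`: `k`, `labels`, `centers`,
#'   `tot_withinss`, `within_distance_sum`, `mean_silhouette` (NA for
#'   `k = 1`), `sizes`.
#' @export
slc_kmeans <- function(x, k, seed = 1L, restarts = 10L) {
  X <- lca_values(x)
  k <- check_positive_int(k, "k")
  n <- nrow(X)
  if (n < 2) stop_bad_arg("need at least 2 rows")
  if (k > n) stop_bad_arg("`k` = ", k, " exceeds the ", n, " rows")
  n_unique <- nrow(unique(X))
  if (k > n_unique) {
    stop_bad_arg("`k` = ", k, " exceeds the ", n_unique, " distinct rows")
  }

  if (k == 1) {
    center <- matrix(colMeans(X), 1)
    d <- sqrt(rowSums((X - center[rep(1, n), , drop = FALSE])^2))
    return(structure(
      list(k = 1L, labels = rep(1L, n), centers = center,
           tot_withinss = sum(d^2), within_distance_sum = sum(d),
           mean_silhouette = NA_real_, sizes = n),
      class = "slc_clustering"))
  }

  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(restarts)) {
      fit <- NULL
      for (attempt in 1:5) {   # re-seed on empty-cluster collapse
        init <- kmeanspp_init(X, k)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(X, centers = init, iter.max = 100L,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop_bad_arg("k-means failed to produce a valid clustering")

  d_own <- sqrt(rowSums((X - best$centers[best$cluster, , drop = FALSE])^2))
  sil <- if (k < n) {
    mean(cluster::silhouette(best$cluster, dist(X))[, "sil_width"])
  } else {
    NA_real_
  }
  structure(
    list(k = k, labels = as.integer(best$cluster), centers = best$centers,
         tot_withinss = best$tot.withinss, within_distance_sum = sum(d_own),
         mean_silhouette = sil, sizes = as.integer(best$size)),
    class = "slc_clustering"
  )
}

# k-means++ seeding: iteratively sample centers with probability
# proportional to squared distance from the nearest chosen center.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  centers[1, ] <- X[idx[1], ]
  d2 <- rowSums((X - centers[rep(1, n), , drop = FALSE])^2)
  for (j in seq_len(k)[-1]) {
    if (all(d2 <= 0)) {
      pool <- setdiff(seq_len(n), idx[seq_len(j - 1)])
      idx[j] <- if (length(pool) > 1) sample(pool, 1) else pool
    } else {
      idx[j] <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- X[idx[j], ]
    d2 <- pmin(d2, rowSums((X - centers[rep(j, n), , drop = FALSE])^2))
  }
  # duplicate initial centers make Lloyd collapse; nudge exact duplicates
  dup <- duplicated(centers)
  if (any(dup)) {
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(rnorm(sum(dup) * ncol(X), 0, 1e-8), sum(dup))
  }
  centers
}

#' @export
print.slc_clustering <- function(x, ...) {
  cat("<slc_clustering> k = ", x$k, ", sizes: ",
      paste(x$sizes, collapse = ", "), "\n", sep = "")
  cat(sprintf("  within-SS %.3f, distance sum %.3f, mean silhouette %s\n",
              x$tot_withinss, x$within_distance_sum,
              ifelse(is.na(x$mean_silhouette), "NA",
                     sprintf("%.3f", x$mean_silhouette))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slc_clustering <- function(x, ...) {
  tibble(row = seq_along(x$labels), cluster = x$labels)
}

#' @exportS3Method generics::glance
glance.slc_clustering <- function(x, ...) {
  tibble(k = x$k, tot_withinss = x$tot_withinss,
         within_distance_sum = x$within_distance_sum,
         mean_silhouette = x$mean_silhouette)
}

#' Scan cluster numbers and select k by peak silhouette
#'
#' Runs [slc_kmeans()] for every `k` in `[k_min, k_max]`, recording the mean
#' silhouette and the within-cluster distance sum (the elbow curve, reported
#' as advisory output).  The selected `k` is the silhouette argmax, smallest
#' `k` on ties.  Values of `k` exceeding the number of distinct rows are
#' recorded as `NA` and excluded from selection, so degenerate inputs with
#' duplicated rows are handled without failure.
#'
#' @param x Rows to cluster (as in [slc_kmeans()]).
#' @param k_min,k_max Inclusive scan range (`k_max` capped at the row count).
#' @param seed,restarts Passed to [slc_kmeans()].
#' @return An object of class `slc_kscan`: `scan` tibble (`k`, `silhouette`,
#'   `within_distance_sum`, `tot_withinss`), `selected_k`, and the
#'   `clusterings` list.  [tidy()] returns the scan tibble;
#'   [autoplot()] draws the silhouette and elbow curves.
#' @export
scan_k <- function(x, k_min = 2L, k_max = 100L, seed = 1L, restarts = 10L) {
  X <- lca_values(x)
  k_min <- check_positive_int(k_min, "k_min")
  k_max <- check_positive_int(k_max, "k_max")
  if (k_min > k_max) stop_bad_arg("`k_min` must not exceed `k_max`")
  if (k_max > nrow(X)) stop_bad_arg("`k_max` exceeds the number of rows")

  ks <- k_min:k_max
  fits <- purrr::map(ks, function(k) {
    tryCatch(slc_kmeans(X, k, seed = seed + k, restarts = restarts),
             cellslc_argument_error = function(e) NULL)
  })
  scan <- tibble(
    k = ks,
    silhouette = purrr::map_dbl(fits, function(f) f$mean_silhouette %||% NA_real_),
    within_distance_sum = purrr::map_dbl(fits, function(f) f$within_distance_sum %||% NA_real_),
    tot_withinss = purrr::map_dbl(fits, function(f) f$tot_withinss %||% NA_real_)
  )
  sel <- if (all(is.na(scan$silhouette))) {
    NA_integer_
  } else {
    scan$k[which.max(scan$silhouette)]   # which.max takes the first (smallest k) on ties
  }
  structure(list(scan = scan, selected_k = sel, clusterings = fits),
            class = "slc_kscan")
}

#' @export
print.slc_kscan <- function(x, ...) {
  cat("<slc_kscan> k in [", min(x$scan$k), ", ", max(x$scan$k),
      "]; selected k = ", x$selected_k, " (peak silhouette ",
      sprintf("%.3f", max(x$scan$silhouette, na.rm = TRUE)), ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slc_kscan <- function(x, ...) x$scan

#' @exportS3Method ggplot2::autoplot
autoplot.slc_kscan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$scan,
                              c("silhouette", "within_distance_sum"),
                              names_to = "curve", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2) +
    ggplot2::facet_wrap(~ .data$curve, scales = "free_y", ncol = 1,
                        labeller = ggplot2::labeller(curve = c(
                          silhouette = "mean silhouette",
                          within_distance_sum = "within-cluster distance sum (elbow)"))) +
    ggplot2::labs(x = "k", y = NULL,
                  title = "Cluster-number scan") +
    ggplot2::theme_minimal()
}

#' Pairwise distance matrix with rows regrouped by cluster
#'
#' Reorders the Euclidean distance matrix so rows of the same cluster are
#' adjacent; with a meaningful clustering the diagonal blocks are darker
#' (smaller distances) than the off-diagonal blocks.
#'
#' @param x Rows (as in [slc_kmeans()]).
#' @param labels Cluster labels.
#' @return An object of class `slc_distmat`: the reordered symmetric matrix
#'   with attributes `order` and `labels` (sorted); [autoplot()] renders the
#'   heatmap.
#' @export
ordered_distance_matrix <- function(x, labels) {
  X <- lca_values(x)
  if (length(labels) != nrow(X)) stop_bad_arg("`labels` must match rows")
  D <- as.matrix(dist(X))
  ord <- order(labels)
  out <- D[ord, ord]
  attr(out, "order") <- ord
  attr(out, "labels") <- labels[ord]
  class(out) <- c("slc_distmat", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.slc_distmat <- function(object, ...) {
  n <- nrow(object)
  df <- tidyr::expand_grid(row = seq_len(n), col = seq_len(n))
  df$distance <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pairwise distances, rows grouped by cluster") +
    ggplot2::theme_minimal()
}

#' PCA + k-means baseline on raw pixels
#'
#' Flattens the images, mean-centers, projects onto the top principal
#' components, and k-means clusters the scores.  Serves as the baseline the
#' LCA representation is compared against: on rotated copies of the same
#' cell it tends to cluster by orientation rather than identity.
#'
#' @param cells Tibble with an `image` list-column, or a list of images.
#' @param n_components Number of principal components (>= 1).
#' @param k Number of clusters.
#' @param seed Seed for k-means.
#' @return A list of class `slc_pca_baseline`: `labels`, `scores`,
#'   `sdev`, `clustering`.
#' @export
pca_baseline <- function(cells, n_components, k, seed = 1L) {
  images <- if (is.data.frame(cells)) cells$image else cells
  if (length(images) < 2) stop_bad_arg("need at least 2 images")
  n_components <- check_positive_int(n_components, "n_components")
  X <- t(vapply(images, as.vector, numeric(length(images[[1]]))))
  if (n_components > ncol(X)) stop_bad_arg("`n_components` exceeds pixel count")
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  fit <- slc_kmeans(pc$x, k, seed = seed)
  structure(
    list(labels = fit$labels, scores = pc$x, sdev = pc$sdev,
         clustering = fit),
    class = "slc_pca_baseline"
  )
}
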