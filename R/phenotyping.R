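#' Cell area in pixels
#'
#' @param mask A binary mask (logical or 0/1 matrix).
#' @return Integer count of foreground pixels; an empty mask returns 0 with
#'   a warning.
#' @export
cell_area <- function(mask) {
  a <- sum(mask > 0)
  if (a == 0) warn("mask is empty; area 0")
  as.integer(a)
}

# Largest 4-connected component of a binary mask (stack-based flood fill).
largest_component <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  lab <- integer(H * W)
  cur <- 0L
  stack <- integer(sum(m))
  for (start in which(m)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- cur
    while (top > 0L) {
      px <- stack[top]
      top <- top - 1L
      r <- (px - 1L) %% H + 1L
      cc <- (px - 1L) %/% H + 1L
      if (r > 1L && m[px - 1L] && lab[px - 1L] == 0L) {
        lab[px - 1L] <- cur; top <- top + 1L; stack[top] <- px - 1L
      }
      if (r < H && m[px + 1L] && lab[px + 1L] == 0L) {
        lab[px + 1L] <- cur; top <- top + 1L; stack[top] <- px + 1L
      }
      if (cc > 1L && m[px - H] && lab[px - H] == 0L) {
        lab[px - H] <- cur; top <- top + 1L; stack[top] <- px - H
      }
      if (cc < W && m[px + H] && lab[px + H] == 0L) {
        lab[px + H] <- cur; top <- top + 1L; stack[top] <- px + H
      }
    }
  }
  if (cur <= 1L) return(m)
  sizes <- tabulate(lab[lab > 0L], cur)
  matrix(lab == which.max(sizes), H, W)
}

#' Count skeleton endpoints of a cell mask
#'
#' Thins the mask to a one-pixel skeleton (Zhang-Suen thinning) and counts
#' skeleton pixels with exactly one 8-connected skeleton neighbor; an
#' isolated skeleton pixel counts as one endpoint.  Skeleton endpoints proxy
#' the number of boundary protrusions.  Multi-component masks are reduced to
#' their largest 4-connected component with a warning.
#'
#' @param mask A binary mask.
#' @return Integer endpoint count (0 for an empty mask).
#' @export
skeleton_endpoints <- function(mask) {
  m <- mask > 0
  if (!any(m)) return(0L)
  comp <- largest_component(m)
  if (sum(comp) < sum(m)) warn("mask has multiple components; using the largest")
  skel <- thin_mask(comp * 1L) > 0
  nb <- neighbor_count(skel)
  as.integer(sum(skel & nb == 1) + sum(skel & nb == 0))
}

# 8-connected neighbor counts via shifted sums.
neighbor_count <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m * 1L
  out <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  out
}

#' Gray-level co-occurrence sum variance
#'
#' Haralick's sum-variance texture statistic of the masked region: the
#' intensities inside the mask are quantized to `levels` equal-width gray
#' levels over their observed range, a symmetric co-occurrence matrix is
#' accumulated at pixel offset `scale` over the four directions 0, 45,
#' 90 and 135 degrees (pairs with both ends inside the mask only), and the
#' variance of the gray-level pair sums about the sum average is returned:
#' `sum over s of (s - sum_average)^2 * p_{x+y}(s)`.  A constant region has
#' a single gray level and returns 0.
#'
#' @param image Intensity matrix.
#' @param mask Binary mask (same shape).
#' @param scale Pixel offset of the co-occurrence pairs.
#' @param levels Number of gray levels for quantization.
#' @return The sum-variance (nonnegative scalar).
#' @export
texture_sum_variance <- function(image, mask, scale = 5L, levels = 8L) {
  scale <- check_positive_int(scale, "scale")
  levels <- check_positive_int(levels, "levels")
  m <- mask > 0
  if (!any(m)) stop_bad_arg("mask is empty")
  vals <- image[m]
  rng <- range(vals)
  if (rng[1] == rng[2]) {
    g <- matrix(1L, nrow(image), ncol(image))
  } else {
    g <- matrix(pmin(levels, 1L + as.integer(floor(
      (image - rng[1]) / (rng[2] - rng[1]) * levels))),
      nrow(image), ncol(image))
  }
  H <- nrow(image); W <- ncol(image)
  offsets <- list(c(0L, scale), c(-scale, scale), c(-scale, 0L),
                  c(-scale, -scale))
  counts <- matrix(0, levels, levels)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r0 <- max(1L, 1L - dr); r1 <- min(H, H - dr)
    c0 <- max(1L, 1L - dc); c1 <- min(W, W - dc)
    if (r0 > r1 || c0 > c1) next
    a_ok <- m[r0:r1, c0:c1]
    b_ok <- m[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc)]
    both <- a_ok & b_ok
    if (!any(both)) next
    ga <- g[r0:r1, c0:c1][both]
    gb <- g[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc)][both]
    # symmetric accumulation
    tab <- table(factor(ga, levels = 1:levels), factor(gb, levels = 1:levels))
    counts <- counts + tab + t(tab)
  }
  total <- sum(counts)
  if (total == 0) stop_bad_arg("mask admits no pixel pairs at offset ", scale)
  p <- counts / total
  # distribution of gray-level sums s = i + j, s in 2..2L
  s_vals <- 2:(2 * levels)
  p_sum <- vapply(s_vals, function(s) {
    i <- pmax(1L, s - levels):pmin(levels, s - 1L)
    sum(p[cbind(i, s - i)])
  }, numeric(1))
  sum_avg <- sum(s_vals * p_sum)
  sum((s_vals - sum_avg)^2 * p_sum)
}

#' Compute the minimal morphometric feature table
#'
#' Area (pixels), skeleton endpoint count, and co-occurrence sum variance at
#' scale 5 for every cell.
#'
#' @param cells A tibble with list-columns `image` and `mask` and a
#'   `cell_id` column.
#' @param scale,levels Passed to [texture_sum_variance()].
#' @return A tibble (`cell_id`, `area_px`, `skeleton_endpoints`,
#'   `texture_sum_variance_5`).
#' @export
cell_features <- function(cells, scale = 5L, levels = 8L) {
  tibble(
    cell_id = cells$cell_id,
    area_px = purrr::map_int(cells$mask, cell_area),
    skeleton_endpoints = purrr::map_int(cells$mask, skeleton_endpoints),
    texture_sum_variance_5 = purrr::map2_dbl(
      cells$image, cells$mask,
      function(im, mk) texture_sum_variance(im, mk, scale, levels))
  )
}

#' Jensen-Shannon divergence and distance
#'
#' `JSD^2 = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, natural
#' logarithm and the convention `0 log 0 = 0`.  The divergence is 0 for
#' identical distributions and `ln 2` for distributions with disjoint
#' support; the distance is its square root.
#'
#' @param p,q Probability vectors of equal length (each summing to 1).
#' @return Named numeric vector: `divergence`, `distance`.
#' @examples
#' jensen_shannon(c(1, 0), c(0, 1))["divergence"] # ln(2)
#' @export
jensen_shannon <- function(p, q) {
  if (length(p) != length(q)) stop_bad_arg("`p` and `q` must have equal length")
  if (any(p < 0) || any(q < 0)) stop_bad_arg("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop_bad_arg("`p` and `q` must each sum to 1")
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  div <- kl(p, m) / 2 + kl(q, m) / 2
  div <- max(0, min(div, log(2)))
  c(divergence = div, distance = sqrt(div))
}

#' Population fraction of each cluster per condition
#'
#' For every condition, the fraction of its cells falling in each cluster,
#' plus a per-cluster fold ratio max/min across conditions.  A half-cell
#' pseudo-fraction (0.5 divided by the smallest condition size) is added to
#' both numerator and denominator of the fold ratio so that empty clusters
#' yield finite folds.
#'
#' @param labels Cluster labels (one per cell).
#' @param conditions Condition labels aligned with `labels`.
#' @return An object of class `slc_enrichment`: tibble `table` (`cluster`,
#'   `condition`, `n`, `fraction`) and tibble `folds` (`cluster`, `fold`,
#'   `direction`).  [tidy()] returns the long table.
#' @export
cluster_fractions <- function(labels, conditions) {
  if (length(labels) != length(conditions)) {
    stop_bad_arg("`labels` and `conditions` must be aligned")
  }
  tab <- dplyr::count(tibble(cluster = labels, condition = conditions),
                      .data$cluster, .data$condition)
  tab <- tidyr::complete(tab, .data$cluster, .data$condition,
                         fill = list(n = 0L))
  totals <- dplyr::summarise(dplyr::group_by(tab, .data$condition),
                             total = sum(.data$n))
  if (any(totals$total == 0)) stop_bad_arg("a condition has zero cells")
  tab <- dplyr::mutate(dplyr::group_by(tab, .data$condition),
                       fraction = .data$n / sum(.data$n))
  tab <- dplyr::ungroup(tab)
  pseudo <- 0.5 / min(totals$total)
  folds <- dplyr::summarise(
    dplyr::group_by(tab, .data$cluster),
    fold = (max(.data$fraction) + pseudo) / (min(.data$fraction) + pseudo),
    direction = .data$condition[which.max(.data$fraction)]
  )
  structure(list(table = tab, folds = dplyr::ungroup(folds)),
            class = "slc_enrichment")
}

#' @export
print.slc_enrichment <- function(x, ...) {
  cat("<slc_enrichment> ", dplyr::n_distinct(x$table$cluster), " clusters x ",
      dplyr::n_distinct(x$table$condition), " conditions\n", sep = "")
  print(x$folds, n = 5)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slc_enrichment <- function(x, ...) {
  dplyr::left_join(x$table, x$folds, by = "cluster")
}

#' Flag clusters enriched or depleted between conditions
#'
#' A cluster is flagged when its max/min fraction ratio across conditions
#' reaches `fold_threshold` (default 2).
#'
#' @param table An [cluster_fractions()] result.
#' @param fold_threshold Minimal fold ratio (> 1).
#' @return A tibble (`cluster`, `fold`, `direction`, `flagged`).
#' @export
enrichment_flags <- function(table, fold_threshold = 2) {
  if (!inherits(table, "slc_enrichment")) {
    stop_bad_arg("`table` must come from cluster_fractions()")
  }
  if (fold_threshold <= 1) stop_bad_arg("`fold_threshold` must exceed 1")
  dplyr::mutate(table$folds, flagged = .data$fold >= fold_threshold)
}

#' Rank features by Jensen-Shannon distance between two clusters
#'
#' Each feature is histogrammed for the two clusters on their shared range
#' (`bins` equal-width bins with a small pseudo-count), and features are
#' ranked by the Jensen-Shannon distance between the two histograms.  The
#' Spearman rank correlation of every feature with the top-ranked feature
#' (over the cells of both clusters) supports choosing a complementary
#' second feature.  A feature constant across all cells gets distance 0.
#'
#' @param features A [cell_features()] tibble (any numeric columns beyond
#'   `cell_id` are treated as features).
#' @param labels Cluster labels aligned with `features` rows.
#' @param cluster_a,cluster_b The two clusters to contrast (>= 5 cells each).
#' @param bins Number of histogram bins.
#' @param pseudo Pseudo-count added to each bin before normalization.
#' @return An object of class `slc_feature_ranking`: a tibble (`feature`,
#'   `jsd`, `spearman_vs_top`, `rank`) sorted by rank.
#' @export
rank_features_by_jsd <- function(features, labels, cluster_a, cluster_b,
                                 bins = 20L, pseudo = 1e-6) {
  bins <- check_positive_int(bins, "bins")
  in_a <- labels == cluster_a
  in_b <- labels == cluster_b
  if (sum(in_a) < 5 || sum(in_b) < 5) {
    stop_bad_arg("both clusters need at least 5 cells")
  }
  feat_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                       "cell_id")
  if (length(feat_cols) == 0) stop_bad_arg("no numeric feature columns")

  jsd_one <- function(x) {
    xa <- x[in_a]; xb <- x[in_b]
    rng <- range(c(xa, xb))
    if (rng[1] == rng[2]) return(0)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
    bin <- function(v) {
      idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
      tabulate(idx, nbins = bins)
    }
    ha <- bin(xa) + pseudo
    hb <- bin(xb) + pseudo
    unname(jensen_shannon(ha / sum(ha), hb / sum(hb))["distance"])
  }
  jsd <- vapply(features[feat_cols], jsd_one, numeric(1))
  top <- feat_cols[which.max(jsd)]
  both <- in_a | in_b
  rho <- vapply(feat_cols, function(f) {
    suppressWarnings(cor(features[[f]][both], features[[top]][both],
                         method = "spearman"))
  }, numeric(1))
  out <- tibble(
    feature = feat_cols,
    jsd = unname(jsd),
    spearman_vs_top = unname(rho),
    rank = rank(-jsd, ties.method = "first")
  )
  out <- dplyr::arrange(out, .data$rank)
  class(out) <- c("slc_feature_ranking", class(out))
  out
}

#' Select a 2-D projection pair: top JSD plus a weakly correlated runner-up
#'
#' The first feature is the JSD rank-1 feature; the second is the
#' highest-JSD feature whose absolute Spearman correlation with the first is
#' at most `rho_max`.  If no feature qualifies, the least-correlated of the
#' top five JSD features is used with a warning.
#'
#' @param ranking An [rank_features_by_jsd()] result.
#' @param rho_max Maximal allowed |Spearman| with the top feature.
#' @return Character vector `c(feature_top, feature_second)`.
#' @export
select_projection_pair <- function(ranking, rho_max = 0.5) {
  if (nrow(ranking) < 2) stop_bad_arg("need at least 2 features")
  ord <- dplyr::arrange(ranking, .data$rank)
  top <- ord$feature[1]
  rest <- ord[-1, ]
  ok <- abs(rest$spearman_vs_top) <= rho_max
  if (any(ok)) {
    second <- rest$feature[which(ok)[1]]   # rest is sorted by JSD rank
  } else {
    warn("all features correlate with the top feature above `rho_max`; using the least correlated of the top 5")
    pool <- head(rest, 4)
    second <- pool$feature[which.min(abs(pool$spearman_vs_top))]
  }
  c(top, second)
}
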