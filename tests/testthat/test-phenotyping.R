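test_that("cell area counts foreground pixels", {
  expect_equal(cell_area(matrix(TRUE, 5, 5)), 25L)
  expect_warning(a0 <- cell_area(matrix(FALSE, 3, 3)))
  expect_equal(a0, 0L)

  # discrete disk of radius 10: lattice points with r^2 <= 100
  cc <- 15
  d2 <- outer(seq_len(29) - cc, seq_len(29) - cc, function(r, c) r^2 + c^2)
  expect_equal(cell_area(d2 <= 100), 317L)
})

test_that("skeleton endpoints match hand-checkable geometries", {
  line <- matrix(FALSE, 20, 20)
  line[10, 5:14] <- TRUE
  expect_equal(skeleton_endpoints(line), 2L)

  plus <- matrix(FALSE, 21, 21)
  plus[11, 4:18] <- TRUE
  plus[4:18, 11] <- TRUE
  expect_equal(skeleton_endpoints(plus), 4L)

  cc <- 15
  d2 <- outer(seq_len(29) - cc, seq_len(29) - cc, function(r, c) r^2 + c^2)
  expect_lte(skeleton_endpoints(d2 <= 100), 2L)

  expect_equal(skeleton_endpoints(matrix(FALSE, 4, 4)), 0L)

  two <- matrix(FALSE, 20, 20)
  two[3:6, 3:6] <- TRUE
  two[14:17, 14:17] <- TRUE
  expect_warning(skeleton_endpoints(two), "multiple components")
})

test_that("texture sum variance equals the brute-force pair enumeration", {
  expect_equal(texture_sum_variance(matrix(0.5, 10, 10), matrix(TRUE, 10, 10)), 0)

  # stripes of period 2*scale alternate extremes at the offset
  stripe <- matrix(rep(c(0, 1), each = 2, length.out = 8), 8, 8)
  m8 <- matrix(TRUE, 8, 8)
  expect_equal(texture_sum_variance(stripe, m8, scale = 2, levels = 2),
               brute_force_sum_variance(stripe, m8, scale = 2, levels = 2))

  for (s in 1:5) {
    withr::with_seed(s, {
      img <- matrix(runif(100), 10, 10)
      mask <- matrix(runif(100) > 0.25, 10, 10)
    })
    if (sum(mask) < 10) next
    expect_equal(texture_sum_variance(img, mask, scale = 3, levels = 8),
                 brute_force_sum_variance(img, mask, scale = 3, levels = 8),
                 tolerance = 1e-12)
  }

  # doubling the contrast of a two-level image leaves the quantization and
  # hence the statistic unchanged
  a <- matrix(rep(c(0.2, 0.4), 8), 4, 4)
  b <- matrix(rep(c(0.2, 0.6), 8), 4, 4)
  m4 <- matrix(TRUE, 4, 4)
  expect_equal(texture_sum_variance(a, m4, scale = 1, levels = 2),
               texture_sum_variance(b, m4, scale = 1, levels = 2))

  expect_error(texture_sum_variance(a, matrix(FALSE, 4, 4)),
               class = "cellslc_argument_error")
  one <- matrix(FALSE, 4, 4); one[2, 2] <- TRUE
  expect_error(texture_sum_variance(a, one, scale = 1),
               class = "cellslc_argument_error")
})

test_that("Jensen-Shannon divergence matches closed forms and is symmetric", {
  expect_equal(unname(jensen_shannon(c(0.3, 0.7), c(0.3, 0.7))),
               c(0, 0))
  expect_equal(jensen_shannon(c(1, 0), c(0, 1))[["divergence"]], log(2))
  expect_equal(jensen_shannon(c(1, 0), c(0, 1))[["distance"]], sqrt(log(2)))

  # closed form for p = (1, 0), q = (1/2, 1/2):
  # KL(p||m) = ln(4/3), KL(q||m) = (ln(2/3) + ln 2)/2, averaged
  expected <- (log(4 / 3) + (log(2 / 3) + log(2)) / 2) / 2
  expect_equal(jensen_shannon(c(1, 0), c(0.5, 0.5))[["divergence"]], expected)

  # symmetry and bounds on random distributions
  for (s in 1:5) {
    withr::with_seed(s, {
      p <- runif(6); p <- p / sum(p)
      q <- runif(6); q <- q / sum(q)
    })
    d1 <- jensen_shannon(p, q)
    d2 <- jensen_shannon(q, p)
    expect_equal(d1, d2)
    expect_gte(d1[["divergence"]], 0)
    expect_lte(d1[["divergence"]], log(2))
  }

  expect_error(jensen_shannon(c(1, 0), c(0.5, 0.25, 0.25)),
               class = "cellslc_argument_error")
  expect_error(jensen_shannon(c(0.5, 0.5), c(0.7, 0.4)),
               class = "cellslc_argument_error")
})

test_that("cluster fractions and fold ratios follow the counting rules", {
  en <- cluster_fractions(c(1, 1, 2, 2), c("A", "A", "B", "B"))
  tab <- en$table
  expect_equal(tab$fraction[tab$condition == "A" & tab$cluster == 1], 1)
  expect_equal(tab$fraction[tab$condition == "A" & tab$cluster == 2], 0)
  expect_equal(tab$fraction[tab$condition == "B" & tab$cluster == 2], 1)

  en2 <- cluster_fractions(c(1, 1, 1, 2), c("A", "A", "B", "B"))
  t2 <- en2$table
  expect_equal(t2$fraction[t2$condition == "A" & t2$cluster == 1], 1)
  expect_equal(t2$fraction[t2$condition == "B" & t2$cluster == 1], 0.5)
  expect_equal(t2$fraction[t2$condition == "B" & t2$cluster == 2], 0.5)

  single <- cluster_fractions(c(1, 2, 1), c("A", "A", "A"))
  expect_true(all(single$folds$fold == 1))

  expect_error(cluster_fractions(1:3, c("A", "A")),
               class = "cellslc_argument_error")
})

test_that("enrichment flags fire at the observed cross-density fold ratios", {
  # fractions 16.25% vs 4.56% (fold ~ 3.56) and 13.44% vs 5.36% (~ 2.51)
  mk <- function(frac_high, frac_low, n = 10000) {
    labels <- c(rep(1, round(frac_high * n)), rep(2, n - round(frac_high * n)),
                rep(1, round(frac_low * n)), rep(2, n - round(frac_low * n)))
    conds <- rep(c("high", "low"), each = n)
    cluster_fractions(labels, conds)
  }
  f1 <- enrichment_flags(mk(0.1625, 0.0456))
  expect_true(f1$flagged[f1$cluster == 1])
  expect_equal(f1$fold[f1$cluster == 1], 3.56, tolerance = 0.01)
  expect_equal(f1$direction[f1$cluster == 1], "high")

  f2 <- enrichment_flags(mk(0.0536, 0.1344))
  expect_true(f2$flagged[f2$cluster == 1])
  expect_equal(f2$fold[f2$cluster == 1], 2.51, tolerance = 0.01)
  expect_equal(f2$direction[f2$cluster == 1], "low")

  even <- cluster_fractions(rep(c(1, 2), 10), rep(c("A", "B"), each = 10))
  expect_false(any(enrichment_flags(even)$flagged))

  expect_error(enrichment_flags(mk(0.2, 0.2), fold_threshold = 1),
               class = "cellslc_argument_error")
})

test_that("JSD feature ranking orders separating features first", {
  withr::with_seed(9, {
    n <- 40
    labels <- rep(c(1, 2), each = n)
    sep <- c(rnorm(n, 0), rnorm(n, 6))          # separates the clusters
    echo <- sep + rnorm(2 * n, 0, 0.05)          # near-duplicate of sep
    flat <- rep(0.7, 2 * n)                      # identical in both clusters
    indep <- c(rnorm(n, 0), rnorm(n, 2))         # informative, less separating
    feats <- tibble::tibble(cell_id = as.character(1:(2 * n)),
                            sep = sep, echo = echo, flat = flat, indep = indep)
  })
  rk <- rank_features_by_jsd(feats, labels, 1, 2)
  expect_equal(rk$feature[rk$rank == 1], "sep")
  expect_equal(rk$jsd[rk$feature == "flat"], 0)
  expect_equal(rk$rank[rk$feature == "flat"], 4)
  # disjoint ranges approach the maximal distance sqrt(ln 2)
  expect_gt(rk$jsd[rk$feature == "sep"], sqrt(log(2)) - 0.05)
  expect_gt(rk$spearman_vs_top[rk$feature == "echo"], 0.95)

  expect_error(rank_features_by_jsd(feats, labels, 1, 3),
               class = "cellslc_argument_error")
})

test_that("projection-pair selection prefers high JSD with low correlation", {
  ranking <- tibble::tibble(
    feature = c("f1", "f2", "f3"),
    jsd = c(0.8, 0.7, 0.5),
    spearman_vs_top = c(1, 0.9, 0.1),
    rank = 1:3
  )
  class(ranking) <- c("slc_feature_ranking", class(ranking))
  expect_equal(select_projection_pair(ranking), c("f1", "f3"))

  allcor <- ranking
  allcor$spearman_vs_top <- c(1, 0.9, 0.8)
  expect_warning(pair <- select_projection_pair(allcor), "least correlated")
  expect_equal(pair, c("f1", "f3"))

  expect_error(select_projection_pair(ranking[1, ]),
               class = "cellslc_argument_error")

  # two independent informative features: top two by JSD
  ind <- ranking
  ind$spearman_vs_top <- c(1, 0.2, 0.1)
  expect_equal(select_projection_pair(ind), c("f1", "f2"))
})
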