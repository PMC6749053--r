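# Fixtures are generated in code and memoized for the session, so expensive
# objects (rendered cells, trained networks) are built once and shared.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# Two types x three modes, the default well-separated library.
fx_library <- function() {
  fixture("library", make_phenotype_library(2, 3, seed = 11))
}

# Quick 64-pixel toy images: one Gaussian blob (class A) vs two smaller
# blobs (class B); trivially separable, cheap to train on.
toy_image <- function(kind, side = 64) {
  bg <- matrix(rnorm(side^2, 0.4, 0.05), side)
  ctr <- side / 2 + runif(2, -6, 6)
  r <- rep(seq_len(side), times = side)
  c <- rep(seq_len(side), each = side)
  if (kind == 1) {
    d2 <- (r - ctr[1])^2 + (c - ctr[2])^2
    bg <- bg + matrix(0.3 * exp(-d2 / 120), side)
  } else {
    ang <- runif(1, 0, pi)
    off <- 10 * c(cos(ang), sin(ang))
    d2a <- (r - ctr[1] - off[1])^2 + (c - ctr[2] - off[2])^2
    d2b <- (r - ctr[1] + off[1])^2 + (c - ctr[2] + off[2])^2
    bg <- bg + matrix(0.3 * exp(-d2a / 40) + 0.3 * exp(-d2b / 40), side)
  }
  pmax(pmin(bg, 1), 0)
}

toy_cells <- function(n_per_class, side = 64, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      cell_type = rep(c("A", "B"), each = n_per_class),
      image = c(lapply(seq_len(n_per_class), function(i) toy_image(1, side)),
                lapply(seq_len(n_per_class), function(i) toy_image(2, side)))
    )
  })
}

# A trained 64-pixel toy classifier shared by unit tests.
fx_toy_model_set <- function() {
  fixture("toy_model_set", {
    train_classifier(
      toy_cells(20),
      config = training_config(learning_rate = 0.01, n_repeats = 1,
                               max_epochs = 12, seed = 3)
    )
  })
}

# An untrained model wrapper around freshly initialized parameters.
untrained_model <- function(n_classes, side = 224, seed = 1) {
  spec <- build_network_spec(n_classes, input_side = side)
  structure(
    list(spec = spec,
         params = cellslc:::init_network_params(spec, seed = seed),
         run_stats = cellslc:::init_run_stats(spec),
         history = tibble::tibble(), input_side = side,
         classes = as.character(seq_len(n_classes))),
    class = "slc_model"
  )
}

# The SLC acceptance fixture: one cell type, three planted phenotype modes,
# two density conditions whose mode mixing differs strongly for modes 1 and
# 3; 30 cells, m = 15 augmentations.  Model trained to the validation
# target; shared between the self-label recovery and enrichment tests.
fx_slc <- function() {
  fixture("slc", {
    lib <- make_phenotype_library(1, 3, seed = 11)
    low <- generate_flask(
      flask_design("Dlow", 1, "low", 15, c(0.6, 0.3, 0.1),
                   batch_shift = list(), seed = 2), lib)
    high <- generate_flask(
      flask_design("Dhigh", 1, "high", 15, c(0.1, 0.3, 0.6),
                   batch_shift = list(), seed = 3), lib)
    cells <- dplyr::bind_rows(low, high)
    policy <- augmentation_policy(m = 15)
    ds <- build_self_label_dataset(cells, policy, seed = 4)
    cfg <- training_config(learning_rate = 0.05, max_epochs = 8,
                           target_val_accuracy = 0.96, seed = 5)
    model <- train_self_label(ds, cfg)
    lca <- lca_matrix(model, ds$originals)
    list(library = lib, cells = cells, dataset = ds, model = model, lca = lca)
  })
}

# Brute-force k-means oracle: minimal within-cluster squared distance over
# every partition of the rows into k non-empty clusters (small n only).
brute_force_kmeans <- function(X, k) {
  n <- nrow(X)
  assignments <- expand.grid(rep(list(seq_len(k)), n))
  best <- NULL
  for (i in seq_len(nrow(assignments))) {
    lab <- as.integer(assignments[i, ])
    if (length(unique(lab)) != k) next
    ss <- 0
    for (g in unique(lab)) {
      rows <- X[lab == g, , drop = FALSE]
      ctr <- colMeans(rows)
      ss <- ss + sum(sweep(rows, 2, ctr)^2)
    }
    if (is.null(best) || ss < best$ss - 1e-12) best <- list(ss = ss, labels = lab)
  }
  best
}

# Brute-force GLCM sum-variance oracle by direct pair enumeration.
brute_force_sum_variance <- function(image, mask, scale = 5, levels = 8) {
  vals <- image[mask > 0]
  rng <- range(vals)
  quant <- function(v) {
    if (rng[1] == rng[2]) return(1L)
    min(levels, 1L + floor((v - rng[1]) / (rng[2] - rng[1]) * levels))
  }
  H <- nrow(image); W <- ncol(image)
  sums <- c()
  offs <- list(c(0, scale), c(-scale, scale), c(-scale, 0), c(-scale, -scale))
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (!mask[r, cc]) next
    for (off in offs) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      if (!mask[r2, c2]) next
      sums <- c(sums, quant(image[r, cc]) + quant(image[r2, c2]))
    }
  }
  if (length(sums) == 0) stop("no pairs")
  # each unordered pair counted twice by symmetry; here each ordered pair
  # once per direction set, matching the symmetric accumulation up to the
  # total count, which cancels in the normalized distribution
  sa <- mean(sums)
  mean((sums - sa)^2)
}
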