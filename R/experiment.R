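#' Enumerate training-pool / validation flask-pair splits
#'
#' With `n_pairs` flask pairs and a training pool of `pool_size` pairs,
#' every combination of pool and single held-out validation pair is listed:
#' `choose(n_pairs, pool_size) * (n_pairs - pool_size)` splits.  For 4 flask
#' pairs this yields 12, 12 and 4 validation datasets at pool sizes 1, 2
#' and 3.
#'
#' @param n_pairs Number of flask pairs in the roster.
#' @param pool_size Number of pairs pooled for training
#'   (`1 <= pool_size < n_pairs`).
#' @return A tibble (`split`, `train_pool` list-column, `validation_pair`)
#'   in deterministic order.
#' @examples
#' nrow(enumerate_flask_splits(4, 2)) # 12
#' @export
enumerate_flask_splits <- function(n_pairs, pool_size) {
  n_pairs <- check_positive_int(n_pairs, "n_pairs")
  pool_size <- check_positive_int(pool_size, "pool_size")
  if (pool_size >= n_pairs) {
    stop_bad_arg("`pool_size` must be smaller than `n_pairs`")
  }
  pools <- combn(n_pairs, pool_size, simplify = FALSE)
  rows <- purrr::map(pools, function(pool) {
    held <- setdiff(seq_len(n_pairs), pool)
    tibble(train_pool = rep(list(pool), length(held)),
           validation_pair = held)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, split = dplyr::row_number(), .before = 1)
}

#' Experiment configuration
#'
#' Bundles the design name and the synthetic-cohort, training and analysis
#' parameters of [run_experiment()].  Defaults are desk-scale: small flasks,
#' few epochs, a learning rate suited to short schedules.
#'
#' @param design One of `"within_flask"`, `"cross_flask"`, `"pooled"`,
#'   `"density"`, `"mixed"`, `"slc"`.
#' @param ... Overrides of the defaults (see Details in the package
#'   vignette); unknown names are an error.
#' @param out_dir Optional directory for result CSVs.
#' @param seed Master seed.
#' @return A list of class `slc_experiment_config`.
#' @export
experiment_config <- function(design = c("within_flask", "cross_flask",
                                         "pooled", "density", "mixed", "slc"),
                              ..., out_dir = NULL, seed = 1L) {
  design <- match.arg(design)
  defaults <- list(
    n_pairs = 4L,                 # flask pairs in the roster
    pool_size = 3L,               # training pool size for design "pooled"
    cells_per_flask = 30L,
    modes_per_type = 2L,
    mode_spread = 1,
    library_seed = 11L,
    mixing_by_condition = list(low = NULL, high = NULL),  # NULL = defaults below
    condition_cycle = c("low", "high"),
    training = list(),
    # mixed-population design
    n_frames = 4L,
    n_per_type = c(5L, 5L),
    # SLC design
    slc_n_cells = 24L,
    slc_m = 12L,
    slc_modes = 3L,               # planted phenotype modes
    slc_mixing = list(low = c(0.6, 0.3, 0.1), high = c(0.15, 0.3, 0.55)),
    k_min = 2L,
    k_max = 8L,
    fold_threshold = 2
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) stop_bad_arg("unknown config fields: ",
                                    paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, dots)
  cfg$design <- design
  cfg$out_dir <- out_dir
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "slc_experiment_config")
}

# default condition-dependent mode mixing for two modes per type
default_mixing <- function(cfg, condition) {
  mx <- cfg$mixing_by_condition[[condition]]
  if (!is.null(mx)) return(mx)
  m <- cfg$modes_per_type
  if (m == 1) return(1)
  w <- if (condition == "low") seq(m, 1) else seq(1, m)
  w / sum(w)
}

merged_training_config <- function(cfg) {
  base <- list(learning_rate = 0.02, max_epochs = 10L, n_repeats = 1L,
               target_val_accuracy = 0.97, seed = cfg$seed)
  do.call(training_config, utils::modifyList(base, cfg$training))
}

# Build the flask-pair roster: pair p holds one flask of each of two types,
# condition cycling through cfg$condition_cycle, flask-level batch shifts
# drawn per flask.  All images are quantile-normalized to the first cell.
build_roster <- function(cfg, library, opts = render_options()) {
  pairs <- purrr::map(seq_len(cfg$n_pairs), function(p) {
    condition <- cfg$condition_cycle[(p - 1L) %% length(cfg$condition_cycle) + 1L]
    cells <- purrr::map(1:2, function(ty) {
      design <- flask_design(
        flask_id = sprintf("P%dT%d", p, ty), cell_type = ty,
        condition = condition, n_cells = cfg$cells_per_flask,
        mode_mixing = default_mixing(cfg, condition),
        seed = cfg$seed + 101L * p + ty
      )
      generate_flask(design, library, opts)
    })
    dplyr::mutate(dplyr::bind_rows(cells), pair = p)
  })
  roster <- dplyr::bind_rows(pairs)
  ref <- reference_distribution(roster$image[[1]])
  roster$image <- purrr::map(roster$image, quantile_normalize, ref = ref)
  list(roster = roster, ref = ref)
}

# Fit on one cell set, validate on another (no internal split).
fit_on <- function(train_cells, val_cells, tcfg, label_col = "cell_type") {
  all_cells <- dplyr::bind_rows(train_cells, val_cells)
  labels_f <- factor(all_cells[[label_col]])
  side <- nrow(all_cells$image[[1]])
  images <- images_to_matrix(all_cells$image, side)
  spec <- build_network_spec(nlevels(labels_f), input_side = side)
  train_idx <- seq_len(nrow(train_cells))
  val_idx <- nrow(train_cells) + seq_len(nrow(val_cells))
  model <- withr::with_seed(tcfg$seed, {
    fit_network(images, as.integer(labels_f), spec, tcfg, train_idx, val_idx)
  })
  model$classes <- levels(labels_f)
  last <- model$history[nrow(model$history), ]
  ci <- error_confidence_interval(1 - last$val_accuracy, length(val_idx))
  list(model = model,
       accuracy = last$val_accuracy, train_accuracy = last$train_accuracy,
       n_val = length(val_idx), ci = ci)
}

acc_row <- function(fit, ...) {
  tibble(..., accuracy = fit$accuracy, train_accuracy = fit$train_accuracy,
         n_val = fit$n_val, error_ci_lo = fit$ci[["lo"]],
         error_ci_hi = fit$ci[["hi"]])
}

#' Run a full synthetic experiment
#'
#' Executes one of the experiment designs end to end on synthetic data:
#' generation, preprocessing, training or clustering, and a report.
#'
#' * `within_flask` - train/validate inside each flask pair (random 80/20).
#' * `cross_flask` - train on one pair, validate on every other pair.
#' * `pooled` - train on pools of `pool_size` pairs, validate per held-out
#'   pair (all [enumerate_flask_splits()] combinations).
#' * `density` - flask pairs at two controlled densities; reports
#'   within-condition, cross-condition and pooled-training accuracies.
#' * `mixed` - train pooled over the roster, score mixed-population frames
#'   cell by cell against the synthetic ground truth.
#' * `slc` - self-label clustering of one cell type across two densities:
#'   LCA extraction, k scan, clustering, cross-density enrichment.
#'
#' @param config An [experiment_config()].
#' @param verbose Print training progress.
#' @return An object of class `slc_experiment_report` with `design`,
#'   `results` (tibble), `summary` (tibble of aggregate means), optional
#'   design-specific components, and `provenance`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  if (!inherits(config, "slc_experiment_config")) {
    stop_bad_arg("`config` must be an experiment_config()")
  }
  tcfg <- merged_training_config(config)
  out <- switch(config$design,
    within_flask = run_within_flask(config, tcfg, verbose),
    cross_flask = run_cross_flask(config, tcfg),
    pooled = run_pooled(config, tcfg),
    density = run_density(config, tcfg),
    mixed = run_mixed(config, tcfg),
    slc = run_slc(config, tcfg)
  )
  out$provenance <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cellslc")),
    r_version = R.version.string
  )
  class(out) <- "slc_experiment_report"
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

run_within_flask <- function(cfg, tcfg, verbose) {
  library <- make_phenotype_library(2, cfg$modes_per_type, cfg$library_seed,
                                    cfg$mode_spread)
  ros <- build_roster(cfg, library)
  results <- dplyr::bind_rows(purrr::map(seq_len(cfg$n_pairs), function(p) {
    cells <- ros$roster[ros$roster$pair == p, ]
    fit <- train_classifier(cells, config = tcfg, verbose = verbose)
    tibble(pair = p,
           accuracy = mean(fit$summary$val_accuracy),
           train_accuracy = mean(fit$summary$train_accuracy),
           n_val = fit$summary$val_n[1],
           error_ci_lo = mean(fit$summary$error_ci_lo),
           error_ci_hi = mean(fit$summary$error_ci_hi))
  }))
  list(design = "within_flask", results = results,
       summary = tibble(metric = "mean_within_flask_accuracy",
                        value = mean(results$accuracy)))
}

run_cross_flask <- function(cfg, tcfg) {
  library <- make_phenotype_library(2, cfg$modes_per_type, cfg$library_seed,
                                    cfg$mode_spread)
  ros <- build_roster(cfg, library)
  grid <- expand.grid(train = seq_len(cfg$n_pairs),
                      validate = seq_len(cfg$n_pairs))
  grid <- grid[grid$train != grid$validate, ]
  results <- dplyr::bind_rows(purrr::pmap(grid, function(train, validate) {
    fit <- fit_on(ros$roster[ros$roster$pair == train, ],
                  ros$roster[ros$roster$pair == validate, ], tcfg)
    acc_row(fit, train_pair = train, validation_pair = validate)
  }))
  list(design = "cross_flask", results = results,
       summary = tibble(metric = "mean_cross_flask_accuracy",
                        value = mean(results$accuracy)))
}

run_pooled <- function(cfg, tcfg) {
  library <- make_phenotype_library(2, cfg$modes_per_type, cfg$library_seed,
                                    cfg$mode_spread)
  ros <- build_roster(cfg, library)
  splits <- enumerate_flask_splits(cfg$n_pairs, cfg$pool_size)
  results <- dplyr::bind_rows(purrr::map(seq_len(nrow(splits)), function(i) {
    pool <- splits$train_pool[[i]]
    held <- splits$validation_pair[i]
    fit <- fit_on(ros$roster[ros$roster$pair %in% pool, ],
                  ros$roster[ros$roster$pair == held, ], tcfg)
    acc_row(fit, split = splits$split[i],
            train_pool = paste(pool, collapse = "+"), validation_pair = held)
  }))
  list(design = "pooled", results = results,
       summary = tibble(metric = "mean_pooled_accuracy",
                        value = mean(results$accuracy)))
}

run_density <- function(cfg, tcfg) {
  library <- make_phenotype_library(2, cfg$modes_per_type, cfg$library_seed,
                                    cfg$mode_spread)
  # two flask pairs per condition
  cfg2 <- cfg
  cfg2$n_pairs <- 4L
  cfg2$condition_cycle <- c("low", "low", "high", "high")
  ros <- build_roster(cfg2, library)
  pair_cells <- function(p) ros$roster[ros$roster$pair == p, ]
  comparisons <- list(
    list(kind = "within", train = 1L, validate = 2L),
    list(kind = "within", train = 3L, validate = 4L),
    list(kind = "cross", train = 1L, validate = 4L),
    list(kind = "cross", train = 3L, validate = 2L),
    list(kind = "pooled", train = c(1L, 3L), validate = 2L),
    list(kind = "pooled", train = c(1L, 3L), validate = 4L)
  )
  results <- dplyr::bind_rows(purrr::map(comparisons, function(cmp) {
    fit <- fit_on(dplyr::bind_rows(purrr::map(cmp$train, pair_cells)),
                  pair_cells(cmp$validate), tcfg)
    acc_row(fit, kind = cmp$kind,
            train_pair = paste(cmp$train, collapse = "+"),
            validation_pair = cmp$validate)
  }))
  means <- dplyr::summarise(dplyr::group_by(results, .data$kind),
                            value = mean(.data$accuracy))
  list(design = "density", results = results,
       summary = tibble(metric = paste0("mean_", means$kind, "_condition_accuracy"),
                        value = means$value))
}

run_mixed <- function(cfg, tcfg) {
  library <- make_phenotype_library(2, cfg$modes_per_type, cfg$library_seed,
                                    cfg$mode_spread)
  ros <- build_roster(cfg, library)
  fit <- train_classifier(ros$roster, config = tcfg)
  model <- fit$models[[which.max(fit$summary$val_accuracy)]]
  model$reference <- ros$ref
  frames <- purrr::map(seq_len(cfg$n_frames), function(i) {
    npt <- if (i %% 3 == 0) rev(cfg$n_per_type) else cfg$n_per_type
    render_mixed_frame(library, types = c(1, 2), n_per_type = npt,
                       seed = cfg$seed + 500L + i)
  })
  eval <- classify_mixed_frames(model, frames, ref = ros$ref)
  list(design = "mixed", results = eval$per_frame,
       summary = tibble(metric = c("overall_mixed_accuracy",
                                   "training_val_accuracy"),
                        value = c(eval$overall,
                                  mean(fit$summary$val_accuracy))),
       frames = frames, model_set = fit)
}

run_slc <- function(cfg, tcfg) {
  library <- make_phenotype_library(1, cfg$slc_modes, cfg$library_seed)
  n_half <- cfg$slc_n_cells %/% 2L
  flasks <- purrr::imap(cfg$slc_mixing, function(mix, cond) {
    design <- flask_design(paste0("D", cond), 1, cond, n_half, mix,
                           batch_shift = list(),
                           seed = cfg$seed + match(cond, names(cfg$slc_mixing)))
    generate_flask(design, library)
  })
  cells <- dplyr::bind_rows(flasks)
  policy <- augmentation_policy(m = cfg$slc_m)
  ds <- build_self_label_dataset(cells, policy, seed = cfg$seed)
  model <- train_self_label(ds, tcfg)
  lca <- lca_matrix(model, ds$originals)
  ks <- scan_k(lca, cfg$k_min, cfg$k_max, seed = cfg$seed)
  clustering <- ks$clusterings[[which(ks$scan$k == ks$selected_k)]]
  enrich <- cluster_fractions(clustering$labels, cells$condition)
  flags <- enrichment_flags(enrich, cfg$fold_threshold)
  list(design = "slc",
       results = dplyr::mutate(tidy(enrich), selected_k = ks$selected_k),
       summary = tibble(
         metric = c("selected_k", "self_label_val_accuracy", "max_fold"),
         value = c(ks$selected_k,
                   model$history$val_accuracy[nrow(model$history)],
                   max(flags$fold))),
       lca = lca, kscan = ks, clustering = clustering,
       enrichment = enrich, flags = flags, model = model, cells = cells)
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$results, file.path(dir, "results.csv"))
  readr::write_csv(report$summary, file.path(dir, "summary.csv"))
  if (report$design == "slc") {
    readr::write_csv(report$lca, file.path(dir, "lca.csv"))
    readr::write_csv(report$kscan$scan, file.path(dir, "kscan.csv"))
    readr::write_csv(tibble(cell_id = report$lca$cell_id,
                            condition = report$cells$condition,
                            cluster = report$clustering$labels),
                     file.path(dir, "labels.csv"))
    readr::write_csv(tidy(report$enrichment), file.path(dir, "enrichment.csv"))
  }
  writeLines(yaml::as.yaml(report$provenance[c("config_hash", "seed",
                                               "package_version", "r_version")]),
             file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' @export
print.slc_experiment_report <- function(x, ...) {
  cat("<slc_experiment_report> design:", x$design, "\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slc_experiment_report <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.slc_experiment_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric", values_from = "value")
}

#' @exportS3Method ggplot2::autoplot
autoplot.slc_enrichment <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = factor(.data$cluster), y = .data$fraction,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "cluster", y = "fraction of condition's cells",
                  title = "Cluster occupancy by condition") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.slc_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = c("split", "metric"),
                           names_sep = "_", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(title = "Training history", y = NULL) +
    ggplot2::theme_minimal()
}
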