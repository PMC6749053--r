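test_that("flask-split enumeration reproduces the pooling combinatorics", {
  expect_equal(nrow(enumerate_flask_splits(4, 1)), 12)
  expect_equal(nrow(enumerate_flask_splits(4, 2)), 12)
  expect_equal(nrow(enumerate_flask_splits(4, 3)), 4)
  expect_equal(nrow(enumerate_flask_splits(2, 1)), 2)

  # all (pool, validation) combinations, validation never inside the pool
  for (n in 2:6) {
    for (s in seq_len(n - 1)) {
      sp <- enumerate_flask_splits(n, s)
      expect_equal(nrow(sp), choose(n, s) * (n - s))
      expect_true(all(purrr::map2_lgl(sp$train_pool, sp$validation_pair,
                                      function(pool, v) !(v %in% pool))))
      keys <- purrr::map2_chr(sp$train_pool, sp$validation_pair,
                              function(pool, v) paste(c(pool, "|", v),
                                                      collapse = ","))
      expect_equal(anyDuplicated(keys), 0)
    }
  }

  expect_error(enumerate_flask_splits(4, 4), class = "cellslc_argument_error")
  expect_error(enumerate_flask_splits(3, 0), class = "cellslc_argument_error")
})

test_that("experiment configs validate their fields", {
  cfg <- experiment_config("slc", slc_n_cells = 10L, seed = 3)
  expect_s3_class(cfg, "slc_experiment_config")
  expect_equal(cfg$slc_n_cells, 10L)
  expect_error(experiment_config("slc", not_a_field = 1),
               class = "cellslc_argument_error")
  expect_error(experiment_config("made_up_design"))
})

test_that("the SLC experiment design runs end to end and emits artifacts", {
  out <- withr::local_tempdir()
  cfg <- experiment_config(
    "slc", slc_n_cells = 8L, slc_m = 4L, k_max = 5L,
    training = list(max_epochs = 2L, learning_rate = 0.05),
    out_dir = out, seed = 7
  )
  report <- run_experiment(cfg)
  expect_s3_class(report, "slc_experiment_report")
  expect_true(all(c("selected_k", "self_label_val_accuracy", "max_fold") %in%
                    report$summary$metric))
  for (f in c("lca.csv", "kscan.csv", "labels.csv", "enrichment.csv",
              "results.csv", "summary.csv", "provenance.yaml")) {
    expect_true(file.exists(file.path(out, f)), label = f)
  }
  lca_csv <- readr::read_csv(file.path(out, "lca.csv"), show_col_types = FALSE)
  expect_equal(nrow(lca_csv), 8)
  expect_equal(sum(grepl("^f[0-9]+$", names(lca_csv))), 288)
  expect_false(is.na(report$provenance$config_hash))
})

test_that("cross-flask and pooled designs enumerate and score all splits", {
  tcfg <- list(max_epochs = 1L, n_repeats = 1L, learning_rate = 0.02)
  cross <- run_experiment(experiment_config(
    "cross_flask", n_pairs = 2L, cells_per_flask = 4L,
    training = tcfg, seed = 13))
  expect_equal(nrow(cross$results), 2)   # 2 ordered (train, validate) pairs
  expect_true(all(cross$results$train_pair != cross$results$validation_pair))

  pooled <- run_experiment(experiment_config(
    "pooled", n_pairs = 3L, pool_size = 2L, cells_per_flask = 4L,
    training = tcfg, seed = 13))
  expect_equal(nrow(pooled$results), 3)  # choose(3,2) * 1 held-out each
  expect_true(all(pooled$results$accuracy >= 0 & pooled$results$accuracy <= 1))
  expect_true(all(c("error_ci_lo", "error_ci_hi") %in% names(pooled$results)))
})

test_that("rerunning an experiment with the same config reproduces it", {
  cfg <- experiment_config(
    "within_flask", n_pairs = 1L, cells_per_flask = 5L,
    training = list(max_epochs = 2L, n_repeats = 1L), seed = 11
  )
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_equal(r1$results, r2$results)
  expect_equal(r1$provenance$config_hash, r2$provenance$config_hash)
  expect_true(all(c("accuracy", "error_ci_lo", "error_ci_hi") %in%
                    names(r1$results)))
})
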