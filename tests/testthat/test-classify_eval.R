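# feature table with two Gaussian blobs, separation `gap` standard deviations
toy_features <- function(n_subj = 6, cycles = 40, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_subj), function(i) {
      lbl <- if (i <= n_subj / 2) "healthy" else "epilepsy"
      mu <- if (lbl == "healthy") 0 else gap
      data.frame(subject_id = sprintf("s%02d", i), label = lbl,
                 center_kind = "median", cycle = seq_len(cycles),
                 center = rnorm(cycles),
                 variance = rnorm(cycles, mu, 1),
                 skewness = rnorm(cycles, mu / 2, 1),
                 kurtosis = rnorm(cycles, 3, 1),
                 stringsAsFactors = FALSE)
    })
    structure(do.call(rbind, rows),
              class = c("cycle_features", "data.frame"))
  })
}

test_that("metrics follow their confusion-count definitions exactly", {
  m <- metrics_from_confusion(tp = 97, fn = 3, tn = 98, fp = 2)
  expect_equal(unname(m), c(0.975, 0.97, 0.98))
  expect_equal(unname(metrics_from_confusion(50, 0, 50, 0)), c(1, 1, 1))
  # degenerate classifier: everything predicted healthy on balanced data
  m2 <- metrics_from_confusion(tp = 0, fn = 50, tn = 50, fp = 0)
  expect_equal(unname(m2), c(0.5, 0, 1))
  # undefined metrics are NA, not zero
  m3 <- metrics_from_confusion(tp = 0, fn = 0, tn = 9, fp = 1)
  expect_true(is.na(m3["sensitivity"]))
  expect_equal(unname(m3["specificity"]), 0.9)
})

test_that("patient split is stratified, deterministic and a partition", {
  subj <- data.frame(
    subject_id = sprintf("h%02d", 1:18),
    label = "healthy",
    sex = c(rep("M", 5), rep("F", 13)))
  plan <- make_patient_split(rbind(
    subj,
    data.frame(subject_id = c("e1", "e2", "e3"), label = "epilepsy",
               sex = "F")), train_fraction = 0.7, seed = 3)
  healthy <- plan[plan$label == "healthy", ]
  # 5 males -> 3 train / 2 test; 13 females -> 9 train / 4 test
  expect_equal(sum(healthy$fold == "train" & healthy$subject_id %in%
                     sprintf("h%02d", 1:5)), 3)
  expect_equal(sum(healthy$fold == "test" & healthy$subject_id %in%
                     sprintf("h%02d", 1:5)), 2)
  expect_equal(sum(healthy$fold == "train"), 12)
  expect_equal(sum(healthy$fold == "test"), 6)
  # every subject assigned exactly once
  expect_setequal(plan$subject_id, c(sprintf("h%02d", 1:18), "e1", "e2", "e3"))
  expect_true(all(plan$fold %in% c("train", "test")))
  # determinism
  plan2 <- make_patient_split(rbind(
    subj,
    data.frame(subject_id = c("e1", "e2", "e3"), label = "epilepsy",
               sex = "F")), train_fraction = 0.7, seed = 3)
  expect_identical(plan, plan2)
  # a single-subject class cannot be held out
  expect_error(make_patient_split(data.frame(subject_id = c("a", "b"),
                                             label = c("healthy", "epilepsy"))),
               "at least 2")
})

test_that("grouped k-fold covers all subjects once with balanced folds", {
  subj <- data.frame(subject_id = sprintf("s%02d", 1:20),
                     label = rep(c("healthy", "epilepsy"), each = 10))
  plan <- grouped_kfold(subj, k = 10, seed = 5)
  expect_equal(as.integer(table(plan$fold)), rep(2L, 10))
  # each fold mixes the classes
  expect_true(all(tapply(plan$label, plan$fold,
                         function(l) length(unique(l))) == 2))
  expect_setequal(plan$subject_id, subj$subject_id)
  expect_identical(plan, grouped_kfold(subj, k = 10, seed = 5))

  small <- grouped_kfold(data.frame(subject_id = letters[1:4],
                                    label = rep(c("healthy", "epilepsy"), 2)),
                         k = 2, seed = 1)
  expect_equal(as.integer(table(small$fold)), c(2L, 2L))
  expect_error(grouped_kfold(subj, k = 1), "at least 2")
})

test_that("MLP fits a separable problem and is reproducible", {
  feats <- toy_features(gap = 10, seed = 2)
  model <- train_mlp(feats, cfg = mlp_config(seed = 4))
  pred <- predict(model, feats)
  expect_equal(mean(pred == feats$label), 1.0)
  model2 <- train_mlp(feats, cfg = mlp_config(seed = 4))
  expect_identical(predict(model2, feats, type = "prob"),
                   predict(model, feats, type = "prob"))
  # training loss decreases overall
  expect_lt(model$loss[length(model$loss)], model$loss[1])

  one_class <- feats[feats$label == "healthy", ]
  expect_error(train_mlp(one_class), "both classes")
})

test_that("sigmoid/SGD preset also learns the separable problem", {
  feats <- toy_features(gap = 10, seed = 6)
  cfg <- mlp_config(hidden_neurons = 10, activation = "sigmoid",
                    optimizer = "sgd", learning_rate = 0.5, seed = 8)
  model <- train_mlp(feats, cfg = cfg)
  expect_gte(mean(predict(model, feats) == feats$label), 0.95)
})

test_that("evaluate reports sensitivity on epilepsy and confusion totals", {
  feats <- toy_features(gap = 8, seed = 3)
  model <- train_mlp(feats, cfg = mlp_config(seed = 1))
  ev <- evaluate(model, feats)
  expect_equal(sum(ev$confusion), nrow(feats))
  m <- metrics_from_confusion(ev$confusion["tp"], ev$confusion["fn"],
                              ev$confusion["tn"], ev$confusion["fp"])
  expect_equal(unname(ev$metrics), unname(m))
})

test_that("run_experiment: fold count, identity, leakage-free determinism", {
  feats <- toy_features(n_subj = 8, cycles = 30, gap = 6, seed = 9)
  rep1 <- run_experiment(feats, cfg = mlp_config(max_epochs = 200), k = 4,
                         seed = 11)
  expect_s3_class(rep1, "eval_report")
  expect_equal(nrow(rep1$per_fold), 4)
  expect_gte(rep1$accuracy["mean"], 0.95)
  # metric identity: accuracy = (sens*P + spec*N) / (P + N) on pooled counts
  P <- rep1$confusion["tp"] + rep1$confusion["fn"]
  N <- rep1$confusion["tn"] + rep1$confusion["fp"]
  pooled <- metrics_from_confusion(rep1$confusion["tp"], rep1$confusion["fn"],
                                   rep1$confusion["tn"], rep1$confusion["fp"])
  expect_equal(unname(pooled["accuracy"]),
               unname((pooled["sensitivity"] * P + pooled["specificity"] * N) /
                        (P + N)))
  rep2 <- run_experiment(feats, cfg = mlp_config(max_epochs = 200), k = 4,
                         seed = 11)
  expect_equal(rep1$per_fold, rep2$per_fold)
  # report formatting: two decimals with ± dispersion
  out <- capture.output(print(rep1))
  expect_true(any(grepl("accuracy\\s+\\d\\.\\d{2} ± \\d\\.\\d{2}", out)))
})

test_that("holdout mode evaluates a single patient-level split", {
  feats <- toy_features(n_subj = 8, cycles = 20, gap = 8, seed = 10)
  rep <- run_experiment(feats, cfg = mlp_config(max_epochs = 200),
                        mode = "holdout", seed = 2)
  expect_equal(nrow(rep$per_fold), 1)
  expect_gte(rep$accuracy["mean"], 0.9)
})

test_that("label permutation drives accuracy to chance", {
  feats <- toy_features(n_subj = 10, cycles = 40, gap = 8, seed = 12)
  rep <- run_experiment(feats, cfg = mlp_config(max_epochs = 150), k = 5,
                        seed = 13, permute_labels = TRUE)
  expect_lt(abs(rep$accuracy["mean"] - 0.5), 0.1)
})
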