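#' Patient-level train/test split
#'
#' Assigns whole subjects to train or test, stratified by class label (and by
#' sex when supplied), so that no subject's cycles ever appear on both sides
#' -- the grouping that prevents identity leakage in patient-wise evaluation.
#' Within each stratum, `floor(train_fraction * n)` subjects (at least 1,
#' leaving at least 1 for test) are drawn for training; e.g. 5 males + 13
#' females at fraction 0.7 gives 3 + 9 training and 2 + 4 test subjects.
#'
#' @param subjects Data frame with columns `subject_id`, `label` and
#'   optionally `sex`; or a character vector of ids with `labels` supplied
#'   separately.
#' @param train_fraction Fraction of subjects per stratum assigned to train.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param labels,sex Optional vectors parallel to `subjects` when it is a
#'   plain vector.
#' @return A `split_plan`: data frame `subject_id`, `label`, `fold` where
#'   `fold` is `"train"` or `"test"`.
#' @export
make_patient_split <- function(subjects, train_fraction = 0.7, seed = 1L,
                               labels = NULL, sex = NULL) {
  tab <- as_subject_table(subjects, labels, sex)
  if (any(table(tab$label) < 2L)) {
    stop("every class needs at least 2 subjects to hold one out", call. = FALSE)
  }
  strata <- if (is.null(tab$sex)) {
    interaction(tab$label, drop = TRUE)
  } else {
    interaction(tab$label, tab$sex, drop = TRUE)
  }
  assign <- character(nrow(tab))
  with_seed(seed, {
    for (s in levels(strata)) {
      i <- which(strata == s)
      n <- length(i)
      n_train <- max(1L, min(n - 1L, floor(train_fraction * n)))
      train_i <- i[sample.int(n, n_train)]
      assign[train_i] <- "train"
      assign[setdiff(i, train_i)] <- "test"
    }
  })
  structure(data.frame(subject_id = tab$subject_id, label = tab$label,
                       fold = assign, stringsAsFactors = FALSE),
            class = c("split_plan", "data.frame"), k = NA_integer_)
}

#' Patient-grouped k-fold plan
#'
#' Distributes whole subjects over `k` folds, stratified by class: within each
#' class, subjects are shuffled (seeded) and dealt round-robin to folds.
#' Every subject lands in exactly one fold, so a subject never straddles the
#' train/test boundary of any fold. With fewer subjects than folds some folds
#' receive no test subject and are skipped at evaluation time.
#'
#' @param subjects As in [make_patient_split()].
#' @param k Number of folds (>= 2).
#' @inheritParams make_patient_split
#' @return A `split_plan` data frame `subject_id`, `label`, `fold` with
#'   integer folds in `1..k`.
#' @export
grouped_kfold <- function(subjects, k = 10L, seed = 1L, labels = NULL) {
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  tab <- as_subject_table(subjects, labels, NULL)
  fold <- integer(nrow(tab))
  with_seed(seed, {
    offset <- 0L
    for (lbl in unique(tab$label)) {
      i <- which(tab$label == lbl)
      i <- i[sample.int(length(i))]
      # stagger class offsets so small folds still mix classes
      fold[i] <- ((seq_along(i) - 1L + offset) %% k) + 1L
      offset <- offset + length(i)
    }
  })
  structure(data.frame(subject_id = tab$subject_id, label = tab$label,
                       fold = fold, stringsAsFactors = FALSE),
            class = c("split_plan", "data.frame"), k = as.integer(k))
}

as_subject_table <- function(subjects, labels, sex) {
  if (is.data.frame(subjects)) {
    tab <- data.frame(subject_id = as.character(subjects$subject_id),
                      label = as.character(subjects$label),
                      stringsAsFactors = FALSE)
    if (!is.null(subjects$sex)) tab$sex <- as.character(subjects$sex)
  } else {
    tab <- data.frame(subject_id = as.character(subjects),
                      label = as.character(labels), stringsAsFactors = FALSE)
    if (!is.null(sex)) tab$sex <- as.character(sex)
  }
  if (anyNA(tab$label)) stop("labels required for every subject", call. = FALSE)
  if (anyDuplicated(tab$subject_id)) {
    stop("duplicated subject ids", call. = FALSE)
  }
  tab
}

#' Classification metrics from confusion counts
#'
#' Sensitivity is the true-positive rate on the epilepsy (positive) class,
#' specificity the true-negative rate on the healthy class:
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`. A metric whose denominator is zero
#' (no positive or no negative instances) is reported as `NA`, not 0.
#'
#' @param tp,fn,tn,fp Confusion counts.
#' @return Named numeric vector `(accuracy, sensitivity, specificity)`.
#' @examples
#' metrics_from_confusion(tp = 97, fn = 3, tn = 98, fp = 2)
#' @export
metrics_from_confusion <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  c(accuracy = if (total > 0) (tp + tn) / total else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Evaluate a trained model on labelled cycles
#'
#' Predicts every row of a labelled feature table and reports accuracy,
#' sensitivity and specificity with the epilepsy class as positive, together
#' with the confusion counts.
#'
#' @param model An `mlp_model` from [train_mlp()].
#' @param features A `cycle_features` table with a `label` column.
#' @param positive_class Positive class for sensitivity (default
#'   `"epilepsy"`).
#' @return A list: `metrics` (accuracy/sensitivity/specificity) and
#'   `confusion` (tp, fn, tn, fp).
#' @export
evaluate <- function(model, features, positive_class = "epilepsy") {
  truth <- factor(as.character(features$label),
                  levels = c("healthy", "epilepsy"))
  pred <- predict(model, features)
  pos <- truth == positive_class
  hit <- pred == truth
  conf <- c(tp = sum(pos & hit), fn = sum(pos & !hit),
            tn = sum(!pos & hit), fp = sum(!pos & !hit))
  list(metrics = metrics_from_confusion(conf["tp"], conf["fn"], conf["tn"],
                                        conf["fp"]),
       confusion = conf)
}

#' Run a patient-grouped classification experiment
#'
#' Trains and evaluates the MLP on a per-cycle feature table under one of two
#' protocols: `mode = "cv"`, patient-grouped k-fold cross-validation (each
#' fold's subjects are the test set, all others train); or `mode =
#' "holdout"`, a single stratified ~70/30 patient split. Fold assignment
#' depends only on the subject ids, labels and `seed` -- not on
#' `center_kind` -- so mean- and median-centered feature tables from the same
#' records are evaluated on identical folds, enabling paired comparison.
#'
#' @param features A `cycle_features` table ([extract_features()] /
#'   [features_from_records()]).
#' @param cfg An [mlp_config()].
#' @param k Folds for `mode = "cv"`.
#' @param seed Integer seed driving fold assignment and weight
#'   initialization.
#' @param mode `"cv"` or `"holdout"`.
#' @param train_fraction Train fraction for `mode = "holdout"`.
#' @param use_center Add the center statistic as a fourth MLP input.
#' @param permute_labels Permutation-null control: after fold construction on
#'   the true subjects, cycle labels are randomly permuted (seeded), severing
#'   the label-feature association. A sound pipeline then scores at chance
#'   (~0.5) accuracy.
#' @return An `eval_report`: per-fold metrics, their mean and standard
#'   deviation, pooled confusion totals, and per-subject majority-vote
#'   accuracy as a separate field.
#' @export
run_experiment <- function(features, cfg = mlp_config(), k = 10L, seed = 1L,
                           mode = c("cv", "holdout"), train_fraction = 0.7,
                           use_center = FALSE, permute_labels = FALSE) {
  mode <- match.arg(mode)
  subjects <- unique(data.frame(subject_id = features$subject_id,
                                label = features$label,
                                stringsAsFactors = FALSE))
  if (permute_labels) {
    features$label <- with_seed(derive_seed(seed, 104729L),
                                sample(features$label))
  }
  if (length(unique(subjects$label)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  plan <- if (mode == "cv") {
    grouped_kfold(subjects, k = k, seed = seed)
  } else {
    make_patient_split(subjects, train_fraction = train_fraction, seed = seed)
  }
  fold_ids <- if (mode == "cv") sort(unique(plan$fold)) else "test"

  per_fold <- list()
  conf_total <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  votes <- list()
  for (f in fold_ids) {
    test_subj <- plan$subject_id[plan$fold == f]
    train_subj <- setdiff(plan$subject_id, test_subj)
    tr <- features[features$subject_id %in% train_subj, , drop = FALSE]
    te <- features[features$subject_id %in% test_subj, , drop = FALSE]
    stopifnot(length(intersect(unique(tr$subject_id),
                               unique(te$subject_id))) == 0L)
    if (!nrow(te) || length(unique(tr$label)) < 2L) next
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(seed, match(f, fold_ids))
    model <- train_mlp(tr, cfg = fold_cfg, use_center = use_center)
    ev <- evaluate(model, te)
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(fold = f, n_test = nrow(te), t(ev$metrics),
                 stringsAsFactors = FALSE)
    conf_total <- conf_total + ev$confusion
    pred <- predict(model, te)
    votes[[length(votes) + 1L]] <-
      data.frame(subject_id = te$subject_id, label = te$label,
                 pred = as.character(pred), stringsAsFactors = FALSE)
  }
  per_fold <- do.call(rbind, per_fold)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  votes <- do.call(rbind, votes)
  subj_vote <- majority_vote(votes)

  structure(list(
    mode = mode, k = if (mode == "cv") k else 1L,
    center_kind = unique(features$center_kind)[1L],
    per_fold = per_fold,
    accuracy = agg(per_fold$accuracy),
    sensitivity = agg(per_fold$sensitivity),
    specificity = agg(per_fold$specificity),
    confusion = conf_total,
    subject_majority = subj_vote,
    seed = seed
  ), class = "eval_report")
}

majority_vote <- function(votes) {
  if (is.null(votes) || !nrow(votes)) return(NULL)
  per_subj <- lapply(split(votes, votes$subject_id), function(d) {
    tab <- table(d$pred)
    data.frame(subject_id = d$subject_id[1L], label = d$label[1L],
               pred = names(tab)[which.max(tab)], stringsAsFactors = FALSE)
  })
  per_subj <- do.call(rbind, per_subj)
  rownames(per_subj) <- NULL
  attr(per_subj, "accuracy") <- mean(per_subj$pred == per_subj$label)
  per_subj
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(m) sprintf("%.2f ± %.2f", m["mean"],
                             if (is.na(m["sd"])) 0 else m["sd"])
  cat(sprintf("<eval_report> %s, %s-centered features, %d fold(s)\n",
              x$mode, x$center_kind, nrow(x$per_fold)))
  cat(sprintf("  accuracy    %s\n", fmt(x$accuracy)))
  cat(sprintf("  sensitivity %s\n", fmt(x$sensitivity)))
  cat(sprintf("  specificity %s\n", fmt(x$specificity)))
  cat(sprintf("  confusion   TP=%d FN=%d TN=%d FP=%d\n",
              as.integer(x$confusion["tp"]), as.integer(x$confusion["fn"]),
              as.integer(x$confusion["tn"]), as.integer(x$confusion["fp"])))
  if (!is.null(x$subject_majority)) {
    cat(sprintf("  per-subject majority-vote accuracy %.2f\n",
                attr(x$subject_majority, "accuracy")))
  }
  invisible(x)
}
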