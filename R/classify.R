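# Classification and selection protocols: chronological 80/20 and
# leave-one-subject-out evaluation, single-feature screening, gain-based
# electrode ranking. Classifiers are the six classical learners; their
# hyperparameters follow the reference settings (see classifier_config).

#' Classifier configuration
#'
#' Reference hyperparameter settings per method:
#' `knn` 5 neighbours; `svm` linear kernel, C = 10, gamma = 200;
#' `rf` 200 trees, depth 10, minimum leaf 1; `gbt` 100 rounds, depth 10,
#' learning rate 0.1; `lda` and `gnb` have none. Stochastic learners
#' (`rf`, `gbt`) are seeded.
#'
#' @param method one of `"gbt"`, `"rf"`, `"svm"`, `"knn"`, `"gnb"`, `"lda"`.
#' @param seed integer seed for stochastic learners.
#' @param params named list overriding individual hyperparameters.
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(method = c("gbt", "rf", "svm", "knn", "gnb", "lda"),
                              seed = 1L, params = list()) {
  method <- match.arg(method)
  defaults <- switch(method,
    gbt = list(nrounds = 100L, max_depth = 10L, eta = 0.1),
    rf  = list(num_trees = 200L, max_depth = 10L, min_node_size = 1L),
    svm = list(cost = 10, gamma = 200),
    knn = list(k = 5L),
    gnb = list(),
    lda = list())
  defaults[names(params)] <- params
  structure(list(method = method, seed = as.integer(seed), params = defaults),
            class = "classifier_config")
}

# ---- wide feature table -------------------------------------------------

.meta_cols <- c("subject_id", "group", "trial_id", "label", "window_index",
                "channel")

#' Pivot a long feature table to one row per window
#'
#' The long table from [extract_features()] has one row per channel-window;
#' classifiers consume one row per window with `feature_channel` columns.
#' Rows are ordered by subject, trial, then window index (chronological
#' within trial), columns by feature then channel - both deterministic.
#'
#' @param features long feature data frame.
#' @param feature_set optional subset of feature column names to keep
#'   (default: every non-metadata column).
#' @param channels optional subset of channel labels to keep.
#' @return A list with `x` (numeric matrix), `meta` (data frame with
#'   `subject_id`, `group`, `trial_id`, `label`, `window_index`), and
#'   `channels`.
#' @export
features_wide <- function(features, feature_set = NULL, channels = NULL) {
  fcols <- setdiff(names(features), .meta_cols)
  if (!is.null(feature_set)) {
    missing <- setdiff(feature_set, fcols)
    if (length(missing)) .fail("unknown feature(s): %s",
                               paste(missing, collapse = ", "))
    fcols <- feature_set
  }
  chs <- unique(features$channel)
  if (!is.null(channels)) {
    missing <- setdiff(channels, chs)
    if (length(missing)) .fail("unknown channel(s): %s",
                               paste(missing, collapse = ", "))
    chs <- channels
    features <- features[features$channel %in% chs, , drop = FALSE]
  }
  key <- interaction(features$subject_id, features$trial_id,
                     features$window_index, drop = TRUE, lex.order = TRUE)
  meta <- features[!duplicated(key),
                   c("subject_id", "group", "trial_id", "label",
                     "window_index")]
  ord <- order(meta$subject_id, meta$trial_id, meta$window_index)
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  rowkey <- paste(meta$subject_id, meta$trial_id, meta$window_index, sep = "\r")
  x <- matrix(NA_real_, nrow(meta), length(fcols) * length(chs),
              dimnames = list(NULL, paste(rep(fcols, each = length(chs)),
                                          rep(chs, length(fcols)), sep = "_")))
  ri <- match(paste(features$subject_id, features$trial_id,
                    features$window_index, sep = "\r"), rowkey)
  for (f in fcols) {
    ci <- match(paste(f, features$channel, sep = "_"), colnames(x))
    x[cbind(ri, ci)] <- features[[f]]
  }
  if (anyNA(x)) .fail("incomplete feature table: missing channel-window cells")
  list(x = x, meta = meta, channels = chs)
}

# ---- split, scaling -----------------------------------------------------

#' Chronological 80/20 split
#'
#' Within each trial the windows are ordered by index; the first
#' `train_fraction` go to training, the rest to test. No shuffling, no
#' randomness.
#'
#' @param meta data frame with `subject_id`, `trial_id`, `window_index`
#'   (e.g. `features_wide()$meta`).
#' @param train_fraction fraction of each trial's windows used for
#'   training (default 0.8).
#' @return A list with integer row indices `train` and `test`.
#' @export
chrono_split <- function(meta, train_fraction = 0.8) {
  trial <- interaction(meta$subject_id, meta$trial_id, drop = TRUE)
  train <- integer(0); test <- integer(0)
  for (tr in levels(trial)) {
    idx <- which(trial == tr)
    idx <- idx[order(meta$window_index[idx])]
    k <- floor(train_fraction * length(idx))
    if (k < 1L || k >= length(idx))
      .fail("trial %s has too few windows (%d) for a %g/%g split",
            tr, length(idx), train_fraction, 1 - train_fraction)
    train <- c(train, idx[seq_len(k)])
    test <- c(test, idx[(k + 1L):length(idx)])
  }
  list(train = sort(train), test = sort(test))
}

#' Fit a per-column z-score scaler on training rows only
#' @param x numeric training matrix.
#' @return A `feature_scaler` with `center` and `scale` (zero-variance
#'   columns get scale 1).
#' @export
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  structure(list(center = ctr, scale = scl), class = "feature_scaler")
}

#' Apply a fitted scaler
#' @param scaler a `feature_scaler` from [fit_scaler()].
#' @param x numeric matrix with the same columns.
#' @return The z-scored matrix.
#' @export
apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2L, scaler$center), 2L, scaler$scale, "/")
}

# ---- model fitting ------------------------------------------------------

# evaluate expr with a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

.fit_model <- function(x, y, config) {
  y <- factor(y)
  pr <- config$params
  .with_seed(config$seed, .fit_model_impl(x, y, config, pr))
}

.fit_model_impl <- function(x, y, config, pr) {
  switch(config$method,
    lda = {
      fit <- MASS::lda(x, grouping = y)
      list(predict = function(newx) stats::predict(fit, newx)$class)
    },
    gnb = {
      fit <- e1071::naiveBayes(x, y)
      list(predict = function(newx) stats::predict(fit, newx))
    },
    knn = {
      list(predict = function(newx)
        class::knn(train = x, test = newx, cl = y, k = pr$k))
    },
    svm = {
      fit <- e1071::svm(x, y, kernel = "linear", cost = pr$cost,
                        gamma = pr$gamma, scale = FALSE)
      list(predict = function(newx) stats::predict(fit, newx))
    },
    rf = {
      fit <- ranger::ranger(x = x, y = y, num.trees = pr$num_trees,
                            max.depth = pr$max_depth,
                            min.node.size = pr$min_node_size,
                            num.threads = 1L, seed = config$seed)
      list(predict = function(newx)
        stats::predict(fit, data = newx, num.threads = 1L)$predictions)
    },
    gbt = {
      lev <- levels(y)
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softmax", num_class = length(lev),
                      max_depth = pr$max_depth, eta = pr$eta,
                      nthread = 1L, seed = config$seed),
        data = dtrain, nrounds = pr$nrounds, verbose = 0)
      list(predict = function(newx) {
        cls <- stats::predict(fit, xgboost::xgb.DMatrix(newx))
        factor(lev[cls + 1L], levels = lev)
      }, booster = fit)
    })
}

.eval_result <- function(truth, pred, levels_) {
  truth <- factor(truth, levels = levels_)
  pred <- factor(pred, levels = levels_)
  confusion <- table(truth = truth, predicted = pred)
  acc <- 100 * sum(diag(confusion)) / sum(confusion)
  per_class <- 100 * diag(confusion) / rowSums(confusion)
  structure(list(accuracy = acc, confusion = confusion,
                 per_class_accuracy = per_class),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> accuracy %.2f%%\n", x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Train and evaluate with the chronological 80/20 protocol
#'
#' Per trial, the first 80% of windows train and the last 20% test;
#' features are z-scored with training statistics only.
#'
#' @param features long feature data frame from [extract_features()].
#' @param config a [classifier_config()].
#' @param train_fraction see [chrono_split()].
#' @param feature_set,channels optional restriction, see [features_wide()].
#' @return An `eval_result`: `accuracy` (percent), `confusion`
#'   (class x class counts), `per_class_accuracy`, plus the fitted
#'   `scaler` and the `split` used (for leakage audits).
#' @export
train_eval <- function(features, config = classifier_config(),
                       train_fraction = 0.8, feature_set = NULL,
                       channels = NULL) {
  wide <- features_wide(features, feature_set, channels)
  split <- chrono_split(wide$meta, train_fraction)
  y <- factor(wide$meta$label)
  if (any(table(y[split$train]) == 0) || any(table(y[split$test]) == 0))
    .fail("a class is absent from the training or test portion")
  scaler <- fit_scaler(wide$x[split$train, , drop = FALSE])
  xtr <- apply_scaler(scaler, wide$x[split$train, , drop = FALSE])
  xte <- apply_scaler(scaler, wide$x[split$test, , drop = FALSE])
  model <- .fit_model(xtr, y[split$train], config)
  res <- .eval_result(y[split$test], model$predict(xte), levels(y))
  res$scaler <- scaler
  res$split <- split
  res
}

#' Per-feature classification accuracy
#'
#' Each of the sixteen topological features is evaluated on its own: the
#' classifier sees only that feature's columns (one per channel) under the
#' chronological split.
#'
#' @inheritParams train_eval
#' @param feature_set features to screen (default [topo_feature_names()]).
#' @return Named numeric vector of accuracies in percent.
#' @export
evaluate_single_features <- function(features, config = classifier_config(),
                                     feature_set = topo_feature_names(),
                                     train_fraction = 0.8) {
  vapply(feature_set, function(f)
    train_eval(features, config, train_fraction, feature_set = f)$accuracy,
    0)
}

#' Rank electrode channels by boosted-tree gain
#'
#' Fits an ensemble of gradient-boosted-tree models on all
#' `feature x channel` columns and aggregates the per-column split-gain
#' importances by channel (mean over features and ensemble members;
#' columns never used by a split contribute gain 0). The ensemble members
#' differ in their seed and use column/row subsampling
#' (`colsample_bytree`, `subsample`), which spreads credit across
#' correlated channels and stabilises the ranking at small sample sizes -
#' a single deep boosted fit tends to put all of its gain on one member
#' of a redundant channel group.
#'
#' @param features long feature data frame.
#' @param config a [classifier_config()] with `method = "gbt"`; its tree
#'   depth, learning rate and round count are used for every member.
#' @param n_repeats ensemble size (default 16).
#' @param colsample,subsample column/row subsampling rates per member
#'   (defaults 0.4 and 0.6).
#' @return A `gain_report`: `gain` (feature x channel matrix),
#'   `channel_mean_gain`, and `channel_rank` (channels by descending mean
#'   gain, ties toward the input channel order).
#' @export
rank_channels_by_gain <- function(features, config = classifier_config("gbt"),
                                  n_repeats = 16L, colsample = 0.4,
                                  subsample = 0.6) {
  if (config$method != "gbt") .fail("gain ranking requires method = 'gbt'")
  wide <- features_wide(features)
  y <- factor(wide$meta$label)
  scaler <- fit_scaler(wide$x)
  x <- apply_scaler(scaler, wide$x)
  pr <- config$params
  gain_by_col <- stats::setNames(rep(0, ncol(x)), colnames(x))
  for (r in seq_len(n_repeats)) {
    seed_r <- config$seed + r - 1L
    bst <- .with_seed(seed_r, {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softmax", num_class = nlevels(y),
                      max_depth = pr$max_depth, eta = pr$eta,
                      colsample_bytree = colsample, subsample = subsample,
                      nthread = 1L, seed = seed_r),
        data = dtrain, nrounds = pr$nrounds, verbose = 0)
    })
    imp <- xgboost::xgb.importance(model = bst)
    gain_by_col[imp$Feature] <- gain_by_col[imp$Feature] + imp$Gain / n_repeats
  }
  fcols <- unique(sub(paste0("_(", paste(wide$channels, collapse = "|"), ")$"),
                      "", names(gain_by_col)))
  gain <- matrix(0, length(fcols), length(wide$channels),
                 dimnames = list(fcols, wide$channels))
  for (f in fcols) for (ch in wide$channels)
    gain[f, ch] <- gain_by_col[[paste(f, ch, sep = "_")]]
  mean_gain <- colMeans(gain)
  rank <- wide$channels[order(-mean_gain, seq_along(mean_gain))]
  structure(list(gain = gain, channel_mean_gain = mean_gain,
                 channel_rank = rank),
            class = "gain_report")
}

#' @export
print.gain_report <- function(x, ...) {
  cat("<gain_report> channels by mean gain:\n")
  print(round(sort(x$channel_mean_gain, decreasing = TRUE), 5))
  invisible(x)
}

#' Bilateral montage mate of an electrode label
#'
#' In the 10-20/10-10 dialect, lateral electrodes carry a trailing number:
#' odd on the left, even on the right (T7/T8, C3/C4, FP1/FP2). The mate
#' flips the number by one; midline electrodes (trailing `z`/`Z`) and
#' unknown labels have none.
#'
#' @param label electrode label (case preserved).
#' @return The mate label, or `NA` if there is none.
#' @export
montage_mate <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)([0-9]+)$", label))[[1]]
  if (length(m) != 3L) return(NA_character_)
  num <- as.integer(m[3])
  paste0(m[2], if (num %% 2 == 1) num + 1L else num - 1L)
}

#' Select the top-k channels from a gain report
#'
#' Channels are taken in descending mean-gain order. With
#' `symmetry = TRUE`, the bilateral mate of each selected lateral electrode
#' is co-selected (immediately after it) when present in the montage,
#' before truncation to `k`.
#'
#' @param report a `gain_report` from [rank_channels_by_gain()].
#' @param k number of channels to keep (default 12).
#' @param symmetry co-select bilateral mates (default `FALSE`).
#' @return Character vector of `k` channel labels.
#' @export
select_channels <- function(report, k = 12L, symmetry = FALSE) {
  all_ch <- names(report$channel_mean_gain)
  if (k > length(all_ch)) .fail("k (%d) exceeds channel count (%d)",
                                k, length(all_ch))
  ordered <- report$channel_rank
  if (symmetry) {
    expanded <- character(0)
    for (ch in ordered) {
      expanded <- c(expanded, ch)
      mate <- montage_mate(ch)
      if (!is.na(mate)) {
        hit <- all_ch[toupper(all_ch) == toupper(mate)]
        if (length(hit)) expanded <- c(expanded, hit[1L])
      }
    }
    ordered <- expanded[!duplicated(expanded)]
  }
  ordered[seq_len(k)]
}

#' Leave-one-subject-out evaluation with group-crossed classes
#'
#' Labels are formed as `(group, emotion)` pairs. For every subject, a
#' model is trained on all other subjects and tested on the held-out
#' subject's windows; per-subject accuracies and the pooled confusion
#' matrix are reported. Features are z-scored per fold with
#' training-fold statistics.
#'
#' @inheritParams train_eval
#' @return A `loso_result`: `per_subject` (named accuracy vector, percent),
#'   `accuracy` (mean of per-subject accuracies), `confusion` (pooled
#'   class x class counts).
#' @export
loso_cross_group <- function(features, config = classifier_config(),
                             feature_set = NULL, channels = NULL) {
  wide <- features_wide(features, feature_set, channels)
  y <- factor(paste(wide$meta$group, wide$meta$label, sep = "."))
  subjects <- unique(wide$meta$subject_id)
  if (length(subjects) < 2L) .fail("need at least 2 subjects for LOSO")
  per_group <- table(unique(wide$meta[c("subject_id", "group")])$group)
  if (any(per_group < 2L))
    .fail("need at least 2 subjects per group for a cross-group protocol")
  lev <- levels(y)
  pooled <- matrix(0L, length(lev), length(lev),
                   dimnames = list(truth = lev, predicted = lev))
  acc <- stats::setNames(numeric(length(subjects)), subjects)
  for (s in subjects) {
    te <- which(wide$meta$subject_id == s)
    tr <- setdiff(seq_len(nrow(wide$x)), te)
    scaler <- fit_scaler(wide$x[tr, , drop = FALSE])
    model <- .fit_model(apply_scaler(scaler, wide$x[tr, , drop = FALSE]),
                        y[tr], config)
    pred <- model$predict(apply_scaler(scaler, wide$x[te, , drop = FALSE]))
    res <- .eval_result(y[te], pred, lev)
    acc[s] <- res$accuracy
    pooled <- pooled + unclass(res$confusion)
  }
  structure(list(per_subject = acc, accuracy = mean(acc),
                 confusion = as.table(pooled)),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> mean accuracy %.2f%% over %d subjects\n",
              x$accuracy, length(x$per_subject)))
  print(round(x$per_subject, 2))
  invisible(x)
}

#' Per-class feature summaries
#'
#' Mean and sample standard deviation of each feature per class (or per
#' group x class), across all channel-window rows by default.
#'
#' @param features long feature data frame.
#' @param feature_set features to summarise (default
#'   [topo_feature_names()]).
#' @param by grouping columns (default `"label"`; use
#'   `c("group", "label")` for group-wise tables).
#' @return A data frame with the grouping columns, `feature`, `mean`,
#'   `sd`, and `n`.
#' @export
summarize_features <- function(features, feature_set = topo_feature_names(),
                               by = "label") {
  if (!nrow(features)) .fail("empty feature table")
  groups <- interaction(features[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    sub <- features[groups == g, , drop = FALSE]
    do.call(rbind, lapply(feature_set, function(f) {
      cbind(sub[1L, by, drop = FALSE],
            data.frame(feature = f, mean = mean(sub[[f]]),
                       sd = stats::sd(sub[[f]]), n = nrow(sub)))
    }))
  }))
  rownames(out) <- NULL
  out
}
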