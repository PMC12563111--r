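# A small synthetic feature table built directly (no signal processing):
# n_win windows per trial, one row per channel-window.
make_feature_table <- function(n_subj = 2, classes = c("a", "b"),
                               n_trials = 2, n_win = 10,
                               channels = c("T7", "T8", "O1", "O2"),
                               groups = "g1",
                               fill = function(label, channel, n) rnorm(n)) {
  rows <- list()
  for (g in groups) for (s in seq_len(n_subj)) for (cl in classes)
    for (tr in seq_len(n_trials)) for (ch in channels) {
      vals <- lapply(topo_feature_names(), function(f)
        fill(cl, ch, n_win))
      names(vals) <- topo_feature_names()
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject_id = paste0(g, "_s", s), group = g,
                   trial_id = paste0(cl, tr), label = cl,
                   window_index = seq_len(n_win) - 1L, channel = ch),
        as.data.frame(vals))
    }
  do.call(rbind, rows)
}

test_that("the chronological split is deterministic and never shuffles", {
  tab <- make_feature_table(n_win = 20)
  wide <- features_wide(tab)
  sp <- chrono_split(wide$meta)
  # 20 windows per trial -> 16 train + 4 test, test strictly after train
  for (tr in unique(paste(wide$meta$subject_id, wide$meta$trial_id))) {
    idx <- which(paste(wide$meta$subject_id, wide$meta$trial_id) == tr)
    expect_length(intersect(idx, sp$train), 16L)
    expect_length(intersect(idx, sp$test), 4L)
    expect_true(max(wide$meta$window_index[intersect(idx, sp$train)]) <
                  min(wide$meta$window_index[intersect(idx, sp$test)]))
  }
  expect_identical(sp, chrono_split(wide$meta))
  expect_error(chrono_split(wide$meta[wide$meta$window_index == 0, ]),
               "too few")
})

test_that("a perfectly separable feature classifies at 100%", {
  tab <- make_feature_table(fill = function(label, channel, n)
    (label == "a") * 10 + rnorm(n, sd = 0.01))
  for (m in c("gbt", "knn", "lda")) {
    # lda warns about collinearity on the near-constant separable fixture
    res <- suppressWarnings(train_eval(tab, classifier_config(m, seed = 1)))
    expect_equal(res$accuracy, 100)
    expect_equal(sum(res$confusion), length(res$split$test))
  }
})

test_that("pure-noise features stay at chance level", {
  set.seed(50)
  accs <- replicate(20, {
    tab <- make_feature_table(n_win = 10)
    train_eval(tab, classifier_config("gbt", seed = 1))$accuracy
  })
  n_test <- 2 * 2 * 2 * 2   # subjects x classes x trials x test windows
  band <- 3 * sqrt(0.25 / (20 * n_test)) * 100
  expect_lt(abs(mean(accs) - 50), band)
})

test_that("accuracy equals the confusion-matrix trace ratio", {
  set.seed(51)
  tab <- make_feature_table(fill = function(label, channel, n)
    (label == "a") * 2 + rnorm(n))
  res <- train_eval(tab, classifier_config("gbt", seed = 1))
  expect_equal(res$accuracy,
               100 * sum(diag(res$confusion)) / sum(res$confusion))
  expect_equal(unname(rowSums(res$confusion)),
               unname(as.vector(table(features_wide(tab)$meta$label[res$split$test]))))
})

test_that("single-feature screening finds the intended subset", {
  set.seed(52)
  good <- c("SACC", "SAC")
  tab <- make_feature_table(n_win = 10)
  for (f in good) tab[[f]] <- tab[[f]] + (tab$label == "a") * 8
  accs <- evaluate_single_features(tab, classifier_config("gbt", seed = 1))
  expect_named(accs, topo_feature_names())
  floor_acc <- 90
  expect_setequal(names(accs)[accs >= floor_acc], good)
})

test_that("gain ranking recovers planted channels and is structurally sound", {
  set.seed(53)
  tab <- make_feature_table(channels = c("F3", "F4", "C3", "C4"), n_win = 12)
  for (f in topo_feature_names())
    tab[[f]] <- tab[[f]] +
      (tab$label == "a") * 4 * (tab$channel %in% c("F4", "C3"))
  rep <- rank_channels_by_gain(tab, classifier_config("gbt", seed = 1))
  expect_setequal(rep$channel_rank, c("F3", "F4", "C3", "C4"))
  expect_true(all(rep$gain >= 0))
  expect_setequal(rep$channel_rank[1:2], c("F4", "C3"))
  expect_error(rank_channels_by_gain(tab, classifier_config("svm")), "gbt")
})

test_that("channel selection respects k and bilateral symmetry", {
  gain <- c(T7 = 5, O1 = 4, CZ = 3, T8 = 0.5, O2 = 0.2, F3 = 0.1)
  rep <- structure(list(channel_mean_gain = gain,
                        channel_rank = names(sort(gain, decreasing = TRUE))),
                   class = "gain_report")
  expect_identical(select_channels(rep, k = 6), names(gain))
  expect_identical(select_channels(rep, k = 2), c("T7", "O1"))
  # symmetry pulls the mates forward before truncation
  expect_identical(select_channels(rep, k = 4, symmetry = TRUE),
                   c("T7", "T8", "O1", "O2"))
  expect_error(select_channels(rep, k = 10), "exceeds")

  expect_identical(montage_mate("T7"), "T8")
  expect_identical(montage_mate("FP2"), "FP1")
  expect_true(is.na(montage_mate("CZ")))
})

test_that("LOSO folds hold out whole subjects and conserve counts", {
  set.seed(54)
  tab <- make_feature_table(n_subj = 2, groups = c("normal_hearing",
                                                   "hearing_impaired"),
                            classes = c("sad", "happy"), n_win = 6,
                            fill = function(label, channel, n)
                              rnorm(n, mean = 3 * (label == "sad")))
  res <- loso_cross_group(tab, classifier_config("gbt", seed = 1))
  expect_length(res$per_subject, 4L)
  wide <- features_wide(tab)
  truth <- table(factor(paste(wide$meta$group, wide$meta$label, sep = ".")))
  expect_equal(unname(rowSums(res$confusion)), unname(as.vector(truth)))
  expect_equal(res$accuracy, mean(res$per_subject))

  one_subj <- tab[tab$subject_id != "hearing_impaired_s2", ]
  expect_error(loso_cross_group(one_subj, classifier_config("gbt")),
               "2 subjects per group")
})

test_that("feature summaries compute grouped means and sds", {
  tab <- make_feature_table(n_win = 4)
  tab$SACC <- 7                               # constant
  tab$SACT <- ifelse(tab$label == "a", 1, 3)  # midpoint 2 overall
  sm <- summarize_features(tab, feature_set = c("SACC", "SACT"))
  expect_equal(sm$sd[sm$feature == "SACC"], c(0, 0))
  expect_equal(sm$mean[sm$feature == "SACT"], c(1, 3))
  overall <- summarize_features(transform(tab, label = "all"),
                                feature_set = "SACT")
  expect_equal(overall$mean, 2)
})

test_that("no training statistic leaks from the test rows", {
  set.seed(55)
  tab <- make_feature_table(n_win = 10)
  wide <- features_wide(tab)
  sp <- chrono_split(wide$meta)
  scaler <- fit_scaler(wide$x[sp$train, ])
  # corrupt every test row and refit: identical training-derived statistics
  x2 <- wide$x
  x2[sp$test, ] <- 1e6 * matrix(rnorm(length(sp$test) * ncol(x2)),
                                length(sp$test))
  expect_identical(fit_scaler(x2[sp$train, ]), scaler)
  # gain ranking computed on training rows only is equally unaffected
  tab2 <- tab
  test_keys <- paste(wide$meta$subject_id, wide$meta$trial_id,
                     wide$meta$window_index)[sp$test]
  in_test <- paste(tab2$subject_id, tab2$trial_id, tab2$window_index) %in%
    test_keys
  tab2[in_test, topo_feature_names()] <- 1e6
  train_tab <- tab[!in_test, ]
  train_tab2 <- tab2[!in_test, ]
  r1 <- rank_channels_by_gain(train_tab, classifier_config("gbt", seed = 1))
  r2 <- rank_channels_by_gain(train_tab2, classifier_config("gbt", seed = 1))
  expect_identical(r1$gain, r2$gain)
})
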