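# Gaussian feature-table fixture: six band features with a controllable
# class separation on a subset of features.
fake_table <- function(seed, n_per_class = 300, sep = 2,
                       informative = c("delta", "high_beta")) {
  set.seed(seed)
  feats <- c("delta", "theta", "alpha", "sigma", "high_beta", "low_gamma")
  lab <- factor(rep(c("NREM", "Wake"), each = n_per_class),
                levels = c("NREM", "Wake"))
  d <- as.data.frame(lapply(setNames(feats, feats), function(f) {
    mu <- if (f %in% informative) sep * (as.integer(lab) - 1.5) else 0
    rnorm(2 * n_per_class, mean = mu)
  }))
  d$label <- lab
  d$stage <- ifelse(lab == "Wake", "W", "N2")
  d$region <- "cortex"
  class(d) <- c("feature_table", "data.frame")
  d
}

test_that("class balancing reduces NREM to the wake count, only that", {
  feats <- c("delta", "theta", "alpha", "sigma", "high_beta", "low_gamma")
  mk <- function(n_nrem, n_wake) {
    d <- as.data.frame(lapply(setNames(feats, feats),
                              function(f) rnorm(n_nrem + n_wake)))
    d$stage <- c(rep(c("N2", "N3"), length.out = n_nrem), rep("W", n_wake))
    d$region <- "cortex"
    d
  }
  ft <- build_features_balanced(mk(5000, 800), "cortex", seed = 7)
  expect_equal(as.numeric(table(ft$label)), c(800, 800))
  # deterministic under seed
  ft2 <- build_features_balanced(mk(5000, 800), "cortex", seed = 7)
  expect_equal(which(ft$delta[1] == mk(5000, 800)$delta),
               which(ft2$delta[1] == mk(5000, 800)$delta))
  # wake > NREM: only warn, keep everything
  expect_warning(ftw <- build_features_balanced(mk(100, 300), "cortex",
                                                seed = 1),
                 "only reduces NREM")
  expect_equal(nrow(ftw), 400)
  expect_error(build_features_balanced(mk(100, 0), "cortex", seed = 1),
               "both classes")
})

test_that("confusion metrics satisfy their algebraic identities exactly", {
  set.seed(11)
  truth <- factor(sample(c("NREM", "Wake"), 500, replace = TRUE,
                         prob = c(0.7, 0.3)), levels = c("NREM", "Wake"))
  scores <- runif(500) + 0.3 * (truth == "Wake")
  pred <- factor(ifelse(scores > 0.6, "Wake", "NREM"),
                 levels = c("NREM", "Wake"))
  m <- confusion_metrics(truth, pred, scores)
  prev <- mean(truth == "Wake")
  sens <- unname(m["sensitivity"]) / 100
  spec <- unname(m["specificity"]) / 100
  expect_equal(unname(m["ppv"]) / 100,
               sens * prev / (sens * prev + (1 - spec) * (1 - prev)))
  expect_equal(unname(m["npv"]) / 100,
               spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev))
  expect_equal(unname(m["accuracy"]) / 100,
               sens * prev + spec * (1 - prev))
  expect_true(all(m >= 0 & m <= 100))
})

test_that("cross-validated SVM separates well-separated classes", {
  ft <- fake_table(1, sep = 3)
  cv <- crossval_svm(ft, k = 5, seed = 2)
  expect_gt(cv$metrics$mean[cv$metrics$metric == "accuracy"], 90)
  expect_gt(cv$metrics$mean[cv$metrics$metric == "auc"], 95)
  # 2-fold agrees within simulation noise
  cv2 <- crossval_svm(ft, k = 2, seed = 2)
  expect_lt(abs(cv$metrics$mean[1] - cv2$metrics$mean[1]), 6)
  # folds partition the data and never train on their own test rows
  expect_equal(sort(unique(cv$fold)), 1:5)
  for (f in 1:5)
    expect_lte(cv$models[[f]]$tot.nSV, sum(cv$fold != f))
})

test_that("label permutation calibrates accuracy and AUC to chance", {
  ft <- fake_table(3, sep = 3, n_per_class = 200)
  accs <- vapply(1:8, function(p) {
    ftp <- ft
    set.seed(p)
    ftp$label <- sample(ftp$label)
    cv <- crossval_svm(ftp, k = 5, seed = p)
    cv$metrics$mean[cv$metrics$metric == "accuracy"]
  }, 0)
  expect_lt(abs(mean(accs) - 50), 5)
})

test_that("a single informative feature approaches its Bayes pair", {
  # 1-D oracle: best threshold on the informative feature by direct sweep
  ft <- fake_table(5, sep = 2, informative = "delta", n_per_class = 400)
  sweep_acc <- function(x, lab) {
    cand <- sort(unique(x))
    max(vapply(cand, function(thr)
      mean((x > thr) == (lab == "Wake")), 0))
  }
  oracle <- sweep_acc(ft$delta, ft$label)
  cv <- crossval_svm(ft, k = 5, seed = 6)
  bal <- (cv$metrics$mean[cv$metrics$metric == "sensitivity"] +
            cv$metrics$mean[cv$metrics$metric == "specificity"]) / 2
  expect_lt(abs(bal / 100 - oracle), 0.06)
})

test_that("mutual-information ranking finds the informative bands", {
  ft <- fake_table(7, sep = 0)
  ft$delta <- as.numeric(ft$label == "Wake") + rnorm(nrow(ft), sd = 0.05)
  mi <- rank_features_mi(ft)
  expect_equal(mi$feature[mi$rank == 1], "delta")
  expect_gt(mi$mi_bits[mi$feature == "delta"], 0.8)
  expect_true(all(mi$mi_bits >= 0))
  expect_lt(max(mi$mi_bits[mi$feature != "delta"]), 0.05)
})

test_that("wake-detection timecourse is zero for unambiguous NREM", {
  ft <- fake_table(9, sep = 4)
  cv <- crossval_svm(ft, k = 5, seed = 1)
  nrem_rows <- ft[ft$label == "NREM", ][1:40, ]
  nrem_rows$rel_t_s <- rep(c(-47.5, -42.5), 20)
  tc <- wake_detection_timecourse(cv$models, nrem_rows)
  expect_equal(tc$wake_pct, c(0, 0))
  expect_equal(tc$n, c(20, 20))
})

test_that("peri-transition epochs are held out of the training pool", {
  n <- cached_night(test_cfg(301, dur = 2700))
  bp <- epoch_band_powers(n$clean_recording, n$hypnogram, epoch_len_s = 5,
                          scheme = "ml")
  bps <- bp[bp$region == "subcortex", ]
  ev <- find_transitions(n$hypnogram)
  spl <- build_transition_features(bps, ev)
  expect_gt(nrow(spl$transition_ft), 0)
  expect_equal(nrow(spl$train_pool) + nrow(spl$transition_ft), nrow(bps))
  # wake-anchored labels are 5 s midpoints
  expect_true(all(abs(spl$transition_ft$rel_t_s / 5 -
                        floor(spl$transition_ft$rel_t_s / 5) - 0.5) < 1e-9))
  # no epoch in the training pool lies inside a peri-event window
  for (e in which(ev$valid)) {
    w <- ev$wake_onset_s[e]
    expect_false(any(spl$train_pool$t_label_s > w - 60 &
                       spl$train_pool$t_label_s < w + 30 &
                       spl$train_pool$t_label_s > ev$nrem_onset_s[e]))
  }
})
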