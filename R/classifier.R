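## NREM-vs-wake classification from six band-power features: class-balanced
## feature tables, cross-validated Gaussian-kernel SVMs with fold-wise
## metrics, mutual-information feature ranking, and the time-resolved wake
## detection around awakenings.

ML_FEATURES <- c("delta", "theta", "alpha", "sigma", "high_beta",
                 "low_gamma")

#' Build a class-balanced NREM/wake feature table
#'
#' Selects one region's epochs (hemispheres pooled), labels N2/N3 as `NREM`
#' and W as `Wake`, and randomly downsamples the NREM rows without
#' replacement to the wake count. The rule only reduces NREM: when wake
#' outnumbers NREM a warning is issued and both classes are kept whole.
#'
#' @param epochs data.frame from [epoch_band_powers()] computed with the
#'   `"ml"` scheme.
#' @param region `"cortex"` or `"subcortex"`.
#' @param seed RNG seed for the subsample (deterministic given it).
#' @return data.frame of class `feature_table`: six feature columns, a
#'   `label` factor (`NREM`/`Wake`) and metadata columns.
#' @export
build_features_balanced <- function(epochs, region = c("cortex", "subcortex"),
                                    seed = 1L) {
  region <- match.arg(region)
  d <- epochs[epochs$region == region & epochs$stage %in% c("N2", "N3", "W"), ]
  d$label <- factor(ifelse(d$stage == "W", "Wake", "NREM"),
                    levels = c("NREM", "Wake"))
  n_w <- sum(d$label == "Wake"); n_n <- sum(d$label == "NREM")
  if (n_w == 0 || n_n == 0) stop("both classes must be present")
  if (n_n > n_w) {
    with_seed(seed, {
      keep_n <- sample(which(d$label == "NREM"), n_w)
      d <- d[sort(c(keep_n, which(d$label == "Wake"))), ]
    })
  } else if (n_w > n_n) {
    warning("wake epochs outnumber NREM; balancing rule only reduces NREM, ",
            "keeping all rows")
  }
  rownames(d) <- NULL
  class(d) <- c("feature_table", "data.frame")
  d
}

#' Binary classification metrics from a confusion matrix
#'
#' Accuracy, AUC, sensitivity, specificity, PPV and NPV in percent, with
#' Wake as the positive class. All metrics derive from one confusion matrix,
#' so their algebraic identities (e.g. PPV from sensitivity, specificity and
#' prevalence) hold exactly.
#'
#' @param truth,pred factors/characters with levels NREM/Wake.
#' @param scores numeric scores for the AUC (probability of Wake).
#' @return named numeric vector (percent).
#' @export
confusion_metrics <- function(truth, pred, scores) {
  # positive class = Wake
  tp <- sum(truth == "Wake" & pred == "Wake")
  tn <- sum(truth == "NREM" & pred == "NREM")
  fp <- sum(truth == "NREM" & pred == "Wake")
  fn <- sum(truth == "Wake" & pred == "NREM")
  auc <- if (length(unique(truth)) == 2)
    as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                   levels = c("NREM", "Wake"),
                                   direction = "<", quiet = TRUE)))
  else NA_real_
  c(accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    auc = 100 * auc,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    ppv = 100 * tp / (tp + fp),
    npv = 100 * tn / (tn + fn))
}

.stratified_folds <- function(label, k, seed) {
  with_seed(seed, {
    fold <- integer(length(label))
    for (cl in levels(label)) {
      idx <- sample(which(label == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Cross-validated Gaussian-kernel SVM for NREM vs wake
#'
#' Stratified k-fold cross-validation of a radial-kernel SVM with fixed
#' kernel width 2.6 (Gaussian `exp(-||x-z||^2 / 2.6^2)`), features
#' standardized on the training folds only, uniform prior, and a 0.5
#' threshold on the Platt probability score (no threshold optimization).
#' The optional asymmetric cost makes missing a wake epoch costlier than
#' missing NREM, as wanted for awakening-sensitive 5 s models.
#'
#' @param ft a [build_features_balanced()] table.
#' @param k folds (5 or 2).
#' @param cost_wake_miss relative cost of misclassifying Wake as NREM
#'   (class weight on Wake); 1 = symmetric.
#' @param kernel_width Gaussian kernel width.
#' @param seed RNG seed for fold assignment.
#' @return list of class `cv_report`: `metrics` (per metric mean and SEM
#'   across folds, %), `fold_metrics`, `models`, `fold` assignment.
#' @export
crossval_svm <- function(ft, k = 5, cost_wake_miss = 1, kernel_width = 2.6,
                         seed = 1L) {
  stopifnot(inherits(ft, "feature_table"), k >= 2)
  X <- as.matrix(ft[, ML_FEATURES])
  y <- ft$label
  fold <- .stratified_folds(y, k, seed)
  gamma <- 1 / kernel_width^2
  wts <- c(NREM = 1, Wake = cost_wake_miss)
  fold_metrics <- matrix(NA_real_, nrow = k, ncol = 6,
                         dimnames = list(NULL, c("accuracy", "auc",
                                                 "sensitivity", "specificity",
                                                 "ppv", "npv")))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    m <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr], kernel = "radial",
                    gamma = gamma, scale = TRUE, probability = TRUE,
                    class.weights = wts)
    pr <- stats::predict(m, X[te, , drop = FALSE], probability = TRUE)
    p_wake <- attr(pr, "probabilities")[, "Wake"]
    pred <- factor(ifelse(p_wake >= 0.5, "Wake", "NREM"),
                   levels = c("NREM", "Wake"))
    fold_metrics[f, ] <- confusion_metrics(y[te], pred, p_wake)
    models[[f]] <- m
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(
    metrics = data.frame(metric = colnames(fold_metrics),
                         mean = colMeans(fold_metrics),
                         sem = apply(fold_metrics, 2, sem)),
    fold_metrics = fold_metrics, models = models, fold = fold,
    scheme = paste0(k, "-fold")), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$scheme, " cross-validation\n")
  m <- x$metrics
  m$mean <- sprintf("%.2f", m$mean); m$sem <- sprintf("%.2f", m$sem)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Mutual-information ranking of band-power features
#'
#' Plug-in mutual information (bits) between each equal-frequency-discretized
#' feature (16 bins) and the binary NREM/wake label, with the Miller-Madow
#' bias correction, ranked descending.
#'
#' @param ft a `feature_table`.
#' @param n_bins discretization bins per feature.
#' @return data.frame: `feature`, `mi_bits`, `rank`.
#' @export
rank_features_mi <- function(ft, n_bins = 16) {
  stopifnot(inherits(ft, "feature_table"))
  y <- ft$label
  mi <- vapply(ML_FEATURES, function(f) {
    x <- ft[[f]]
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    xb <- cut(x, breaks = br, include.lowest = TRUE)
    tab <- table(xb, y)
    n <- sum(tab)
    pxy <- tab / n
    px <- rowSums(pxy); py <- colSums(pxy)
    nz <- pxy > 0
    mi_hat <- sum(pxy[nz] * log2(pxy[nz] /
                                   outer(px, py)[nz]))
    # Miller-Madow: + (K_xy - K_x - K_y + 1) / (2 n ln 2)
    corr <- (sum(nz) - sum(px > 0) - sum(py > 0) + 1) / (2 * n * log(2))
    max(mi_hat + corr, 0)
  }, 0)
  out <- data.frame(feature = ML_FEATURES, mi_bits = unname(mi))
  out$rank <- rank(-out$mi_bits, ties.method = "first")
  out[order(out$rank), ]
}

#' Classify epochs with a set of fold models
#'
#' Majority vote of Wake/NREM decisions (0.5 probability threshold per
#' model) across the trained fold models.
#'
#' @param models list of [e1071::svm] fits from [crossval_svm()].
#' @param ft feature table of epochs to classify.
#' @return fraction of models voting Wake, per epoch.
#' @export
predict_wake_fraction <- function(models, ft) {
  X <- as.matrix(ft[, ML_FEATURES])
  votes <- vapply(models, function(m) {
    pr <- stats::predict(m, X, probability = TRUE)
    as.numeric(attr(pr, "probabilities")[, "Wake"] >= 0.5)
  }, numeric(nrow(X)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  rowMeans(votes)
}

#' Split epochs into a training pool and peri-transition evaluation set
#'
#' For one night's epoch table and its validated transitions, marks the
#' epochs inside `[-window_pre_s, +window_post_s)` around each awakening
#' with their relative time `rel_t_s` (the fine-track wake onsets sit on the
#' 5 s grid, so peri-event bins coincide with global epochs). Marked epochs
#' are removed from the training pool so that evaluation around awakenings
#' is held out from model training.
#'
#' @param epochs one night's rows from [epoch_band_powers()] (5 s, `ml`
#'   scheme).
#' @param events [find_transitions()] rows for the same night.
#' @param window_pre_s,window_post_s peri-event window around wake onset,
#'   seconds.
#' @return list(`train_pool`, `transition_ft`); the latter carries
#'   `rel_t_s` and `event_id`.
#' @export
build_transition_features <- function(epochs, events, window_pre_s = 60,
                                      window_post_s = 30) {
  events <- events[events$valid, , drop = FALSE]
  rel <- rep(NA_real_, nrow(epochs))
  eid <- rep(NA_integer_, nrow(epochs))
  for (e in seq_len(nrow(events))) {
    w <- events$wake_onset_s[e]
    lo <- max(w - window_pre_s, events$nrem_onset_s[e])
    hi <- min(w + window_post_s,
              events$wake_onset_s[e] + events$wake_dur_s[e])
    in_win <- epochs$t_label_s > lo & epochs$t_label_s < hi
    rel[in_win] <- epochs$t_label_s[in_win] - w
    eid[in_win] <- e
  }
  tf <- epochs[!is.na(rel), , drop = FALSE]
  tf$rel_t_s <- rel[!is.na(rel)]
  tf$event_id <- eid[!is.na(rel)]
  class(tf) <- c("feature_table", "data.frame")
  list(train_pool = epochs[is.na(rel), , drop = FALSE], transition_ft = tf)
}

#' Time-resolved wake detection around awakenings
#'
#' For feature-table rows carrying a relative time to awakening (`rel_t_s`),
#' returns the percentage of epochs classified Wake per relative-time bin
#' (mean and SEM across epochs). The models must have been trained on data
#' excluding the evaluated transition epochs.
#'
#' @param models fold models from [crossval_svm()].
#' @param transition_ft feature table with a `rel_t_s` column.
#' @return data.frame: `rel_t_s`, `wake_pct`, `sem`, `n`.
#' @export
wake_detection_timecourse <- function(models, transition_ft) {
  stopifnot("rel_t_s" %in% names(transition_ft))
  wf <- predict_wake_fraction(models, transition_ft)
  wake_vote <- as.numeric(wf >= 0.5)
  bins <- sort(unique(transition_ft$rel_t_s))
  out <- do.call(rbind, lapply(bins, function(b) {
    v <- wake_vote[transition_ft$rel_t_s == b]
    data.frame(rel_t_s = b, wake_pct = 100 * mean(v),
               sem = 100 * stats::sd(v) / sqrt(length(v)), n = length(v))
  }))
  out
}
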