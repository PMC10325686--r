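#' Confusion-matrix metrics
#'
#' @param y_true,y_pred Binary vectors of equal, non-zero length.
#' @return List with `accuracy`, `sensitivity`, `ppv`, `npv`, the counts
#'   `tp`, `fp`, `fn`, `tn`, and `undefined` — the names of any metric with
#'   a zero denominator (those come back `NA`, flagged rather than 0).
#' @export
confusion_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(
    accuracy = (tp + tn) / length(y_true),
    sensitivity = safe(tp, tp + fn),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
  out$undefined <- names(which(vapply(out[c("sensitivity", "ppv", "npv")],
                                      is.na, TRUE)))
  out
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair-ranking probability: the fraction of
#' (positive, negative) pairs where the positive scores higher, ties
#' counted one half. Invariant under strictly monotone score transforms.
#'
#' @param y_true Binary labels; both classes must be present.
#' @param scores Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  np <- sum(y_true == 1)
  nn <- sum(y_true == 0)
  if (np == 0 || nn == 0)
    stop("roc_auc requires both classes present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Mean and t-based 95% confidence interval over folds
#'
#' @param fold_values Numeric vector, length >= 2.
#' @param conf Confidence level.
#' @return List with `mean`, `ci_low`, `ci_high`
#'   (mean +/- t(1 - (1-conf)/2, k-1) * sd / sqrt(k)).
#' @export
fold_mean_ci <- function(fold_values, conf = 0.95) {
  k <- length(fold_values)
  if (k < 2) stop("need at least 2 fold values", call. = FALSE)
  m <- mean(fold_values)
  half <- stats::qt(1 - (1 - conf) / 2, df = k - 1) *
    stats::sd(fold_values) / sqrt(k)
  list(mean = m, ci_low = m - half, ci_high = m + half)
}

#' Aggregate sector calls into a per-patient 16-segment map
#'
#' Each AHA segment is `scar` when the majority of its retained
#' slice-sectors are scar-positive (ties count as scar), `healthy`
#' otherwise, and `excluded` when the segment has no retained sectors
#' (e.g. segments 13-16 when all apical slices belonged to the cap).
#'
#' @param segments Integer vector of AHA ids (1-16), one per retained
#'   sector.
#' @param positive Logical/binary vector: is the sector scar-positive?
#' @param tie Policy for exact ties, `"scar"` (default) or `"healthy"`.
#' @return An `aha_map`: named character vector of length 16
#'   (`"1"`..`"16"`) with values scar/healthy/excluded.
#' @export
aggregate_aha <- function(segments, positive, tie = c("scar", "healthy")) {
  tie <- match.arg(tie)
  stopifnot(length(segments) == length(positive))
  positive <- as.logical(positive)
  out <- stats::setNames(rep("excluded", 16L), as.character(1:16))
  for (seg in unique(segments)) {
    pos <- sum(positive[segments == seg])
    tot <- sum(segments == seg)
    out[as.character(seg)] <-
      if (pos * 2 > tot || (pos * 2 == tot && tie == "scar" && tot > 0))
        "scar" else "healthy"
  }
  class(out) <- "aha_map"
  out
}

#' Cohen's kappa for a 2 x 2 agreement table
#'
#' @param a,b,c,d Counts: both positive, rater1-only, rater2-only, both
#'   negative.
#' @return List with `kappa`, `ci_low`, `ci_high` (large-sample standard
#'   error), `po`, `pe`.
#' @export
cohen_kappa2 <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) stop("empty agreement table", call. = FALSE)
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (pe == 1) {
    kap <- if (po == 1) 1 else 0
    return(list(kappa = kap, ci_low = kap, ci_high = kap, po = po, pe = pe))
  }
  kap <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  list(kappa = kap, ci_low = kap - 1.96 * se, ci_high = kap + 1.96 * se,
       po = po, pe = pe)
}

#' Segment-level agreement between predicted and reference AHA maps
#'
#' For every AHA segment, the predicted and reference states across
#' patients form a 2 x 2 table (segments excluded in either map are
#' dropped pairwise) scored with Cohen's kappa; overall agreement is the
#' fraction of matching non-excluded segment states.
#'
#' @param predicted_maps,reference_maps Lists of `aha_map`s (same patients,
#'   same order).
#' @return List with `per_segment` (data frame: segment, n, accuracy,
#'   kappa, ci_low, ci_high) and `overall_agreement`.
#' @export
segment_agreement <- function(predicted_maps, reference_maps) {
  stopifnot(length(predicted_maps) == length(reference_maps),
            length(predicted_maps) > 0)
  match_n <- 0L
  total_n <- 0L
  rows <- list()
  for (seg in as.character(1:16)) {
    p <- vapply(predicted_maps, `[[`, "", seg)
    r <- vapply(reference_maps, `[[`, "", seg)
    keep <- p != "excluded" & r != "excluded"
    p <- p[keep]; r <- r[keep]
    n <- length(p)
    total_n <- total_n + n
    match_n <- match_n + sum(p == r)
    if (n == 0) {
      rows[[seg]] <- data.frame(segment = as.integer(seg), n = 0L,
                                accuracy = NA_real_, kappa = NA_real_,
                                ci_low = NA_real_, ci_high = NA_real_)
      next
    }
    a <- sum(p == "scar" & r == "scar")
    b <- sum(p == "scar" & r == "healthy")
    c_ <- sum(p == "healthy" & r == "scar")
    d <- sum(p == "healthy" & r == "healthy")
    kp <- cohen_kappa2(a, b, c_, d)
    rows[[seg]] <- data.frame(segment = as.integer(seg), n = n,
                              accuracy = (a + d) / n, kappa = kp$kappa,
                              ci_low = kp$ci_low, ci_high = kp$ci_high)
  }
  if (total_n == 0)
    stop("no overlapping non-excluded segments", call. = FALSE)
  list(per_segment = do.call(rbind, rows),
       overall_agreement = match_n / total_n)
}

#' Mean ROC curve over folds
#'
#' Vertical averaging of per-fold ROC curves over a fixed grid of
#' false-positive rates.
#'
#' @param fold_truth,fold_scores Lists (one element per fold) of labels and
#'   scores.
#' @param fpr_grid Grid of false-positive rates.
#' @return Data frame with columns `fpr`, `tpr_mean`.
#' @export
mean_roc <- function(fold_truth, fold_scores,
                     fpr_grid = seq(0, 1, by = 0.01)) {
  tprs <- vapply(seq_along(fold_truth), function(i) {
    y <- as.integer(fold_truth[[i]])
    s <- fold_scores[[i]]
    thr <- c(Inf, sort(unique(s), decreasing = TRUE))
    fpr <- vapply(thr, function(t) mean(s[y == 0] >= t), 0)
    tpr <- vapply(thr, function(t) mean(s[y == 1] >= t), 0)
    stats::approx(c(0, fpr, 1), c(0, tpr, 1), xout = fpr_grid,
                  ties = max, rule = 2)$y
  }, numeric(length(fpr_grid)))
  data.frame(fpr = fpr_grid, tpr_mean = rowMeans(tprs))
}

#' Patient-wise cross-validated training and evaluation
#'
#' For every fold, a fresh network is trained on the remaining folds (a
#' patient-wise 10% validation carve-out drives the plateau scheduler, and
#' the majority class is undersampled to balance in the training portion
#' only), then scored on the held-out fold with its natural class balance.
#' Every patient is predicted exactly once.
#'
#' @param samples List with `patches` (list of 85 x 85 matrices) and `meta`
#'   (data frame: patient_id, aha_segment, slice_index, label in 0/1).
#' @param folds A [make_folds()] split of the same patients.
#' @param arch,cfg Network and training configuration.
#' @param augment_cfg Optional [augment_config()] for training.
#' @param verbose Print progress.
#' @return A `metrics_report`: per-fold metrics, their fold means with 95%
#'   CIs, pooled predictions (`predictions` data frame), per-patient
#'   predicted and reference `aha_maps`, and `agreement`.
#' @export
run_cross_validation <- function(samples, folds, arch = arch_config(),
                                 cfg = train_config(), augment_cfg = NULL,
                                 verbose = FALSE) {
  meta <- samples$meta
  patches <- samples$patches
  stopifnot(length(patches) == nrow(meta))
  k <- folds$k
  fold_of <- folds$fold_of_patient
  per_fold <- list()
  preds <- list()
  fold_truth <- list()
  fold_scores <- list()

  for (f in seq_len(k)) {
    test_pat <- names(fold_of)[fold_of == f]
    train_pat <- names(fold_of)[fold_of != f]
    # patient-wise validation carve-out from the training folds
    n_val <- max(1L, ceiling(0.1 * length(train_pat)))
    val_pat <- with_seed(cfg$seed + f, sample(train_pat, n_val))
    core_pat <- setdiff(train_pat, val_pat)
    tr_idx <- which(meta$patient_id %in% core_pat)
    va_idx <- which(meta$patient_id %in% val_pat)
    te_idx <- which(meta$patient_id %in% test_pat)
    if (length(va_idx) == 0) va_idx <- tr_idx
    keep <- undersample(meta$label[tr_idx], seed = cfg$seed + 100L + f)
    tr_idx <- tr_idx[keep]
    if (verbose)
      message(sprintf("fold %d: train %d (balanced), val %d, test %d",
                      f, length(tr_idx), length(va_idx), length(te_idx)))
    fit <- train_cnn(patches[tr_idx], meta$label[tr_idx],
                     patches[va_idx], meta$label[va_idx],
                     arch, cfg, augment_cfg = augment_cfg, verbose = verbose)
    sc <- predict_cnn(fit$model, patches[te_idx])
    yb <- meta$label[te_idx]
    pb <- as.integer(sc > 0.5)
    cm <- confusion_metrics(yb, pb)
    per_fold[[f]] <- data.frame(
      fold = f, n_test = length(te_idx),
      accuracy = cm$accuracy, sensitivity = cm$sensitivity,
      ppv = cm$ppv, npv = cm$npv,
      auc = if (length(unique(yb)) == 2) roc_auc(yb, sc) else NA_real_,
      tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn
    )
    preds[[f]] <- data.frame(meta[te_idx, , drop = FALSE], score = sc,
                             pred = pb, fold = f)
    fold_truth[[f]] <- yb
    fold_scores[[f]] <- sc
  }

  fold_df <- do.call(rbind, per_fold)
  pred_df <- do.call(rbind, preds)
  summary <- lapply(c("accuracy", "sensitivity", "ppv", "npv", "auc"),
                    function(mname) {
    v <- fold_df[[mname]]
    v <- v[!is.na(v)]
    if (length(v) >= 2) c(fold_mean_ci(v), list(metric = mname))
    else list(mean = mean(v), ci_low = NA_real_, ci_high = NA_real_,
              metric = mname)
  })
  names(summary) <- c("accuracy", "sensitivity", "ppv", "npv", "auc")

  pred_maps <- list()
  ref_maps <- list()
  for (p in unique(pred_df$patient_id)) {
    rows <- pred_df[pred_df$patient_id == p, ]
    pred_maps[[p]] <- aggregate_aha(rows$aha_segment, rows$pred == 1L)
    ref_maps[[p]] <- aggregate_aha(rows$aha_segment, rows$label == 1L)
  }
  agree <- segment_agreement(pred_maps, ref_maps)

  structure(list(per_fold = fold_df, summary = summary,
                 predictions = pred_df,
                 roc = mean_roc(fold_truth, fold_scores),
                 predicted_maps = pred_maps, reference_maps = ref_maps,
                 agreement = agree),
            class = "metrics_report")
}
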