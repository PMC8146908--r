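#' Confusion counts for detection evaluation
#'
#' Detection settings have no natural true-negative class (there are no
#' "true background objects" on a conveyor), so `tn` defaults to 0 and
#' accuracy computed from it must be read with that caveat; reports flag
#' it.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return A `sv_confusion` object.
#' @export
confusion_counts <- function(tp, fp, fn, tn = 0) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v)))
    abort("confusion counts must be non-negative integers",
          class = "sv_domain_error")
  structure(as.list(v), class = "sv_confusion")
}

#' @export
print.sv_confusion <- function(x, ...) {
  cat(sprintf("<confusion: TP %d, FP %d, FN %d, TN %d (no natural TN in detection)>\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' @export
tidy.sv_confusion <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
                 precision = precision(x$tp, x$fp),
                 recall = recall(x$tp, x$fn))
}

#' Match predicted to ground-truth centroids
#'
#' Greedy one-to-one matching in increasing centroid-distance order: pairs
#' within `max_dist` become true positives, unmatched predictions false
#' positives, unmatched truths false negatives. This formalizes the
#' by-eye TP/FP/FN judgement of manual evaluation so it is reproducible.
#'
#' @param predicted,truth Data frames with columns `row`, `col` (px), or
#'   two-column matrices.
#' @param max_dist Maximum centroid distance for a match (px); a sensible
#'   default is half the expected bulb diameter in px.
#' @return A [confusion_counts()] with attribute `"matches"`: a tibble of
#'   matched index pairs and their distances.
#' @export
match_detections <- function(predicted, truth, max_dist) {
  if (max_dist <= 0)
    abort("max_dist must be > 0", class = "sv_domain_error")
  p <- as.matrix(as.data.frame(predicted)[, c("row", "col")])
  t_ <- as.matrix(as.data.frame(truth)[, c("row", "col")])
  np <- nrow(p); nt <- nrow(t_)
  matches <- tibble::tibble(pred = integer(0), truth = integer(0),
                            dist = numeric(0))
  if (np > 0 && nt > 0) {
    dmat <- sqrt(outer(p[, 1], t_[, 1], "-")^2 + outer(p[, 2], t_[, 2], "-")^2)
    cand <- which(dmat <= max_dist, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      used_p <- logical(np); used_t <- logical(nt)
      for (i in seq_len(nrow(cand))) {
        a <- cand[i, 1]; b <- cand[i, 2]
        if (used_p[a] || used_t[b]) next
        used_p[a] <- TRUE; used_t[b] <- TRUE
        matches <- dplyr::bind_rows(matches, tibble::tibble(
          pred = as.integer(a), truth = as.integer(b), dist = dmat[a, b]))
      }
    }
  }
  out <- confusion_counts(tp = nrow(matches), fp = np - nrow(matches),
                          fn = nt - nrow(matches), tn = 0)
  attr(out, "matches") <- matches
  out
}

#' Detection/classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`. For detection runs TN is 0 by
#' construction, which depresses this number; precision and recall are the
#' meaningful pair there.
#'
#' @param c A [confusion_counts()].
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "sv_confusion"))
  tot <- c$tp + c$tn + c$fp + c$fn
  if (tot == 0)
    abort("accuracy undefined for all-zero counts", class = "sv_domain_error")
  (c$tp + c$tn) / tot
}

#' Precision (positive predictive value)
#'
#' `TP / (TP + FP)`.
#'
#' @param tp,fp Counts, or a [confusion_counts()] as `tp`.
#' @return Fraction in \[0, 1\].
#' @examples
#' precision(1115, 352)  # 0.760
#' @export
precision <- function(tp, fp) {
  if (inherits(tp, "sv_confusion")) { fp <- tp$fp; tp <- tp$tp }
  if (tp + fp == 0)
    abort("precision undefined when tp + fp = 0", class = "sv_domain_error")
  tp / (tp + fp)
}

#' Recall (sensitivity)
#'
#' `TP / (TP + FN)`.
#'
#' @param tp,fn Counts, or a [confusion_counts()] as `tp`.
#' @return Fraction in \[0, 1\].
#' @examples
#' recall(1115, 418)  # 0.727
#' @export
recall <- function(tp, fn) {
  if (inherits(tp, "sv_confusion")) { fn <- tp$fn; tp <- tp$tp }
  if (tp + fn == 0)
    abort("recall undefined when tp + fn = 0", class = "sv_domain_error")
  tp / (tp + fn)
}

#' Sample standard deviation
#'
#' `sqrt(sum((x - mean)^2) / (n - 1))`.
#'
#' @param xs Numeric vector, length >= 2.
#' @return The sample SD.
#' @export
sample_sd <- function(xs) {
  if (length(xs) < 2)
    abort("sample_sd needs n >= 2", class = "sv_domain_error")
  stats::sd(xs)
}

#' Root mean square error
#'
#' `sqrt(mean((pred - obs)^2))`.
#'
#' @param pred,obs Numeric vectors of equal length (>= 1).
#' @return The RMSE.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) == 0)
    abort("rmse needs equal-length, non-empty vectors",
          class = "sv_domain_error")
  sqrt(mean((pred - obs)^2))
}

#' Standard error of the mean
#'
#' `s / sqrt(n)`.
#'
#' @param s Sample standard deviation (>= 0).
#' @param n Sample size (>= 1).
#' @return The SEM.
#' @export
sem <- function(s, n) {
  if (n < 1) abort("sem needs n >= 1", class = "sv_domain_error")
  if (s < 0) abort("sem needs s >= 0", class = "sv_domain_error")
  s / sqrt(n)
}

#' Evaluate predicted vs true diameters per size class
#'
#' Groups paired samples by the *true* class and reports, per class, the
#' count, classification accuracy, means of predicted and true diameters,
#' mean difference (predicted minus true), sample SDs, and a two-sample
#' Kolmogorov–Smirnov test between the predicted and true diameter
#' distributions; overall, the classification accuracy and diameter RMSE.
#'
#' @param pred,truth Data frames of equal length with columns `diameter_mm`
#'   and `size_class`, row i of `pred` paired with row i of `truth`.
#' @param names Class names in increasing size order.
#' @return A `sv_size_eval` with `$classes` (tibble) and `$overall`
#'   (one-row tibble). [tidy()] returns the per-class table, [glance()]
#'   the overall row.
#' @export
size_eval <- function(pred, truth, names = c("small", "medium", "large")) {
  pred <- as.data.frame(pred); truth <- as.data.frame(truth)
  if (nrow(pred) != nrow(truth))
    abort("pred and truth must be paired (equal length)",
          class = "sv_domain_error")
  stopifnot(all(c("diameter_mm", "size_class") %in% colnames(pred)),
            all(c("diameter_mm", "size_class") %in% colnames(truth)))
  cls <- factor(as.character(truth$size_class), levels = names)
  per <- lapply(names, function(cl) {
    i <- which(cls == cl)
    if (length(i) == 0) {
      return(tibble::tibble(
        size_class = cl, n = 0L, n_correct = 0L, accuracy = NA_real_,
        mean_pred = NA_real_, mean_true = NA_real_,
        mean_difference = NA_real_, sd_pred = NA_real_, sd_true = NA_real_,
        ks_d = NA_real_, ks_p = NA_real_))
    }
    dp <- pred$diameter_mm[i]; dt <- truth$diameter_mm[i]
    ks <- ks_two_sample(dp, dt)
    nc <- sum(as.character(pred$size_class[i]) == cl)
    tibble::tibble(
      size_class = cl, n = length(i), n_correct = nc,
      accuracy = nc / length(i),
      mean_pred = mean(dp), mean_true = mean(dt),
      mean_difference = mean(dp) - mean(dt),
      sd_pred = if (length(i) >= 2) sample_sd(dp) else NA_real_,
      sd_true = if (length(i) >= 2) sample_sd(dt) else NA_real_,
      ks_d = ks$d, ks_p = ks$p_value)
  })
  overall <- tibble::tibble(
    n = nrow(pred),
    accuracy = mean(as.character(pred$size_class) == as.character(cls)),
    rmse = rmse(pred$diameter_mm, truth$diameter_mm))
  structure(list(classes = dplyr::bind_rows(per), overall = overall,
                 data = tibble::tibble(
                   diameter_pred = pred$diameter_mm,
                   diameter_true = truth$diameter_mm,
                   class_pred = as.character(pred$size_class),
                   class_true = as.character(cls))),
            class = "sv_size_eval")
}

#' @export
print.sv_size_eval <- function(x, ...) {
  cat("Per-class size evaluation (grouped by true class):\n")
  print(x$classes)
  cat(sprintf("Overall: accuracy %.3f, RMSE %.2f mm (n = %d)\n",
              x$overall$accuracy, x$overall$rmse, x$overall$n))
  invisible(x)
}

#' @export
tidy.sv_size_eval <- function(x, ...) x$classes

#' @export
glance.sv_size_eval <- function(x, ...) x$overall
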