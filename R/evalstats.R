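# ------------------------------------------------------------------------
# Evaluation statistics: segmentation overlap metrics, paired-measurement
# error metrics, Pearson/ICC/Bland-Altman agreement, normality gating, and
# the k-fold cross-validation driver.
# ------------------------------------------------------------------------

#' Paired measurements of the same samples by two sources
#'
#' @param value_a,value_b Numeric vectors (degrees), same length; `value_b`
#'   is the reference for relative errors.
#' @param sample_id Optional ids.
#' @param labels Length-2 character vector naming the two sources.
#' @return Data frame of class `fmf_paired_measurements`.
#' @export
paired_measurements <- function(value_a, value_b,
                                sample_id = seq_along(value_a),
                                labels = c("a", "b")) {
  stopifnot(length(value_a) == length(value_b),
            all(is.finite(value_a)), all(is.finite(value_b)),
            length(value_a) >= 2)
  structure(data.frame(sample_id = sample_id, value_a = value_a,
                       value_b = value_b, stringsAsFactors = FALSE),
            labels = labels, class = c("fmf_paired_measurements",
                                       "data.frame"))
}

confusion_counts <- function(pred, truth, class_id) {
  p <- pred == class_id
  t <- truth == class_id
  c(TP = sum(p & t), TN = sum(!p & !t), FP = sum(p & !t), FN = sum(!p & t))
}

#' Segmentation overlap metrics: pixel accuracy, IoU, Dice
#'
#' One-vs-rest pixel counts per class give
#' `PA = (TP+TN)/(TP+TN+FP+FN)`, `IoU = TP/(TP+FP+FN)` and
#' `Dice = 2TP/(2TP+FP+FN)`. A class absent from both masks has undefined
#' overlap and is reported as `NA` (never 0).
#'
#' @param pred,truth [label_mask()] objects (or integer matrices) of equal
#'   size.
#' @param class_id Single class index, or `NULL` for a table over all
#'   foreground classes plus their mean.
#' @return For one class, named vector `c(PA, IOU, Dice)`; otherwise a
#'   data frame with one row per foreground class and a `"mean"` row.
#' @export
seg_metrics <- function(pred, truth, class_id = NULL) {
  pm <- if (inherits(pred, "fmf_label_mask")) pred$labels else pred
  tm <- if (inherits(truth, "fmf_label_mask")) truth$labels else truth
  stopifnot(all(dim(pm) == dim(tm)))
  one <- function(cl) {
    cc <- confusion_counts(pm, tm, cl)
    if (cc["TP"] + cc["FP"] + cc["FN"] == 0)
      return(c(PA = unname((cc["TP"] + cc["TN"]) / sum(cc)),
               IOU = NA_real_, Dice = NA_real_))
    c(PA = unname((cc["TP"] + cc["TN"]) / sum(cc)),
      IOU = unname(cc["TP"] / (cc["TP"] + cc["FP"] + cc["FN"])),
      Dice = unname(2 * cc["TP"] / (2 * cc["TP"] + cc["FP"] + cc["FN"])))
  }
  if (!is.null(class_id)) return(one(class_id))
  cls <- sort(setdiff(unique(c(pm, tm)), 0L))
  if (!length(cls)) cls <- 1:2
  tab <- t(vapply(cls, one, numeric(3)))
  cn <- if (inherits(truth, "fmf_label_mask")) truth$class_names[cls + 1L]
        else as.character(cls)
  out <- data.frame(class = c(cn, "mean"),
                    rbind(tab, colMeans(tab, na.rm = TRUE)))
  rownames(out) <- NULL
  out
}

#' Paired-measurement error metrics
#'
#' `MAE = mean(|a - b|)`, `MRE = mean(|a - b| / b)` (reference `b` must be
#' strictly positive), mean difference `mean(a - b)` and its SD with the
#' n−1 denominator.
#'
#' @param pairs A [paired_measurements()] (or data frame with `value_a`,
#'   `value_b`).
#' @param mre Compute MRE (set `FALSE` when references can be ≤ 0).
#' @return Named list `MAE`, `MRE`, `mean_diff`, `sd_diff`.
#' @export
error_metrics <- function(pairs, mre = TRUE) {
  a <- pairs$value_a; b <- pairs$value_b
  d <- a - b
  mre_v <- NA_real_
  if (mre) {
    if (any(b <= 0)) stop("MRE requires strictly positive reference values")
    mre_v <- mean(abs(d) / b)
  }
  list(MAE = mean(abs(d)), MRE = mre_v,
       mean_diff = mean(d), sd_diff = stats::sd(d))
}

#' Intraclass correlation ICC(2,1): two-way random, absolute agreement,
#' single measures
#'
#' Computed from the two-way ANOVA mean squares (subjects x raters):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with `n` subjects, `k = 2` raters, `MS_R` between-subjects, `MS_C`
#' between-raters, `MS_E` residual mean squares. The 95% CI is the standard
#' F-based interval for this variant (Satterthwaite df for the rater term).
#' Absolute agreement penalizes a systematic offset between the raters.
#'
#' @param pairs A [paired_measurements()].
#' @param conf_level Confidence level for the CI.
#' @return List `icc`, `ci95 = c(lo, hi)`, plus the mean squares.
#' @export
icc_absolute_agreement <- function(pairs, conf_level = 0.95) {
  x <- cbind(pairs$value_a, pairs$value_b)
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 3)
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  MSR <- k * sum((rm_ - gm)^2) / (n - 1)
  MSC <- n * sum((cm - gm)^2) / (k - 1)
  SSE <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR < .Machine$double.eps * max(1, gm^2)) {
    warning("zero between-subject variance; ICC undefined")
    return(list(icc = NA_real_, ci95 = c(NA_real_, NA_real_),
                MSR = MSR, MSC = MSC, MSE = MSE))
  }
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSE)
  # the F interval can overshoot the parameter space at small n
  list(icc = icc, ci95 = c(max(-1, lo), min(1, hi)),
       MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Bland–Altman agreement analysis
#'
#' Differences `value_a - value_b` against their per-pair means; limits of
#' agreement are `mean_diff ± 1.96 * sd_diff` (SD with n−1 denominator).
#'
#' @param pairs A [paired_measurements()].
#' @param plot_path Optional PNG/SVG path; if given, the Bland–Altman plot
#'   (solid mean line, dashed 95% limits) is written there.
#' @return List `mean_diff`, `sd_diff`, `loa95 = c(lo, hi)`, and the
#'   per-sample `differences` and `means`.
#' @export
bland_altman <- function(pairs, plot_path = NULL) {
  d <- pairs$value_a - pairs$value_b
  m <- (pairs$value_a + pairs$value_b) / 2
  md <- mean(d); sdd <- stats::sd(d)
  loa <- c(md - 1.96 * sdd, md + 1.96 * sdd)
  if (!is.null(plot_path)) {
    labs <- attr(pairs, "labels")
    if (is.null(labs)) labs <- c("a", "b")
    df <- data.frame(m = m, d = d)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = m, y = d)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_hline(yintercept = md) +
      ggplot2::geom_hline(yintercept = loa, linetype = "dashed") +
      ggplot2::labs(x = sprintf("Mean of %s and %s (deg)", labs[1], labs[2]),
                    y = sprintf("%s - %s (deg)", labs[1], labs[2]),
                    title = "Bland-Altman agreement") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(plot_path, p, width = 5, height = 4, dpi = 150)
  }
  list(mean_diff = md, sd_diff = sdd, loa95 = loa,
       differences = d, means = m)
}

#' Pearson correlation with normality gating
#'
#' Pearson r with two-sided p-value, plus a Shapiro–Wilk test per column at
#' `alpha`; when a column fails normality its median and range are reported
#' alongside (the non-parametric summary used in that case).
#'
#' @param pairs A [paired_measurements()].
#' @param alpha Normality test level.
#' @return List `r`, `p`, `normality_pass` (per column), and
#'   `nonparametric_summary` (medians and ranges, when any column fails).
#' @export
pearson_and_normality <- function(pairs, alpha = 0.05) {
  a <- pairs$value_a; b <- pairs$value_b
  stopifnot(length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(a, b, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  safe_sw <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)   # degenerate: gate fails
    stats::shapiro.test(x)$p.value
  }
  sw <- c(a = safe_sw(a), b = safe_sw(b))
  pass <- !is.na(sw) & sw > alpha
  nonpar <- NULL
  if (!all(pass)) {
    nonpar <- data.frame(column = c("a", "b"),
                         median = c(stats::median(a), stats::median(b)),
                         min = c(min(a), min(b)), max = c(max(a), max(b)))
  }
  list(r = r, p = p, shapiro_p = sw, normality_pass = pass,
       nonparametric_summary = nonpar)
}

#' Full paired-agreement report
#'
#' Assembles the statistics of a two-source comparison: per-source mean±SD,
#' mean difference ± SD, MAE, MRE, Pearson r and p, ICC(2,1) with 95% CI,
#' Bland–Altman 95% limits of agreement, and the normality gate.
#'
#' @param pairs A [paired_measurements()].
#' @param mre Passed to [error_metrics()].
#' @return List of class `fmf_agreement_report`.
#' @export
agreement_report <- function(pairs, mre = TRUE) {
  em <- error_metrics(pairs, mre = mre)
  icc <- icc_absolute_agreement(pairs)
  ba <- bland_altman(pairs)
  pn <- pearson_and_normality(pairs)
  structure(list(
    labels = attr(pairs, "labels"), n = nrow(pairs),
    mean_a = mean(pairs$value_a), sd_a = stats::sd(pairs$value_a),
    mean_b = mean(pairs$value_b), sd_b = stats::sd(pairs$value_b),
    mean_diff = em$mean_diff, sd_diff = em$sd_diff,
    MAE = em$MAE, MRE = em$MRE,
    pearson_r = pn$r, p_value = pn$p,
    icc = icc$icc, icc_ci95 = icc$ci95,
    loa95 = ba$loa95, normality_pass = pn$normality_pass),
    class = "fmf_agreement_report")
}

#' @export
print.fmf_agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (%s vs %s, n = %d)\n",
              x$labels[1], x$labels[2], x$n))
  cat(sprintf("  %-14s %8.3f +/- %.3f\n", x$labels[1], x$mean_a, x$sd_a))
  cat(sprintf("  %-14s %8.3f +/- %.3f\n", x$labels[2], x$mean_b, x$sd_b))
  cat(sprintf("  mean diff      %8.3f +/- %.3f\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  MAE %.3f   MRE %.3f\n", x$MAE, x$MRE))
  cat(sprintf("  Pearson r %.3f (p = %.3g)\n", x$pearson_r, x$p_value))
  cat(sprintf("  ICC(2,1) %.3f (95%% CI %.3f-%.3f)\n",
              x$icc, x$icc_ci95[1], x$icc_ci95[2]))
  cat(sprintf("  Bland-Altman LoA [%.3f, %.3f]\n", x$loa95[1], x$loa95[2]))
  invisible(x)
}

#' k-fold cross-validation of the segmentation stage
#'
#' Deterministic shuffled split of the samples given a seed, one training
#' run per fold, and a per-fold / mean ± SD Dice table per foreground
#' class.
#'
#' @param samples List of image samples (with `$image` and `$mask`).
#' @param k Number of folds.
#' @param config A [seg_config()].
#' @param seed Split seed.
#' @return List with `folds` (id lists) and `dice` (data frame: class,
#'   one column per fold, `mean`, `sd`); folds without foreground truth are
#'   flagged in `flagged_folds`.
#' @export
crossvalidate_segmentation <- function(samples, k = 5, config, seed = 1L) {
  n <- length(samples)
  stopifnot(k >= 2, k <= n)
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  ord <- order(ids)
  set.seed(seed)
  perm <- sample(ord)
  folds <- unname(split(perm, cut(seq_len(n), k, labels = FALSE)))
  cls_names <- samples[[1]]$mask$class_names[-1]
  dice_mat <- matrix(NA_real_, nrow = length(cls_names), ncol = k,
                     dimnames = list(cls_names, paste0("fold", seq_len(k))))
  flagged <- integer(0)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(perm, test_idx)
    has_fg <- any(vapply(samples[test_idx],
                         function(s) any(s$mask$labels > 0), logical(1)))
    if (!has_fg) flagged <- c(flagged, f)
    cfg <- config
    cfg$seed <- config$seed + f
    model <- build_segmenter(cfg)
    fit <- train_segmenter(model, samples[train_idx], cfg)
    per_class <- sapply(test_idx, function(i) {
      pm <- predict_mask(fit$model, samples[[i]]$image)
      vapply(seq_along(cls_names),
             function(ci) seg_metrics(pm, samples[[i]]$mask, ci)["Dice"],
             numeric(1))
    })
    per_class <- matrix(per_class, nrow = length(cls_names))
    dice_mat[, f] <- rowMeans(per_class, na.rm = TRUE)
  }
  dice <- data.frame(class = cls_names, dice_mat,
                     mean = rowMeans(dice_mat, na.rm = TRUE),
                     sd = apply(dice_mat, 1, stats::sd, na.rm = TRUE))
  rownames(dice) <- NULL
  list(folds = lapply(folds, function(ix) ids[ix]), dice = dice,
       flagged_folds = flagged)
}
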