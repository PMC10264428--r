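#' Confusion matrix for REM-vs-wake epoch classification
#'
#' REM is the positive class throughout: TP counts epochs correctly scored
#' as REM, TN epochs correctly rejected.
#'
#' @param truth,predicted label vectors.
#' @param positive positive-class label (default `"REM"`).
#' @return Object of class `confusion_matrix`: list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_matrix <- function(truth, predicted, positive = "REM") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted), length(truth) > 0)
  tpos <- truth == positive
  ppos <- predicted == positive
  structure(
    list(TP = sum(tpos & ppos), FP = sum(!tpos & ppos),
         TN = sum(!tpos & !ppos), FN = sum(tpos & !ppos),
         positive = positive),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive = %s\n", x$positive))
  print(matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
               dimnames = list(truth = c(x$positive, "other"),
                               predicted = c(x$positive, "other"))))
  invisible(x)
}

#' Accuracy, sensitivity and specificity (percent)
#'
#' `accuracy = 100 (TP+TN)/(TP+FP+TN+FN)`, `sensitivity = 100 TP/(TP+FN)`,
#' `specificity = 100 TN/(TN+FP)`. A ratio with a zero denominator is
#' reported as `NA` (flagged undefined), never silently 0.
#'
#' @param cm a [confusion_matrix()].
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   in percent.
#' @export
cm_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  if (total == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(accuracy = 100 * (cm$TP + cm$TN) / total,
    sensitivity = ratio(cm$TP, cm$TP + cm$FN),
    specificity = ratio(cm$TN, cm$TN + cm$FP))
}

# resolve a classifier spec into a fit/predict pair
classifier_funs <- function(spec) {
  if (is.function(spec)) return(spec)
  spec <- match.arg(spec, c("kernel_nbc", "gaussian_nbc", "qda", "knn"))
  switch(spec,
    kernel_nbc = function(x_train, y_train, x_test) {
      m <- fit_kernel_nbc(x_train, y_train, mode = "kernel")
      p <- predict_proba(m, x_test)
      list(labels = m$classes[max.col(p, ties.method = "first")],
           posterior = p)
    },
    gaussian_nbc = function(x_train, y_train, x_test) {
      m <- fit_kernel_nbc(x_train, y_train, mode = "gaussian")
      p <- predict_proba(m, x_test)
      list(labels = m$classes[max.col(p, ties.method = "first")],
           posterior = p)
    },
    qda = function(x_train, y_train, x_test) {
      fit_predict_comparators(x_train, y_train, x_test, "qda")
    },
    knn = function(x_train, y_train, x_test) {
      fit_predict_comparators(x_train, y_train, x_test, "knn")
    }
  )
}

#' Repeated shuffled split evaluation
#'
#' The evaluation protocol for epoch classification: the pooled epochs are
#' randomly split into 75% training / 25% test, the classifier is fitted
#' and tested, and the whole procedure is repeated over `n_shuffles`
#' independent shuffles (1000 in the full protocol). Splits are
#' unstratified by default, matching a plain random split of the data
#' points; a shuffle whose training or test split lacks a class is redrawn
#' (and counted). Only rows labelled with one of `keep_classes` enter the
#' protocol, REM being the positive class.
#'
#' @param x feature matrix (or [extract_features()] result).
#' @param y labels (taken from `x` when it is a `feature_matrix`).
#' @param classifier classifier spec: `"kernel_nbc"` (default),
#'   `"gaussian_nbc"`, `"qda"`, `"knn"`, or a function
#'   `f(x_train, y_train, x_test)` returning `list(labels, posterior)`.
#' @param n_shuffles number of random splits.
#' @param train_fraction fraction of epochs in the training split.
#' @param seed integer; per-shuffle RNG streams derive deterministically
#'   from it.
#' @param keep_classes classes entering the binary task (default WAKE/REM).
#' @param positive positive class for the confusion matrix.
#' @param stratified preserve class proportions in the split (off by
#'   default).
#' @return Object of class `evaluation_report`: list with `per_shuffle`
#'   (data frame of accuracy/sensitivity/specificity per shuffle, percent),
#'   `mean`, `sd`, `pooled_confusion` (summed over shuffles), `redraws`,
#'   and `meta`.
#' @export
repeated_evaluation <- function(x, y = NULL, classifier = "kernel_nbc",
                                n_shuffles = 1000L, train_fraction = 0.75,
                                seed = 1L,
                                keep_classes = c("WAKE", "REM"),
                                positive = "REM", stratified = FALSE) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$labels
    x <- x$values
  }
  x <- as.matrix(x); y <- as.character(y)
  stopifnot(nrow(x) == length(y), n_shuffles >= 1L,
            train_fraction > 0, train_fraction < 1)
  sel <- y %in% keep_classes
  x <- x[sel, , drop = FALSE]; y <- y[sel]
  if (length(unique(y)) < 2L) {
    stop("need both classes present among kept epochs (",
         paste(keep_classes, collapse = ", "), ")")
  }
  fit_predict <- classifier_funs(classifier)
  n <- nrow(x)
  n_train <- floor(n * train_fraction)
  if (n_train < 2L || n_train >= n) stop("degenerate split sizes")

  set.seed(as.integer(seed))
  shuffle_seeds <- sample.int(.Machine$integer.max - 1L, n_shuffles)
  res <- matrix(NA_real_, n_shuffles, 3L,
                dimnames = list(NULL, c("accuracy", "sensitivity", "specificity")))
  pooled <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  redraws <- 0L
  draw_split <- function() {
    if (stratified) {
      tr <- unlist(lapply(split(seq_len(n), y), function(ix) {
        sample(ix, max(1L, round(length(ix) * train_fraction)))
      }), use.names = FALSE)
    } else {
      tr <- sample.int(n, n_train)
    }
    tr
  }
  for (s in seq_len(n_shuffles)) {
    set.seed(shuffle_seeds[s])
    repeat {
      tr <- draw_split()
      ok <- length(unique(y[tr])) == 2L && min(table(y[tr])) >= 2L &&
        length(unique(y[-tr])) == 2L
      if (ok) break
      redraws <- redraws + 1L
      if (redraws > 100L * n_shuffles) stop("cannot draw a split containing both classes")
    }
    pred <- fit_predict(x[tr, , drop = FALSE], y[tr], x[-tr, , drop = FALSE])
    cm <- confusion_matrix(y[-tr], pred$labels, positive)
    res[s, ] <- cm_metrics(cm)
    pooled <- pooled + c(TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN)
  }
  per_shuffle <- as.data.frame(res)
  structure(
    list(per_shuffle = per_shuffle,
         mean = colMeans(res, na.rm = TRUE),
         sd = apply(res, 2L, stats::sd, na.rm = TRUE),
         pooled_confusion = pooled,
         redraws = redraws,
         meta = list(classifier = if (is.function(classifier)) "custom" else classifier,
                     n_shuffles = n_shuffles, train_fraction = train_fraction,
                     seed = as.integer(seed), n_epochs = n,
                     class_counts = as.list(table(y)),
                     positive = positive, stratified = stratified)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, %d shuffles, %d epochs\n",
              x$meta$classifier, x$meta$n_shuffles, x$meta$n_epochs))
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %6.2f +/- %.2f %%\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over all observed positive-class scores and
#' reports the true/false positive ratios, with the area under the curve by
#' the trapezoid rule. The AUC equals the concordance probability (the
#' normalized Mann-Whitney U statistic), with ties counted half.
#'
#' @param scores numeric scores for the positive class (e.g. posterior REM
#'   probability).
#' @param truth labels.
#' @param positive positive class (default `"REM"`).
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_and_auc <- function(scores, truth, positive = "REM") {
  truth <- as.character(truth)
  stopifnot(length(scores) == length(truth))
  pos <- truth == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs both positive and negative epochs")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Single-band ablation by false-negative ratio
#'
#' Feeds the classifier one frequency band at a time and reports the mean
#' false-negative ratio (`FNR = 100 - sensitivity`) for REM detection under
#' the repeated-split protocol. Bands that do not separate REM from
#' wakefulness drive the classifier to the majority class, pushing the FNR
#' towards 100% when REM is the rare class; discriminative bands keep the
#' FNR low.
#'
#' @param x feature matrix (columns = bands) or `feature_matrix`.
#' @param y labels.
#' @param bands columns to ablate over (indices or names; default all).
#' @param ... passed to [repeated_evaluation()] (classifier, n_shuffles,
#'   seed, ...).
#' @return Data frame with `band`, `mean_fnr`, `sd_fnr`, `mean_sensitivity`.
#' @export
band_ablation_fnr <- function(x, y = NULL, bands = NULL, ...) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$labels
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(bands)) bands <- colnames(x)
  if (is.null(bands)) bands <- seq_len(ncol(x))
  out <- data.frame(band = as.character(bands),
                    mean_fnr = NA_real_, sd_fnr = NA_real_,
                    mean_sensitivity = NA_real_)
  for (i in seq_along(bands)) {
    rr <- repeated_evaluation(x[, bands[i], drop = FALSE], y, ...)
    sens <- rr$per_shuffle$sensitivity
    fnr <- 100 - sens
    out$mean_fnr[i] <- mean(fnr, na.rm = TRUE)
    out$sd_fnr[i] <- stats::sd(fnr, na.rm = TRUE)
    out$mean_sensitivity[i] <- mean(sens, na.rm = TRUE)
  }
  out
}

#' Hourly power/state Pearson correlations
#'
#' For each band, correlates the hourly mean z-scored band power with the
#' hourly percentage of wakefulness and of REM sleep: Pearson r, Fisher-z
#' 95% confidence interval, R-squared and the two-tailed p from the
#' t-distribution with n-2 degrees of freedom. Normality of each series is
#' screened with the Shapiro-Wilk test first; failure produces a warning,
#' not a hard stop.
#'
#' @param summary an [hourly_summary()] data frame.
#' @param states which percentage columns to correlate against.
#' @param shapiro_alpha screening level for the normality warning.
#' @return Data frame with one row per band x state: `band`, `state`, `r`,
#'   `ci_low`, `ci_high`, `r_squared`, `p`, `n`.
#' @export
hourly_correlation <- function(summary, states = c("WAKE", "REM"),
                               shapiro_alpha = 0.05) {
  band_cols <- setdiff(colnames(summary),
                       c("hour", "hour_of_day", "pct_wake", "pct_rem"))
  n <- nrow(summary)
  if (n < 3L) stop("need at least 3 hourly bins")
  state_col <- c(WAKE = "pct_wake", REM = "pct_rem")
  rows <- list()
  for (st in states) {
    yv <- summary[[state_col[[st]]]]
    for (b in band_cols) {
      xv <- summary[[b]]
      if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
        stop("zero variance in hourly series for band ", b, " / state ", st)
      }
      for (series in list(xv, yv)) {
        swp <- tryCatch(stats::shapiro.test(series)$p.value, error = function(e) NA_real_)
        if (is.finite(swp) && swp < shapiro_alpha) {
          warning("hourly series for ", b, " x ", st,
                  " fails Shapiro-Wilk normality screen (p = ",
                  format(swp, digits = 3), ")", call. = FALSE)
          break
        }
      }
      r <- sum((xv - mean(xv)) * (yv - mean(yv))) /
        sqrt(sum((xv - mean(xv))^2) * sum((yv - mean(yv))^2))
      tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
      se <- 1 / sqrt(n - 3)
      ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
      rows[[length(rows) + 1L]] <- data.frame(
        band = b, state = st, r = r, ci_low = ci[1], ci_high = ci[2],
        r_squared = r^2, p = p, n = n
      )
    }
  }
  do.call(rbind, rows)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. For small samples (both
#' groups at most `exact_max`) the two-tailed p comes from full enumeration
#' of the permutation distribution of U (valid under ties); otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max enumeration cutoff per group.
#' @return List with `U` (statistic for `x`), `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    # two-tailed: double the smaller tail (capped at 1)
    p <- min(1, 2 * min(mean(u_all <= U + 1e-9), mean(u_all >= U - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n1 + n2 + 1 - tie_term))
    if (sigma == 0) stop("all observations tied; U distribution degenerate")
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p = p, method = method)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether the median of `x` equals `mu` (default 100, the reference
#' value for the false-negative-ratio ablation: a band whose FNR does not
#' differ from 100 carries no REM information). Zero differences are
#' dropped; if all differences are zero the statistic is undefined and an
#' error is raised. Exact enumeration of the 2^n sign assignments for n at
#' most `exact_max`, tie-corrected normal approximation otherwise.
#'
#' @param x numeric sample.
#' @param mu hypothetical median.
#' @param exact_max enumeration cutoff.
#' @return List with `V` (positive-rank sum), `p`, `n_used`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, mu = 100, exact_max = 15L) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all observations equal the hypothetical median; signed-rank statistic undefined")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # enumerate all sign assignments; ties in |d| are handled because the
    # rank vector is fixed
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(v_all <= V + 1e-9), mean(v_all >= V - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu_v <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    if (sigma == 0) stop("degenerate signed-rank distribution")
    z <- (V - mu_v - sign(V - mu_v) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(V = V, p = p, n_used = n, method = method)
}
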