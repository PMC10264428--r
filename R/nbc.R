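# Silverman's rule-of-thumb bandwidth with a floor for degenerate spreads.
silverman_bandwidth <- function(x, floor_scale) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  h <- 0.9 * spread * n^(-1 / 5)
  floor_h <- 1e-6 * max(floor_scale, 1e-12)
  if (!is.finite(h) || h < floor_h) floor_h else h
}

#' Fit a kernel naive-Bayes classifier
#'
#' Naive Bayes under the hypothesis of conditionally independent features:
#' per class and per feature, the class-conditional density is a
#' one-dimensional Gaussian-kernel density estimate over the training values
#' (`mode = "kernel"`, the default) or a Gaussian fit (`mode = "gaussian"`).
#' Bandwidths follow Silverman's rule, `0.9 min(SD, IQR/1.34) n^{-1/5}`,
#' floored at `1e-6` of the feature range for degenerate spreads. Priors are
#' the empirical class frequencies by default; with heavily imbalanced
#' classes (REM is ~5% of a day) this choice matters, so `priors = "uniform"`
#' is available.
#'
#' @param x numeric matrix (rows = epochs, columns = features) or a
#'   [extract_features()] result.
#' @param y class labels, one per row.
#' @param mode `"kernel"` or `"gaussian"` class-conditional densities.
#' @param priors `"empirical"`, `"uniform"`, or a named numeric vector
#'   summing to 1.
#' @param bandwidth optional fixed bandwidth (scalar) overriding Silverman's
#'   rule for every class/feature.
#' @return Object of class `kernel_nbc`.
#' @export
fit_kernel_nbc <- function(x, y, mode = c("kernel", "gaussian"),
                           priors = "empirical", bandwidth = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "feature_matrix")) {
    if (missing(y)) y <- x$labels
    x <- x$values
  }
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training data must contain at least two classes")
  counts <- table(factor(y, classes))
  if (any(counts < 2L)) stop("each class needs at least two training samples")
  if (anyNA(x)) stop("training features contain NA")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))

  if (identical(priors, "empirical")) {
    pr <- as.numeric(counts) / length(y)
  } else if (identical(priors, "uniform")) {
    pr <- rep(1 / length(classes), length(classes))
  } else {
    stopifnot(is.numeric(priors), abs(sum(priors) - 1) < 1e-9)
    pr <- as.numeric(priors[classes])
  }
  names(pr) <- classes

  ranges <- apply(x, 2L, function(v) diff(range(v)))
  densities <- lapply(classes, function(cl) {
    xs <- x[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(x)), function(j) {
      v <- xs[, j]
      if (mode == "kernel") {
        h <- if (is.null(bandwidth)) silverman_bandwidth(v, ranges[j]) else bandwidth
        list(type = "kernel", points = sort(v), bandwidth = h)
      } else {
        s <- stats::sd(v)
        floor_s <- 1e-6 * max(ranges[j], 1e-12)
        list(type = "gaussian", mean = mean(v), sd = max(s, floor_s))
      }
    })
  })
  names(densities) <- classes
  structure(
    list(classes = classes, priors = pr, densities = densities,
         feature_names = colnames(x), mode = mode),
    class = "kernel_nbc"
  )
}

#' @export
print.kernel_nbc <- function(x, ...) {
  cat(sprintf("<kernel_nbc> %s densities, %d classes (%s), %d features\n",
              x$mode, length(x$classes),
              paste(sprintf("%s %.3f", x$classes, x$priors), collapse = ", "),
              length(x$feature_names)))
  invisible(x)
}

# log density of one class-conditional feature model at values v,
# floored at log(1e-300) so a single far-out feature cannot send the
# whole log posterior to -Inf
.LOG_DENS_FLOOR <- log(1e-300)

eval_log_density <- function(d, v) {
  dens <- if (d$type == "kernel") {
    kde_gauss(v, d$points, d$bandwidth)
  } else {
    stats::dnorm(v, d$mean, d$sd)
  }
  pmax(log(pmax(dens, 0)), .LOG_DENS_FLOOR)
}

#' Posterior class probabilities from a kernel NBC
#'
#' Accumulates `log prior + sum_j log density_cj(x_j)` in log space and
#' normalizes rows with log-sum-exp, so the computation is stable for
#' feature magnitudes up to at least 1e6.
#'
#' @param model a [fit_kernel_nbc()] fit.
#' @param x numeric matrix of feature rows (or `feature_matrix`).
#' @return Matrix of posterior probabilities, one column per class; rows sum
#'   to 1.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "kernel_nbc"))
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  if (ncol(x) != length(model$feature_names)) {
    stop("model expects ", length(model$feature_names), " features, got ", ncol(x))
  }
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop("NA feature value at epoch row ", idx[1L], ", feature '",
         model$feature_names[idx[2L]], "'")
  }
  logpost <- matrix(0, nrow(x), length(model$classes),
                    dimnames = list(NULL, model$classes))
  for (ci in seq_along(model$classes)) {
    cl <- model$classes[ci]
    lp <- if (model$priors[[cl]] > 0) log(model$priors[[cl]]) else -Inf
    acc <- rep(lp, nrow(x))
    if (is.finite(lp)) {
      for (j in seq_len(ncol(x))) {
        acc <- acc + eval_log_density(model$densities[[cl]][[j]], x[, j])
      }
    }
    logpost[, ci] <- acc
  }
  mx <- apply(logpost, 1L, max)
  p <- exp(logpost - mx)
  p / rowSums(p)
}

#' Predict class labels
#'
#' @param object a `kernel_nbc` model.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return Character vector of predicted labels (posterior argmax; ties go
#'   to the first class in sorted order).
#' @export
predict.kernel_nbc <- function(object, newdata, ...) {
  p <- predict_proba(object, newdata)
  object$classes[max.col(p, ties.method = "first")]
}

#' Serialize / restore a kernel NBC model as JSON
#'
#' @param model a `kernel_nbc` fit.
#' @param path file path.
#' @return `write_nbc_json` invisibly returns `path`; `read_nbc_json`
#'   returns the restored model.
#' @export
write_nbc_json <- function(model, path) {
  stopifnot(inherits(model, "kernel_nbc"))
  jsonlite::write_json(
    list(classes = model$classes, priors = as.list(model$priors),
         mode = model$mode, feature_names = model$feature_names,
         densities = model$densities),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_nbc_json
#' @export
read_nbc_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  dens <- lapply(raw$densities, function(per_class) {
    lapply(per_class, function(d) {
      d$type <- as.character(d$type)
      if (d$type == "kernel") d$points <- as.numeric(d$points)
      d
    })
  })
  structure(
    list(classes = as.character(raw$classes),
         priors = unlist(raw$priors)[as.character(raw$classes)],
         densities = dens, feature_names = as.character(raw$feature_names),
         mode = raw$mode),
    class = "kernel_nbc"
  )
}
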