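#' Comparator classifiers: QDA and k-NN
#'
#' Reference classifiers used to check that the features, not the
#' classifier, carry the discrimination. QDA fits a full-covariance
#' Gaussian per class and applies the closed-form quadratic discriminant
#' (singular covariances are ridge-regularized with a logged epsilon); k-NN
#' uses Euclidean distance with `k = 5` by default, breaking vote ties in
#' favour of the nearest neighbour's label and distance ties in favour of
#' the lower training index. A support-vector machine is deliberately not
#' re-implemented; no SVM backend ships with this package's dependency set,
#' so `method = "svm"` signals an error explaining that.
#'
#' @param x_train,y_train training features and labels.
#' @param x_test features to classify.
#' @param method `"qda"` or `"knn"` (`"svm"` errors, see above).
#' @param k neighbourhood size for k-NN.
#' @return List with `labels` (predicted classes for `x_test`) and, for QDA,
#'   `posterior` (normalized class probabilities).
#' @export
fit_predict_comparators <- function(x_train, y_train, x_test,
                                    method = c("qda", "knn", "svm"), k = 5L) {
  method <- match.arg(method)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- as.character(y_train)
  stopifnot(nrow(x_train) == length(y_train), ncol(x_train) == ncol(x_test))
  switch(method,
    qda = qda_fit_predict(x_train, y_train, x_test),
    knn = knn_predict(x_train, y_train, x_test, k),
    svm = stop("no SVM backend is available in this package's dependencies; ",
               "use method 'qda' or 'knn', or an external SVM on the ",
               "exported feature CSV")
  )
}

qda_fit_predict <- function(x_train, y_train, x_test) {
  classes <- sort(unique(y_train))
  d <- ncol(x_train)
  fits <- lapply(classes, function(cl) {
    xs <- x_train[y_train == cl, , drop = FALSE]
    if (nrow(xs) < 2L) stop("QDA needs >= 2 samples per class")
    mu <- colMeans(xs)
    S <- stats::cov(xs)
    eps <- 0
    ch <- tryCatch(chol(S), error = function(e) NULL)
    while (is.null(ch)) {
      eps <- if (eps == 0) 1e-8 * mean(diag(S) + 1e-300) else eps * 10
      ch <- tryCatch(chol(S + diag(eps, d)), error = function(e) NULL)
      if (eps > 1e6) stop("class covariance irreparably singular in QDA")
    }
    if (eps > 0) {
      message("QDA: ridge-regularized covariance of class '", cl,
              "' with epsilon ", format(eps))
    }
    list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))),
         prior = mean(y_train == cl))
  })
  names(fits) <- classes
  disc <- vapply(fits, function(f) {
    z <- backsolve(f$chol, t(x_test) - f$mu, transpose = TRUE)
    -0.5 * f$logdet - 0.5 * colSums(z^2) + log(f$prior)
  }, numeric(nrow(x_test)))
  disc <- matrix(disc, nrow = nrow(x_test),
                 dimnames = list(NULL, classes))
  mx <- apply(disc, 1L, max)
  post <- exp(disc - mx)
  post <- post / rowSums(post)
  list(labels = classes[max.col(disc, ties.method = "first")], posterior = post)
}

knn_predict <- function(x_train, y_train, x_test, k) {
  k <- min(as.integer(k), nrow(x_train))
  stopifnot(k >= 1L)
  n_test <- nrow(x_test)
  labels <- character(n_test)
  tr_sq <- rowSums(x_train^2)
  chunk <- 512L
  for (start in seq(1L, n_test, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_test)
    xt <- x_test[idx, , drop = FALSE]
    # squared Euclidean distances, test chunk x train
    D <- outer(rowSums(xt^2), tr_sq, "+") - 2 * tcrossprod(xt, x_train)
    for (r in seq_along(idx)) {
      # order() is stable, so distance ties resolve to the lower index
      nn <- order(D[r, ])[seq_len(k)]
      votes <- table(y_train[nn])
      top <- names(votes)[votes == max(votes)]
      labels[idx[r]] <- if (length(top) == 1L) top else {
        # vote tie: the nearest neighbour among tied classes decides
        y_train[nn[y_train[nn] %in% top][1L]]
      }
    }
  }
  list(labels = labels)
}
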