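# Shared fixtures: everything is generated in code at test time.

# a short-duration simulation config for desk-scale tests
small_cfg <- function(duration_hours = 0.25, seed = 11L, ...) {
  sim_config(duration_hours = duration_hours, seed = seed, ...)
}

# binary Gaussian feature sets: REM shifted by `sep` SDs in `shift_cols`
make_gauss_features <- function(n = 400, d = 4, sep = 2, rem_frac = 0.05,
                                shift_cols = seq_len(d), seed = 1) {
  set.seed(seed)
  y <- ifelse(runif(n) < rem_frac, "REM", "WAKE")
  # guarantee both classes are usable in any 75/25 split
  if (sum(y == "REM") < 4) y[sample.int(n, 4)] <- "REM"
  if (sum(y == "WAKE") < 4) y[sample.int(n, 4)] <- "WAKE"
  x <- matrix(rnorm(n * d), n, d)
  x[y == "REM", shift_cols] <- x[y == "REM", shift_cols] - sep
  colnames(x) <- paste0("b", seq_len(d))
  list(x = x, y = y)
}

# Brute-force naive-Bayes oracle: direct per-point kernel sums in plain R,
# same Silverman bandwidths and density floor as the model contract, but an
# independent computation path (no log-space accumulation).
oracle_silverman <- function(v, floor_scale) {
  n <- length(v)
  s <- sd(v)
  iqr <- IQR(v) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  h <- 0.9 * spread * n^(-1 / 5)
  fl <- 1e-6 * max(floor_scale, 1e-12)
  if (!is.finite(h) || h < fl) fl else h
}

oracle_nbc_posterior <- function(x_train, y_train, x_test,
                                 priors = "empirical", bandwidth = NULL) {
  classes <- sort(unique(y_train))
  ranges <- apply(x_train, 2, function(v) diff(range(v)))
  pr <- if (identical(priors, "empirical")) {
    sapply(classes, function(cl) mean(y_train == cl))
  } else rep(1 / length(classes), length(classes))
  names(pr) <- classes
  post <- matrix(NA_real_, nrow(x_test), length(classes),
                 dimnames = list(NULL, classes))
  for (r in seq_len(nrow(x_test))) {
    logp <- sapply(classes, function(cl) {
      acc <- log(pr[[cl]])
      for (j in seq_len(ncol(x_train))) {
        tv <- x_train[y_train == cl, j]
        h <- if (is.null(bandwidth)) oracle_silverman(tv, ranges[j]) else bandwidth
        dens <- mean(dnorm((x_test[r, j] - tv) / h)) / h
        acc <- acc + max(log(max(dens, 0)), log(1e-300))
      }
      acc
    })
    p <- exp(logp - max(logp))
    post[r, ] <- p / sum(p)
  }
  post
}

# Independent iterative Grubbs implementation (index bookkeeping via which())
oracle_grubbs_indices <- function(x, alpha = 0.05) {
  flagged <- logical(length(x))
  repeat {
    idx <- which(!flagged)
    n <- length(idx)
    if (n < 3) break
    v <- x[idx]
    s <- sd(v)
    if (!is.finite(s) || s == 0) break
    G <- max(abs(v - mean(v))) / s
    tcr <- qt(1 - alpha / (2 * n), n - 2)
    crit <- (n - 1) / sqrt(n) * sqrt(tcr^2 / (n - 2 + tcr^2))
    if (G <= crit) break
    flagged[idx[which.max(abs(v - mean(v)))]] <- TRUE
  }
  which(flagged)
}
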