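#' k-means classifier specification
#'
#' Parameters of the unsupervised classifier: 2 final clusters,
#' initial centroids chosen as 2 random training observations, 30
#' replicates (best by within-cluster L1 dispersion), and L1 distance
#' for centroid assignment. Centroid updates use the component-wise
#' median, the L1-optimal centre.
#'
#' @param n_replicates number of random restarts, default 30.
#' @param max_iter maximum Lloyd iterations per restart.
#' @return A list of class `kmeans_spec` (k is fixed at 2).
#' @export
kmeans_spec <- function(n_replicates = 30, max_iter = 100) {
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  structure(list(k = 2L, n_replicates = as.integer(n_replicates),
                 max_iter = as.integer(max_iter)),
            class = "kmeans_spec")
}

# L1 (city-block) k-means: random-observation init, L1 assignment,
# component-wise median update, best of n_replicates by total L1
# dispersion. Caller controls the RNG state.
l1_kmeans <- function(X, k = 2L, n_replicates = 30L, max_iter = 100L) {
  n <- nrow(X)
  if (n < k) stop("need at least k training points")
  l1_dist <- function(X, centroids) {
    vapply(seq_len(nrow(centroids)),
           function(j) rowSums(abs(X - matrix(centroids[j, ], n, ncol(X), byrow = TRUE))),
           numeric(n))
  }
  best <- NULL
  for (rep in seq_len(n_replicates)) {
    centroids <- X[sample.int(n, k), , drop = FALSE]
    assign_old <- integer(n)
    for (it in seq_len(max_iter)) {
      D <- l1_dist(X, centroids)
      assign <- max.col(-D, ties.method = "first")
      # re-seed an emptied cluster with the worst-fitted point
      for (j in seq_len(k)) {
        if (!any(assign == j)) {
          far <- which.max(D[cbind(seq_len(n), assign)])
          centroids[j, ] <- X[far, ]
          assign[far] <- j
        }
      }
      if (identical(assign, assign_old)) break
      assign_old <- assign
      for (j in seq_len(k))
        centroids[j, ] <- apply(X[assign == j, , drop = FALSE], 2, median)
    }
    D <- l1_dist(X, centroids)
    assign <- max.col(-D, ties.method = "first")
    dispersion <- sum(D[cbind(seq_len(n), assign)])
    if (is.null(best) || dispersion < best$dispersion)
      best <- list(centroids = centroids, cluster = assign,
                   dispersion = dispersion)
  }
  best
}

# Ridge-penalized logistic regression via IRLS; fallback when maximum
# likelihood diverges under complete separation.
ridge_logistic <- function(Xd, y, lambda = 0.05, max_iter = 50L) {
  p <- ncol(Xd)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(Xd, w * Xd) + pen, crossprod(Xd, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  beta
}

# Normalize the outcome to logical (TRUE = positive class).
as_outcome <- function(y, positive = "NR") {
  if (is.logical(y)) return(y)
  if (is.factor(y)) y <- as.character(y)
  y == positive
}

# Training-fold preprocessing: optional natural-log transform (with a
# data-driven positivity offset) followed by z-scoring; constant
# features are dropped with a warning. Returns the transform and the
# transformed matrix.
fit_preprocess <- function(x, log_features = NULL) {
  x <- data.matrix(x)
  offsets <- setNames(rep(NA_real_, ncol(x)), colnames(x))
  for (f in intersect(log_features, colnames(x))) {
    mn <- min(x[, f])
    offsets[f] <- if (mn > 0) 0 else 1 - mn
    x[, f] <- log(x[, f] + offsets[f])
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    if (!any(keep)) stop("all features are constant")
  }
  list(offsets = offsets, center = ctr, scale = ifelse(keep, scl, 1),
       keep = keep,
       z = scale(x, center = ctr, scale = ifelse(keep, scl, 1))[, keep, drop = FALSE])
}

apply_preprocess <- function(prep, x) {
  x <- data.matrix(x)
  for (f in names(prep$offsets)[!is.na(prep$offsets)])
    x[, f] <- log(pmax(x[, f] + prep$offsets[f], .Machine$double.eps))
  scale(x, center = prep$center, scale = prep$scale)[, prep$keep, drop = FALSE]
}

#' Fit a non-response classifier
#'
#' Fits one of the two multi-parametric classifiers of the pipeline to a
#' feature matrix and a binary outcome (positive class = non-responder):
#'
#' * `"logistic"` — maximum-likelihood logistic regression of
#'   P(NR | x) with intercept; under complete separation (non-converged
#'   IRLS or fitted probabilities collapsing to 0/1) a ridge-penalized
#'   fit is substituted with a warning. Prediction is NR when the fitted
#'   probability is >= 0.5.
#' * `"kmeans"` — unsupervised 2-cluster L1 k-means on the training
#'   features (see [kmeans_spec()]); each cluster is labelled by the
#'   majority outcome of its training members (ties toward NR, the
#'   sensitivity priority), and a new observation takes the label of its
#'   L1-nearest centroid.
#'
#' Features are preprocessed on the training data only: optional
#' natural-log transform (with an automatic positivity offset) and
#' z-scoring, the latter mandatory for the k-means classifier since L1
#' distances mix units.
#'
#' @param x data.frame or matrix of numeric features.
#' @param y outcome: logical (TRUE = positive) or a vector of class
#'   labels in which `positive` marks the positive class.
#' @param method `"logistic"` or `"kmeans"`.
#' @param spec a [kmeans_spec()] (k-means only).
#' @param log_features names of features to log-transform.
#' @param positive label of the positive class, default `"NR"`.
#' @param seed integer seed (k-means initialization).
#' @return An object of class `nr_model` with a [predict][predict.nr_model]
#'   method.
#' @export
nr_model <- function(x, y, method = c("logistic", "kmeans"),
                     spec = kmeans_spec(), log_features = NULL,
                     positive = "NR", seed = NULL) {
  method <- match.arg(method)
  pos <- as_outcome(y, positive)
  if (length(pos) != nrow(as.data.frame(x))) stop("`x` and `y` sizes differ")
  if (sum(pos) < 1L || sum(!pos) < 1L)
    stop("both outcome classes must be present in training data")
  if (method == "logistic" && (sum(pos) < 2L || sum(!pos) < 2L))
    stop("logistic fit needs at least 2 patients per class")
  prep <- fit_preprocess(x, log_features)
  z <- prep$z
  fit <- if (method == "logistic") {
    Xd <- cbind(`(Intercept)` = 1, z)
    sep <- FALSE
    g <- withCallingHandlers(
      glm.fit(Xd, as.numeric(pos), family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (sep || !g$converged) {
      warning("separation detected: falling back to ridge-penalized logistic fit")
      list(coef = ridge_logistic(Xd, as.numeric(pos)), ridge = TRUE)
    } else list(coef = g$coefficients, ridge = FALSE)
  } else {
    km <- with_seed(seed, l1_kmeans(z, k = spec$k,
                                    n_replicates = spec$n_replicates,
                                    max_iter = spec$max_iter))
    lab <- vapply(seq_len(spec$k), function(j) {
      members <- pos[km$cluster == j]
      sum(members) >= sum(!members)          # tie -> positive class
    }, logical(1))
    if (all(lab) || all(!lab))
      warning("both clusters map to the same class; classifier is constant")
    list(centroids = km$centroids, cluster_positive = lab,
         dispersion = km$dispersion, cluster = km$cluster)
  }
  structure(list(method = method, fit = fit, prep = prep,
                 features = colnames(prep$z), positive = positive,
                 spec = spec, n = length(pos), n_pos = sum(pos)),
            class = "nr_model")
}

#' Predict from a non-response classifier
#'
#' @param object an [nr_model()].
#' @param newdata data.frame or matrix containing the model's features.
#' @param type `"class"` (default) for predicted labels, `"prob"` for
#'   the fitted positive-class probability (logistic only).
#' @param ... unused.
#' @return Logical vector (`TRUE` = predicted positive/NR) for
#'   `type = "class"`, numeric probabilities for `type = "prob"`.
#' @export
predict.nr_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  z <- apply_preprocess(object$prep, newdata)
  if (object$method == "logistic") {
    eta <- drop(cbind(1, z) %*% object$fit$coef)
    prob <- 1 / (1 + exp(-eta))
    if (type == "prob") return(prob)
    return(prob >= 0.5)
  }
  if (type == "prob") stop("the k-means classifier has no probability output")
  cent <- object$fit$centroids
  D <- vapply(seq_len(nrow(cent)),
              function(j) rowSums(abs(z - matrix(cent[j, ], nrow(z), ncol(z),
                                                 byrow = TRUE))),
              numeric(nrow(z)))
  D <- matrix(D, nrow = nrow(z))
  object$fit$cluster_positive[max.col(-D, ties.method = "first")]
}

#' @export
print.nr_model <- function(x, ...) {
  cat(sprintf("<nr_model:%s> %d features (%s), %d patients (%d %s)\n",
              x$method, length(x$features),
              paste(x$features, collapse = ", "), x$n, x$n_pos, x$positive))
  if (x$method == "logistic") {
    cat(if (x$fit$ridge) "  ridge-penalized coefficients:\n" else "  coefficients:\n")
    print(round(x$fit$coef, 4))
  } else {
    cat(sprintf("  cluster -> %s mapping: %s\n", x$positive,
                paste(ifelse(x$fit$cluster_positive, x$positive, "other"),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' Evaluates a feature subset with a classifier by leave-one-out
#' cross-validation: each patient is predicted by a model trained on all
#' the others, with all preprocessing (log transforms, standardization)
#' re-estimated on each training fold so no information from the held-out
#' patient leaks into its own prediction. Sensitivity is the percentage
#' of non-responders predicted NR, specificity the percentage of
#' responders (PR+CR) predicted responder, accuracy the raw percentage
#' correct.
#'
#' @param data data.frame with the outcome column and the features.
#' @param features character vector of feature column names.
#' @param method `"logistic"` or `"kmeans"`.
#' @param outcome name of the outcome column (values compared against
#'   `positive`), default `"response"`.
#' @param spec a [kmeans_spec()].
#' @param log_features names of features to log-transform (per fold).
#' @param positive positive class label, default `"NR"`.
#' @param seed master seed; per-fold k-means streams are derived from it.
#' @return An object of class `nr_cv`: `se`, `sp`, `accuracy` (percent),
#'   `confusion` (2x2 table), `predictions` (data.frame), `features`,
#'   `method`.
#' @export
loocv <- function(data, features, method = c("logistic", "kmeans"),
                  outcome = "response", spec = kmeans_spec(),
                  log_features = NULL, positive = "NR", seed = NULL) {
  method <- match.arg(method)
  if (!length(features)) stop("empty feature subset")
  missing_cols <- setdiff(c(features, outcome), names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  x <- data[features]
  if (any(!complete.cases(x)))
    stop("missing values in selected features (rows ",
         paste(which(!complete.cases(x)), collapse = ", "), ")")
  truth <- as_outcome(data[[outcome]], positive)
  n <- length(truth)
  if (sum(truth) == 0 || sum(!truth) == 0) stop("both classes must be present")
  fold_seeds <- if (is.null(seed)) rep(list(NULL), n)
  else with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
  pred <- logical(n)
  for (i in seq_len(n)) {
    if (sum(truth[-i]) == 0 || sum(!truth[-i]) == 0)
      stop("a training fold contains a single class")
    fit <- nr_model(x[-i, , drop = FALSE], truth[-i], method = method,
                    spec = spec, log_features = log_features,
                    seed = fold_seeds[[i]])
    pred[i] <- predict(fit, x[i, , drop = FALSE])
  }
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
  structure(list(se = 100 * tp / (tp + fn), sp = 100 * tn / (tn + fp),
                 accuracy = 100 * (tp + tn) / n,
                 confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                                    dimnames = list(predicted = c("NR", "other"),
                                                    truth = c("NR", "other"))),
                 predictions = data.frame(truth = truth, predicted = pred),
                 features = features, method = method, n = n),
            class = "nr_cv")
}

#' @export
print.nr_cv <- function(x, ...) {
  cat(sprintf("<nr_cv:%s> %s\n  Se %.0f%% (%d/%d NR), Sp %.0f%% (%d/%d responders), accuracy %.0f%%\n",
              x$method, paste(x$features, collapse = " + "),
              x$se, x$confusion[1, 1], sum(x$confusion[, 1]),
              x$sp, x$confusion[2, 2], sum(x$confusion[, 2]), x$accuracy))
  invisible(x)
}

#' @export
summary.nr_cv <- function(object, ...) {
  print(object)
  cat("  confusion matrix (LOOCV):\n")
  print(object$confusion)
  invisible(object)
}

#' Permutation null of the LOOCV accuracy
#'
#' Re-runs the leave-one-out evaluation under random permutations of the
#' outcome labels, giving the chance-level distribution of accuracy
#' (which should concentrate near the majority-class proportion). For
#' the k-means classifier this exploits the fact that the clustering
#' depends only on the features: the per-fold cluster assignments are
#' computed once, and each permutation only re-derives the
#' majority-vote cluster labels and the held-out prediction, which makes
#' thousands of permutations cheap while giving exactly the result of a
#' naive re-run with the same per-fold streams.
#'
#' @inheritParams loocv
#' @param n_perm number of label permutations.
#' @return Numeric vector of `n_perm` accuracies (percent), with
#'   attribute `observed` (the unpermuted accuracy).
#' @export
permutation_null <- function(data, features, method = c("logistic", "kmeans"),
                             outcome = "response", spec = kmeans_spec(),
                             n_perm = 1000, positive = "NR", seed = NULL) {
  method <- match.arg(method)
  x <- data[features]
  truth <- as_outcome(data[[outcome]], positive)
  n <- length(truth)
  with_seed(seed, {
    if (method == "kmeans") {
      # cache per-fold geometry once; labels enter only through votes
      folds <- vector("list", n)
      for (i in seq_len(n)) {
        prep <- fit_preprocess(x[-i, , drop = FALSE])
        km <- l1_kmeans(prep$z, k = spec$k, n_replicates = spec$n_replicates,
                        max_iter = spec$max_iter)
        zi <- apply_preprocess(prep, x[i, , drop = FALSE])
        d <- vapply(seq_len(spec$k),
                    function(j) sum(abs(zi - km$centroids[j, ])), numeric(1))
        folds[[i]] <- list(train = seq_len(n)[-i], cluster = km$cluster,
                           test_cluster = which.min(d))
      }
      acc_of <- function(y) {
        correct <- 0L
        for (i in seq_len(n)) {
          f <- folds[[i]]
          members <- f$cluster == f$test_cluster
          yp <- y[f$train][members]
          pred <- sum(yp) >= sum(!yp)        # tie -> positive
          correct <- correct + (pred == y[i])
        }
        100 * correct / n
      }
      observed <- acc_of(truth)
      accs <- vapply(seq_len(n_perm), function(b) acc_of(sample(truth)),
                     numeric(1))
    } else {
      observed <- loocv(data, features, method = method, outcome = outcome,
                        spec = spec, positive = positive)$accuracy
      accs <- vapply(seq_len(n_perm), function(b) {
        d2 <- data
        d2[[outcome]] <- sample(data[[outcome]])
        loocv(d2, features, method = method, outcome = outcome, spec = spec,
              positive = positive)$accuracy
      }, numeric(1))
    }
    attr(accs, "observed") <- observed
    accs
  })
}

#' Exhaustive feature-subset search
#'
#' Evaluates every feature subset of the requested sizes by [loocv()]
#' and ranks the evaluations by accuracy, breaking ties toward higher
#' sensitivity and then toward smaller subsets. The number of
#' evaluations is checked first: beyond `cap` the search refuses and
#' reports the count, unless `override = TRUE` (an exhaustive scan over
#' 2..26 of 26 features is 2^26 - 27 evaluations and must be requested
#' explicitly).
#'
#' @inheritParams loocv
#' @param sizes integer vector of subset sizes (within 2..length(features)).
#' @param cap maximum number of subset evaluations, default 1e6.
#' @param override evaluate regardless of `cap`.
#' @return A data.frame of class `nr_search`, one row per subset, ranked;
#'   columns `subset`, `size`, `se`, `sp`, `accuracy`.
#' @export
subset_search <- function(data, features, sizes = 2:3,
                          method = c("logistic", "kmeans"),
                          outcome = "response", spec = kmeans_spec(),
                          cap = 1e6, override = FALSE, positive = "NR",
                          seed = NULL) {
  method <- match.arg(method)
  p <- length(features)
  if (any(sizes < 2) || any(sizes > p))
    stop("subset sizes must lie within [2, number of features]")
  count <- sum(choose(p, sizes))
  if (count > cap && !override)
    stop(sprintf("%.0f subset evaluations requested (cap %.0f); narrow `sizes` or set override = TRUE",
                 count, cap))
  rows <- vector("list", count)
  k <- 0L
  for (s in sizes) {
    for (cols in as.data.frame(combn(features, s), stringsAsFactors = FALSE)) {
      k <- k + 1L
      cv <- loocv(data, cols, method = method, outcome = outcome, spec = spec,
                  positive = positive, seed = seed)
      rows[[k]] <- data.frame(subset = paste(cols, collapse = "+"),
                              size = s, se = cv$se, sp = cv$sp,
                              accuracy = cv$accuracy,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$accuracy, -out$se, out$size, out$subset), ]
  rownames(out) <- NULL
  class(out) <- c("nr_search", class(out))
  attr(out, "method") <- method
  out
}

#' @export
print.nr_search <- function(x, n = 10, ...) {
  cat(sprintf("<nr_search:%s> %d subsets evaluated by LOOCV; top %d:\n",
              attr(x, "method"), nrow(x), min(n, nrow(x))))
  print.data.frame(head(as.data.frame(x), n), row.names = FALSE)
  invisible(x)
}
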