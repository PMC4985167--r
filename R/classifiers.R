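# Classification backends: Gaussian-kernel soft-margin SVM (SMO dual solver),
# k-nearest-neighbour, probabilistic neural network (Parzen-window densities).
# All backends share min-max feature scaling learned on training data and a
# common predict() contract returning member/non-member calls with scores.

#' Min-max feature scaler
#'
#' Learns a per-feature affine transform mapping the training range to
#' `[0, 1]`. Constant features map to 0. Distance-based backends (kNN, PNN)
#' and the Gaussian kernel require features on comparable scales.
#'
#' @param X numeric training matrix (rows = proteins).
#' @return An object of class `feature_scaler`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stopf("cannot fit a scaler on an empty matrix")
  mins <- apply(X, 2L, min)
  ranges <- apply(X, 2L, max) - mins
  structure(list(min = mins, range = ranges, p = ncol(X)),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a `feature_scaler`.
#' @param newdata numeric matrix or vector with the training dimensionality.
#' @export
apply_scaler <- function(scaler, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != scaler$p)
    stopf("feature dimension mismatch: expected %d, got %d",
          scaler$p, ncol(newdata))
  denom <- ifelse(scaler$range == 0, 1, scaler$range)
  out <- sweep(sweep(newdata, 2L, scaler$min, "-"), 2L, denom, "/")
  out[, scaler$range == 0] <- 0
  out
}

gaussian_kernel <- function(A, B, sigma) {
  exp(-cross_dist2(as.matrix(A), as.matrix(B)) / (2 * sigma^2))
}

check_two_classes <- function(y) {
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stopf("labels must be coded +1 / -1")
  if (length(unique(y)) < 2L)
    stopf("training data must contain both classes")
  y
}

new_model <- function(method, hyper, scaler, state, platt = NULL,
                      config_digest = NULL) {
  structure(list(version = 1L, method = method, hyper = hyper,
                 scaler = scaler, state = state, platt = platt,
                 config_digest = config_digest),
            class = c(paste0("profam_", method), "profam_model"))
}

#' Train a Gaussian-kernel soft-margin SVM
#'
#' Solves the kernel SVM dual by sequential minimal optimization with
#' per-class box constraints: the misclassification cost of class +1 is
#' `cost * class_weights["pos"]` and of class -1 is
#' `cost * class_weights["neg"]`, supporting separate cost optimization for
#' imbalanced families. Kernel: `K(xi, xj) = exp(-||xj - xi||^2 / (2 sigma^2))`.
#' Decision function: `f(x) = sum_i alpha_i y_i K(x_i, x) + b`; a query is a
#' member iff `f(x) > 0` (ties break to non-member).
#'
#' With `platt = TRUE`, a Platt sigmoid `1 / (1 + exp(A f + B))` is fitted to
#' out-of-fold cross-validated decision values of the training set and stored
#' with the model, yielding posterior membership probabilities.
#'
#' @param X numeric feature matrix (rows = proteins).
#' @param y labels coded +1 (member) / -1 (non-member).
#' @param cost positive soft-margin cost.
#' @param class_weights named pair `c(pos = , neg = )` of positive
#'   per-class cost multipliers.
#' @param sigma positive Gaussian kernel width.
#' @param platt fit a Platt probability sigmoid via cross-validation.
#' @param platt_folds folds for the Platt cross-validation.
#' @param seed seed for the Platt fold assignment.
#' @param config_digest optional descriptor-configuration digest; predictions
#'   refuse feature vectors carrying a different digest.
#' @return A `profam_model` of method `"svm"`.
#' @export
train_svm <- function(X, y, cost = 1, class_weights = c(pos = 1, neg = 1),
                      sigma = 1, platt = FALSE, platt_folds = 3L, seed = 1L,
                      config_digest = NULL) {
  X <- as.matrix(X)
  y <- check_two_classes(y)
  if (cost <= 0 || sigma <= 0) stopf("cost and sigma must be positive")
  if (any(class_weights <= 0)) stopf("class weights must be positive")
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  model <- svm_solve_scaled(Xs, y, cost, class_weights, sigma)
  model$scaler <- scaler
  model$config_digest <- config_digest %||% attr(X, "config_digest")
  if (isTRUE(platt)) {
    f_cv <- svm_cv_decisions(Xs, y, cost, class_weights, sigma,
                             folds = platt_folds, seed = seed)
    model$platt <- fit_platt(f_cv, y)
  }
  model
}

# core solver on already-scaled features
svm_solve_scaled <- function(Xs, y, cost, class_weights, sigma) {
  K <- gaussian_kernel(Xs, Xs, sigma)
  C <- ifelse(y == 1L, cost * class_weights[["pos"]],
              cost * class_weights[["neg"]])
  sol <- smo_solve(K, y, C)
  if (!sol$converged)
    warnf("SMO did not fully converge in %d iterations", sol$iterations)
  sv <- which(sol$alpha > 1e-8)
  state <- list(sv_x = Xs[sv, , drop = FALSE],
                sv_coef = sol$alpha[sv] * y[sv],
                b = sol$b, sigma = sigma)
  new_model("svm",
            hyper = list(cost = cost, class_weights = class_weights,
                         sigma = sigma),
            scaler = NULL, state = state)
}

svm_cv_decisions <- function(Xs, y, cost, class_weights, sigma,
                             folds = 3L, seed = 1L) {
  n <- length(y)
  fold_of <- integer(n)
  with_seed(seed, {
    for (cls in c(1L, -1L)) {
      idx <- sample(which(y == cls))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  f <- numeric(n)
  for (k in seq_len(folds)) {
    hold <- fold_of == k
    if (length(unique(y[!hold])) < 2L) {
      f[hold] <- 0
      next
    }
    m <- svm_solve_scaled(Xs[!hold, , drop = FALSE], y[!hold],
                          cost, class_weights, sigma)
    f[hold] <- svm_decision_scaled(m, Xs[hold, , drop = FALSE])
  }
  f
}

svm_decision_scaled <- function(model, Xs) {
  K <- gaussian_kernel(Xs, model$state$sv_x, model$state$sigma)
  drop(K %*% model$state$sv_coef) + model$state$b
}

#' SVM decision values for new data
#'
#' @param model a trained SVM `profam_model`.
#' @param newdata feature matrix or single feature vector (unscaled).
#' @return Numeric decision values `f(x)`.
#' @export
decision_values <- function(model, newdata) {
  stopifnot(inherits(model, "profam_svm"))
  Xs <- apply_scaler(model$scaler, newdata)
  svm_decision_scaled(model, Xs)
}

#' Fit Platt's probability sigmoid
#'
#' Finds `(A, B)` minimizing the regularized negative log-likelihood of
#' `P(y = 1 | f) = 1 / (1 + exp(A f + B))` on decision values `f`, using
#' Platt's smoothed targets `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)` and a
#' Newton iteration with backtracking. For well-separated decision values
#' `A < 0`, so the probability is strictly increasing in `f`.
#'
#' Degenerate input (all decision values identical) falls back to the
#' prior-based constant probability with a warning (`A = 0`).
#'
#' @param f decision values (for calibration, out-of-fold values).
#' @param y labels coded +1 / -1.
#' @return Named numeric `c(A = , B = )`.
#' @export
fit_platt <- function(f, y) {
  y <- check_two_classes(y)
  n_pos <- sum(y == 1L); n_neg <- sum(y == -1L)
  if (diff(range(f)) < 1e-12) {
    warnf("degenerate decision values; Platt fit falls back to the class prior")
    return(c(A = 0, B = log((n_neg + 1) / (n_pos + 1))))
  }
  # Newton with backtracking (Lin, Weng & Huang 2007 formulation)
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y == 1L, hi, lo)
  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  nll <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  F_old <- nll(A, B)
  for (it in 1:200) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    d1 <- t - p                      # dF/dz per point
    d2 <- p * (1 - p)
    gA <- sum(f * d1); gB <- sum(d1)
    if (abs(gA) < 1e-10 && abs(gB) < 1e-10) break
    hAA <- sum(f * f * d2) + 1e-12
    hAB <- sum(f * d2)
    hBB <- sum(d2) + 1e-12
    det <- hAA * hBB - hAB * hAB
    dA <- -(hBB * gA - hAB * gB) / det
    dB <- -(hAA * gB - hAB * gA) / det
    step <- 1
    repeat {
      A_new <- A + step * dA
      B_new <- B + step * dB
      F_new <- nll(A_new, B_new)
      if (F_new < F_old + 1e-4 * step * (gA * dA + gB * dB)) break
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
    A <- A + step * dA; B <- B + step * dB
    if (abs(F_old - F_new) < 1e-10) { F_old <- F_new; break }
    F_old <- F_new
  }
  c(A = A, B = B)
}

#' @rdname fit_platt
#' @param AB a fitted `c(A, B)` pair.
#' @return `platt_probability`: probabilities `1 / (1 + exp(A f + B))`.
#' @export
platt_probability <- function(f, AB) {
  z <- AB[["A"]] * f + AB[["B"]]
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

#' Train a k-nearest-neighbour classifier
#'
#' Stores the min-max-scaled training vectors; prediction computes Euclidean
#' distances in the scaled space, takes the k nearest training vectors and
#' calls the majority class (vote ties break to non-member). The score is the
#' member-vote fraction; the reported probability is the Laplace-smoothed
#' fraction `(votes + 1) / (k + 2)`, strictly inside (0, 1).
#'
#' @inheritParams train_svm
#' @param k positive neighbour count, at most `nrow(X)`; odd values avoid
#'   vote ties.
#' @return A `profam_model` of method `"knn"`.
#' @export
train_knn <- function(X, y, k = 5L, config_digest = NULL) {
  X <- as.matrix(X)
  y <- check_two_classes(y)
  k <- as.integer(k)
  if (k < 1L) stopf("k must be positive")
  if (k > nrow(X)) stopf("k (%d) exceeds the number of training points (%d)",
                         k, nrow(X))
  if (k %% 2L == 0L) warnf("even k (%d): vote ties break to non-member", k)
  scaler <- fit_scaler(X)
  m <- new_model("knn", hyper = list(k = k), scaler = scaler,
                 state = list(x = apply_scaler(scaler, X), y = y),
                 config_digest = config_digest %||% attr(X, "config_digest"))
  m
}

#' Train a probabilistic neural network (Parzen-window classifier)
#'
#' Class-conditional densities are estimated with the Parzen kernel
#' `g(x) = (1/n) sum_i exp(-sum_j ((x_j - x_ij) / sigma_j)^2)` over each
#' class's stored (scaled) training vectors, exactly as conventionally
#' written for this classifier family (no 1/2 factor, no normalizing
#' constant — both cancel in the two-class decision when shared). A query is
#' classified by the Bayes rule: member iff
#' `h_pos c_pos g_pos(x) > h_neg c_neg g_neg(x)` (ties to non-member), with
#' priors `h` defaulting to training-class frequencies and unit
#' misclassification costs `c`. The score is the normalized posterior
#' `h1 c1 g1 / (h1 c1 g1 + h2 c2 g2)`, computed in log space.
#'
#' @inheritParams train_svm
#' @param smoothing positive smoothing factor; a scalar shared by all
#'   features or a per-feature vector (`sigma_j`).
#' @param priors named pair `c(pos = , neg = )`; default = class frequencies.
#' @param costs named pair of misclassification costs, default `c(1, 1)`.
#' @return A `profam_model` of method `"pnn"`.
#' @export
train_pnn <- function(X, y, smoothing = 0.1, priors = NULL,
                      costs = c(pos = 1, neg = 1), config_digest = NULL) {
  X <- as.matrix(X)
  y <- check_two_classes(y)
  if (any(smoothing <= 0)) stopf("smoothing factor(s) must be positive")
  if (!(length(smoothing) %in% c(1L, ncol(X))))
    stopf("smoothing must be a scalar or one value per feature")
  if (is.null(priors)) priors <- c(pos = mean(y == 1L), neg = mean(y == -1L))
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  new_model("pnn",
            hyper = list(smoothing = smoothing, priors = priors,
                         costs = costs),
            scaler = scaler,
            state = list(pos = Xs[y == 1L, , drop = FALSE],
                         neg = Xs[y == -1L, , drop = FALSE]),
            config_digest = config_digest %||% attr(X, "config_digest"))
}

#' Parzen-window density estimate
#'
#' Direct evaluation of
#' `g(x) = (1/n) sum_i exp(-sum_j ((x_j - x_ij) / sigma_j)^2)` over the rows
#' of `train`, for each row of `queries`.
#'
#' @param train numeric matrix of stored class vectors.
#' @param queries numeric matrix (or single vector) of query points.
#' @param smoothing scalar or per-feature smoothing factor `sigma_j`.
#' @return Numeric vector of densities, one per query.
#' @export
parzen_density <- function(train, queries, smoothing) {
  train <- as.matrix(train)
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1L)
  queries <- as.matrix(queries)
  sig <- rep_len(smoothing, ncol(train))
  d2 <- cross_dist2(sweep(queries, 2L, sig, "/"),
                    sweep(train, 2L, sig, "/"))
  rowMeans(exp(-d2))
}

# log of the Parzen density, stable under exponent underflow
log_parzen <- function(train, Qs, sig) {
  d2 <- cross_dist2(sweep(Qs, 2L, sig, "/"), sweep(train, 2L, sig, "/"))
  apply(d2, 1L, function(row) {
    m <- max(-row)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(-row - m))) - log(length(row))
  })
}

#' Predict family membership with a trained classifier
#'
#' @param object a `profam_model` (any method).
#' @param newdata unscaled feature matrix, [protein_set]-derived feature
#'   vector, or single numeric vector. If it carries a `config_digest`
#'   attribute differing from the model's, prediction is refused.
#' @param ... unused.
#' @return A data frame with one row per query: `query_id`, `label`
#'   (`"member"`/`"non_member"`), `score` and `probability`.
#' @export
predict.profam_model <- function(object, newdata, ...) {
  qd <- attr(newdata, "config_digest")
  if (!is.null(qd) && !is.null(object$config_digest) &&
      !identical(qd, object$config_digest))
    stopf("descriptor configuration mismatch: model %s vs query %s",
          object$config_digest, qd)
  if (is.null(dim(newdata))) {
    ids <- "query1"
    newdata <- matrix(newdata, nrow = 1L)
  } else {
    ids <- rownames(newdata) %||% paste0("query", seq_len(nrow(newdata)))
  }
  res <- switch(object$method,
                svm = predict_svm_matrix(object, newdata),
                knn = predict_knn_matrix(object, newdata),
                pnn = predict_pnn_matrix(object, newdata),
                stopf("unknown method '%s'", object$method))
  data.frame(query_id = ids,
             label = ifelse(res$member, "member", "non_member"),
             score = res$score, probability = res$probability,
             stringsAsFactors = FALSE)
}

predict_svm_matrix <- function(model, X) {
  f <- decision_values(model, X)
  prob <- if (!is.null(model$platt)) platt_probability(f, model$platt)
          else NA_real_
  list(member = f > 0, score = f, probability = prob)
}

predict_knn_matrix <- function(model, X) {
  Xs <- apply_scaler(model$scaler, X)
  D <- cross_dist2(Xs, model$state$x)
  k <- model$hyper$k
  votes <- apply(D, 1L, function(d) {
    nb <- order(d)[seq_len(k)]      # stable order: ties by training index
    sum(model$state$y[nb] == 1L)
  })
  list(member = votes > k / 2,      # exact tie -> non-member
       score = votes / k,
       probability = (votes + 1) / (k + 2))
}

predict_pnn_matrix <- function(model, X) {
  Xs <- apply_scaler(model$scaler, X)
  sig <- rep_len(model$hyper$smoothing, ncol(Xs))
  lg_pos <- log_parzen(model$state$pos, Xs, sig)
  lg_neg <- log_parzen(model$state$neg, Xs, sig)
  lp_pos <- log(model$hyper$priors[["pos"]] * model$hyper$costs[["pos"]]) + lg_pos
  lp_neg <- log(model$hyper$priors[["neg"]] * model$hyper$costs[["neg"]]) + lg_neg
  member <- ifelse(is.finite(lp_pos) | is.finite(lp_neg),
                   lp_pos > lp_neg, FALSE)
  m <- pmax(lp_pos, lp_neg)
  prob <- ifelse(is.finite(m),
                 exp(lp_pos - m) / (exp(lp_pos - m) + exp(lp_neg - m)),
                 0.5)
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  list(member = as.logical(member), score = prob, probability = prob)
}

#' @rdname predict.profam_model
#' @param model a trained `profam_model` of the matching method.
#' @param x feature vector or matrix.
#' @export
predict_svm <- function(model, x) {
  stopifnot(inherits(model, "profam_svm")); predict(model, x)
}

#' @rdname predict.profam_model
#' @export
predict_knn <- function(model, x) {
  stopifnot(inherits(model, "profam_knn")); predict(model, x)
}

#' @rdname predict.profam_model
#' @export
predict_pnn <- function(model, x) {
  stopifnot(inherits(model, "profam_pnn")); predict(model, x)
}

#' Train a classifier of any backend with a named hyperparameter list
#'
#' @param method `"svm"`, `"knn"` or `"pnn"`.
#' @param X unscaled feature matrix.
#' @param y labels coded +1 / -1.
#' @param hyper named list: svm `cost`, `sigma`, `weight_pos`; knn `k`;
#'   pnn `smoothing`.
#' @param platt for svm, fit the Platt sigmoid (ignored otherwise).
#' @param seed seed for the Platt fold assignment.
#' @param config_digest optional descriptor-configuration digest.
#' @return A `profam_model`.
#' @export
train_classifier <- function(method, X, y, hyper = list(), platt = FALSE,
                             seed = 1L, config_digest = NULL) {
  switch(method,
         svm = train_svm(X, y,
                         cost = hyper$cost %||% 1,
                         class_weights = c(pos = hyper$weight_pos %||% 1,
                                           neg = hyper$weight_neg %||% 1),
                         sigma = hyper$sigma %||% 1,
                         platt = platt, seed = seed,
                         config_digest = config_digest),
         knn = train_knn(X, y, k = hyper$k %||% 5L,
                         config_digest = config_digest),
         pnn = train_pnn(X, y, smoothing = hyper$smoothing %||% 0.1,
                         config_digest = config_digest),
         stopf("unknown method '%s'", method))
}

#' Default hyperparameter grids
#'
#' Small honest defaults: svm crosses cost, kernel width and member-class
#' weight (1 or the negative:positive ratio, reflecting the imbalance-aware
#' separate cost optimization); knn odd k; pnn a smoothing ladder.
#'
#' @param method `"svm"`, `"knn"` or `"pnn"`.
#' @param y optional training labels, used to compute the imbalance ratio.
#' @return A data frame, one row per hyperparameter setting.
#' @export
default_grid <- function(method, y = NULL) {
  switch(method,
         svm = {
           ratio <- 1
           if (!is.null(y))
             ratio <- max(1, round(sum(y == -1) / max(1, sum(y == 1))))
           unique(expand.grid(cost = c(1, 10, 100, 1000),
                              sigma = c(0.5, 1, 2, 4),
                              weight_pos = unique(c(1, ratio)),
                              KEEP.OUT.ATTRS = FALSE))
         },
         knn = data.frame(k = c(1L, 3L, 5L, 7L, 9L)),
         pnn = data.frame(smoothing = c(0.05, 0.1, 0.2, 0.4, 0.8)),
         stopf("unknown method '%s'", method))
}

#' Exhaustive hyperparameter search on a tuning set
#'
#' Trains one model per grid row on `(X_train, y_train)` and scores it on
#' `(X_tune, y_tune)` by balanced accuracy `(SE + SP) / 2`; the maximizer is
#' returned (ties: first in grid order). Settings whose tune-set SE or SP is
#' undefined score `-Inf`.
#'
#' @inheritParams train_classifier
#' @param X_train,y_train training partition.
#' @param X_tune,y_tune tuning (testing) partition.
#' @param grid data frame of hyperparameter settings; default
#'   [default_grid()].
#' @return A list with `best` (named hyperparameter list), `criterion`, and
#'   `results` (the grid with its criterion values).
#' @export
grid_search <- function(method, X_train, y_train, X_tune, y_tune,
                        grid = NULL, seed = 1L) {
  grid <- grid %||% default_grid(method, y_train)
  if (nrow(grid) == 0L) stopf("empty hyperparameter grid")
  crit <- vapply(seq_len(nrow(grid)), function(i) {
    hyper <- as.list(grid[i, , drop = FALSE])
    model <- train_classifier(method, X_train, y_train, hyper,
                              platt = FALSE, seed = seed)
    pred <- predict(model, X_tune)
    cm <- confusion_counts(y_tune,
                           ifelse(pred$label == "member", 1L, -1L))
    met <- classification_metrics(cm)
    if (is.na(met[["SE"]]) || is.na(met[["SP"]])) return(-Inf)
    (met[["SE"]] + met[["SP"]]) / 2
  }, numeric(1))
  best_i <- which.max(crit)  # first maximum in grid order
  list(best = as.list(grid[best_i, , drop = FALSE]),
       criterion = crit[best_i],
       results = cbind(grid, criterion = crit))
}

#' Persist / restore a trained model
#'
#' Models are stored as a versioned archive containing the method tag,
#' hyperparameters, scaling parameters, learned state, optional Platt pair
#' and the descriptor-configuration digest. [load_model()] refuses archives
#' of an unknown version.
#'
#' @param model a `profam_model`.
#' @param path file path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "profam_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "profam_model"))
    stopf("'%s' is not a profam model archive", path)
  if (!identical(model$version, 1L))
    stopf("unsupported model archive version: %s", model$version)
  model
}
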