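sep_clusters <- function(n = 20, gap = 3, p = 2, seed = 71) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p), n), matrix(rnorm(n * p, gap), n))
  list(X = X, y = rep(c(1L, -1L), each = n))
}

test_that("min-max scaler maps training data into [0,1]", {
  expect_equal(drop(apply_scaler(fit_scaler(matrix(c(0, 2, 4))),
                                 matrix(c(0, 2, 4)))), c(0, 0.5, 1))
  Xc <- cbind(c(1, 1, 1), c(0, 1, 2))
  sc <- fit_scaler(Xc)
  expect_equal(apply_scaler(sc, Xc)[, 1], rep(0, 3))  # constant column
  set.seed(72)
  X <- matrix(rnorm(200), 40)
  Xs <- apply_scaler(fit_scaler(X), X)
  expect_true(all(Xs >= 0 & Xs <= 1))
  expect_error(apply_scaler(fit_scaler(X), matrix(0, 2, 3)), "mismatch")
  expect_error(fit_scaler(matrix(numeric(0), 0, 2)), "empty")
})

test_that("SVM separates clusters, fits XOR, and obeys the sign rule", {
  d <- sep_clusters()
  m <- train_svm(d$X, d$y, cost = 10, sigma = 1)
  f <- decision_values(m, d$X)
  expect_true(all(sign(f) == d$y))                     # sign agreement
  expect_equal(predict(m, d$X)$label,
               ifelse(d$y == 1, "member", "non_member"))

  # XOR pattern: only a non-linear kernel can fit this
  Xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  Xx <- Xx[rep(1:4, 5), ] + matrix(rnorm(40, sd = 0.05), 20)
  yx <- rep(c(1L, 1L, -1L, -1L), 5)
  mx <- train_svm(Xx, yx, cost = 100, sigma = 0.3)
  expect_equal(ifelse(predict(mx, Xx)$label == "member", 1L, -1L), yx)

  expect_error(train_svm(d$X, rep(1L, 40)), "both classes")
  expect_error(train_svm(d$X, d$y, cost = -1), "positive")
})

test_that("SVM decision value 0 breaks to non-member and Platt wires through", {
  d <- sep_clusters(seed = 73)
  m <- train_svm(d$X, d$y, cost = 10, sigma = 1, platt = TRUE, seed = 1)
  # force f(x) = 0 by shifting the bias: the crafted query must be non-member
  q <- d$X[1, , drop = FALSE]
  f <- decision_values(m, q)
  m0 <- m
  m0$state$b <- m$state$b - f
  expect_equal(predict(m0, q)$label, "non_member")
  # probability equals the sigmoid of the stored pair
  pr <- predict(m, d$X)
  expect_equal(pr$probability,
               unname(1 / (1 + exp(m$platt[["A"]] * pr$score + m$platt[["B"]]))))
})

test_that("Platt fit is monotone and near the grid-search optimum", {
  set.seed(74)
  f <- c(rnorm(60, 1.2), rnorm(60, -0.8))
  y <- rep(c(1L, -1L), each = 60)
  AB <- fit_platt(f, y)
  expect_lt(AB[["A"]], 0)
  grid_f <- seq(-3, 3, length.out = 200)
  p <- platt_probability(grid_f, AB)
  expect_true(all(diff(p) > 0))          # strictly monotone in f
  expect_true(all(p > 0 & p < 1))
  # midpoint: A f + B = 0 gives probability 1/2
  expect_equal(platt_probability(-AB[["B"]] / AB[["A"]], AB), 0.5)
  # degenerate input falls back to the prior
  expect_warning(AB0 <- fit_platt(rep(1, 10), rep(c(1L, -1L), 5)),
                 "degenerate")
  expect_equal(platt_probability(1, AB0), 0.5, tolerance = 0.2)
})

test_that("kNN votes match the exhaustive-search oracle", {
  set.seed(75)
  X <- matrix(runif(200 * 5), 200)
  y <- ifelse(rowSums(X) > 2.5, 1L, -1L)
  y[1:5] <- -y[1:5]  # plant label noise
  m <- train_knn(X, y, k = 5)
  # k = 1 on a training point returns that point's label
  m1 <- train_knn(X, y, k = 1)
  p1 <- predict(m1, X)
  expect_equal(ifelse(p1$label == "member", 1L, -1L), y)  # leave-in property
  # vote arithmetic at k = 3
  m3 <- train_knn(X, y, k = 3)
  p3 <- predict(m3, X[7, , drop = FALSE])
  expect_true(p3$score %in% c(0, 1/3, 2/3, 1))
  expect_error(train_knn(X, y, k = 500), "exceeds")

  Q <- matrix(runif(200 * 5), 200)
  pred <- predict(m, Q)
  sc <- m$scaler
  Xs <- apply_scaler(sc, X); Qs <- apply_scaler(sc, Q)
  oracle <- vapply(seq_len(nrow(Qs)), function(i)
    oracle_knn_label(Xs, y, Qs[i, ], 5), integer(1))
  expect_equal(ifelse(pred$label == "member", 1L, -1L), oracle)
  expect_true(all(pred$probability > 0 & pred$probability < 1))
})

test_that("PNN density matches Eq-style double-loop evaluation", {
  set.seed(76)
  X <- matrix(runif(60 * 4), 60)
  y <- rep(c(1L, -1L), 30)
  m <- train_pnn(X, y, smoothing = 0.3)
  Q <- matrix(runif(25 * 4), 25)
  Qs <- apply_scaler(m$scaler, Q)
  g_pkg <- parzen_density(m$state$pos, Qs, 0.3)
  g_orc <- vapply(seq_len(nrow(Qs)), function(i)
    oracle_parzen(m$state$pos, Qs[i, ], 0.3), numeric(1))
  expect_equal(g_pkg, g_orc)

  # one point per class: query classified to the nearer point
  m2 <- train_pnn(rbind(c(0, 0), c(1, 1)), c(1L, -1L), smoothing = 0.5,
                  priors = c(pos = 0.5, neg = 0.5))
  expect_equal(predict(m2, rbind(c(0.1, 0.1)))$label, "member")
  expect_equal(predict(m2, rbind(c(0.9, 0.9)))$label, "non_member")
  # scaling both costs equally changes no decision
  m3 <- train_pnn(X, y, smoothing = 0.2, costs = c(pos = 5, neg = 5))
  m4 <- train_pnn(X, y, smoothing = 0.2, costs = c(pos = 1, neg = 1))
  expect_equal(predict(m3, Q)$label, predict(m4, Q)$label)
  expect_error(train_pnn(X, y, smoothing = 0), "positive")
})

test_that("all backends are invariant to training-row permutation", {
  set.seed(77)
  d <- sep_clusters(n = 25, gap = 2.2, p = 4, seed = 77)
  Q <- matrix(rnorm(40 * 4, 1), 40)
  perm <- sample(nrow(d$X))
  for (method in c("svm", "knn", "pnn")) {
    hyper <- list(cost = 10, sigma = 1, k = 5L, smoothing = 0.2)
    m_a <- train_classifier(method, d$X, d$y, hyper)
    m_b <- train_classifier(method, d$X[perm, ], d$y[perm], hyper)
    expect_equal(predict(m_a, Q)$label, predict(m_b, Q)$label,
                 info = method)
  }
})

test_that("grid_search returns the tune-set maximizer deterministically", {
  d <- sep_clusters(n = 15, gap = 2.5, seed = 78)
  tune <- sep_clusters(n = 10, gap = 2.5, seed = 79)
  single <- data.frame(k = 3L)
  gs1 <- grid_search("knn", d$X, d$y, tune$X, tune$y, grid = single)
  expect_equal(gs1$best$k, 3L)
  expect_error(grid_search("knn", d$X, d$y, tune$X, tune$y,
                           grid = data.frame(k = integer(0))), "empty")

  gs <- grid_search("svm", d$X, d$y, tune$X, tune$y)
  # chosen setting's criterion is maximal over the whole grid
  expect_true(all(gs$results$criterion <= gs$criterion + 1e-12))
  # a separable grid point reaches balanced accuracy 1
  expect_equal(gs$criterion, 1)
})

test_that("model persistence round-trips and refuses digest mismatches", {
  d <- sep_clusters(seed = 80)
  m <- train_svm(d$X, d$y, cost = 10, sigma = 1, config_digest = "abc123")
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, d$X), predict(m, d$X))
  q <- d$X[1:2, ]
  attr(q, "config_digest") <- "zzz999"
  expect_error(predict(m2, q), "configuration mismatch")
})
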