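# Brute-force reference implementations ("oracles") kept deliberately
# independent of the package's vectorized code paths, plus small random
# fixture generators. All tests seed explicitly.

AAS <- c("A","C","D","E","F","G","H","I","K","L",
         "M","N","P","Q","R","S","T","V","W","Y")

rand_residues <- function(L) paste(sample(AAS, L, replace = TRUE), collapse = "")

rand_protein_set <- function(n, Lmin = 30, Lmax = 80, prefix = "P") {
  protein_set(id = sprintf("%s%04d", prefix, seq_len(n)),
              residues = vapply(sample(Lmin:Lmax, n, replace = TRUE),
                                rand_residues, character(1)))
}

# random three-class grouping guaranteed to use every class
rand_grouping <- function() {
  repeat {
    cls <- sample(1:3, 20, replace = TRUE)
    if (all(1:3 %in% cls)) break
  }
  property_grouping("random", setNames(cls, AAS))
}

# --- descriptor oracles: explicit per-position loops ---

oracle_composition <- function(res, grouping) {
  chars <- strsplit(res, "")[[1]]
  counts <- c(0, 0, 0)
  for (ch in chars) counts[grouping$class_of[[ch]]] <- counts[grouping$class_of[[ch]]] + 1
  counts / length(chars)
}

oracle_transition <- function(res, grouping) {
  chars <- strsplit(res, "")[[1]]
  L <- length(chars)
  if (L < 2) return(c(0, 0, 0))
  tally <- c("12" = 0, "13" = 0, "23" = 0)
  for (i in 1:(L - 1)) {
    a <- grouping$class_of[[chars[i]]]
    b <- grouping$class_of[[chars[i + 1]]]
    if (a != b) {
      key <- paste0(min(a, b), max(a, b))
      tally[key] <- tally[key] + 1
    }
  }
  unname(tally) / (L - 1)
}

oracle_distribution <- function(res, grouping) {
  chars <- strsplit(res, "")[[1]]
  L <- length(chars)
  out <- numeric(15)
  for (j in 1:3) {
    pos <- integer(0)
    for (i in seq_len(L)) if (grouping$class_of[[chars[i]]] == j) pos <- c(pos, i)
    n <- length(pos)
    if (n == 0) next
    ks <- c(1, max(1, floor(0.25 * n)), max(1, floor(0.50 * n)),
            max(1, floor(0.75 * n)), n)
    out[(j - 1) * 5 + 1:5] <- pos[ks] / L
  }
  out
}

oracle_moreau_broto <- function(res, scale, max_lag) {
  v <- scale$value_of
  p <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  x <- p[strsplit(res, "")[[1]]]
  L <- length(x)
  out <- numeric(max_lag)
  for (d in seq_len(max_lag)) {
    s <- 0
    for (i in 1:(L - d)) s <- s + x[i] * x[i + d]
    out[d] <- s / (L - d)
  }
  out
}

oracle_pseaac <- function(res, scales, lam, w) {
  chars <- strsplit(res, "")[[1]]
  L <- length(chars)
  P <- sapply(scales, function(s) {
    v <- s$value_of
    ((v - mean(v)) / sqrt(mean((v - mean(v))^2)))[chars]
  })
  f <- numeric(20)
  for (ch in chars) f[match(ch, AAS)] <- f[match(ch, AAS)] + 1
  f <- f / L
  theta <- numeric(lam)
  for (k in seq_len(lam)) {
    tot <- 0
    for (i in 1:(L - k)) tot <- tot + mean((P[i + k, ] - P[i, ])^2)
    theta[k] <- tot / (L - k)
  }
  c(f, w * theta) / (1 + w * sum(theta))
}

# --- classifier oracles ---

oracle_knn_label <- function(Xtr, ytr, q, k) {
  d <- numeric(nrow(Xtr))
  for (i in seq_len(nrow(Xtr))) d[i] <- sqrt(sum((Xtr[i, ] - q)^2))
  nb <- order(d)[1:k]
  votes <- sum(ytr[nb] == 1)
  if (votes > k / 2) 1L else -1L
}

oracle_parzen <- function(train, q, sigma) {
  sig <- rep_len(sigma, ncol(train))
  tot <- 0
  for (i in seq_len(nrow(train))) {
    e <- 0
    for (j in seq_len(ncol(train))) e <- e + ((q[j] - train[i, j]) / sig[j])^2
    tot <- tot + exp(-e)
  }
  tot / nrow(train)
}

oracle_confusion <- function(yt, yp) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(yt)) {
    if (yt[i] == 1 && yp[i] == 1) tp <- tp + 1
    else if (yt[i] == -1 && yp[i] == -1) tn <- tn + 1
    else if (yt[i] == -1 && yp[i] == 1) fp <- fp + 1
    else fn <- fn + 1
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# the 30-residue two-letter worked example used across descriptor tests
WORKED_SEQ <- "AEAAAEAEEAAAAAEAEEEAAEEAEEEAAE"
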