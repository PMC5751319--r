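# Independent brute-force oracles used to cross-check the vectorized
# implementations.  These deliberately stay loop-based and close to the
# printed definitions.

# between/within kernel scatter via explicit loops over the defining sums
oracle_scatter <- function(data, s) {
  n <- nrow(data$x)
  lv <- levels(data$labels)
  kf <- function(i, j) gaussian_kernel(data$x[i, ], data$x[j, ], s)
  grand <- vapply(seq_len(n), function(k) {
    mean(vapply(seq_len(n), function(j) kf(k, j), numeric(1)))
  }, numeric(1))
  between <- matrix(0, n, n)
  within <- matrix(0, n, n)
  for (cl in lv) {
    idx <- which(data$labels == cl)
    Ni <- length(idx)
    Mi <- vapply(seq_len(n), function(k) {
      mean(vapply(idx, function(j) kf(k, j), numeric(1)))
    }, numeric(1))
    Ki <- matrix(0, n, Ni)
    for (m in seq_len(n)) {
      for (jj in seq_len(Ni)) Ki[m, jj] <- kf(m, idx[jj])
    }
    between <- between + Ni * (Mi - grand) %*% t(Mi - grand)
    within <- within +
      Ki %*% (diag(Ni) - matrix(1 / Ni, Ni, Ni)) %*% t(Ki)
  }
  list(between = between, within = within)
}

# edge/internal split by direct transcription of the selection rules
oracle_split <- function(data, class_index, u) {
  lv <- levels(data$labels)
  members <- which(data$labels == lv[class_index])
  D <- as.matrix(dist(data$x))
  eps <- mean(vapply(members, function(m) sort(D[m, -m])[u], numeric(1)))
  centroid <- colMeans(data$x[members, , drop = FALSE])
  distj <- sqrt(rowSums(sweep(data$x[members, , drop = FALSE], 2, centroid)^2))
  m <- median(distj)
  edge <- integer(0)
  internal <- integer(0)
  for (j in seq_along(members)) {
    g <- members[j]
    ball <- setdiff(which(D[g, ] <= eps), g)
    foreign <- any(data$labels[ball] != lv[class_index])
    if (distj[j] > m && foreign) edge <- c(edge, g)
    if (distj[j] < m && !foreign) internal <- c(internal, g)
  }
  list(edge = edge, internal = internal)
}

# exhaustive-sort KNN
oracle_knn <- function(train_x, train_y, q, k) {
  d <- sqrt(rowSums(sweep(as.matrix(train_x), 2, q)^2))
  top <- as.character(train_y[order(d)][seq_len(k)])
  votes <- table(top)
  winners <- names(votes)[votes == max(votes)]
  if (length(winners) == 1L) winners else top[top %in% winners][1]
}

# loop evaluation of the PSSM-S blocks under the package's block formulas
oracle_pssm_s <- function(profile) {
  sc <- profile$scores
  L <- nrow(sc)
  cons <- integer(L)
  for (i in seq_len(L)) cons[i] <- which.max(sc[i, ])
  aao <- numeric(20)
  for (j in seq_len(20)) aao[j] <- sum(cons == j) / L
  paao <- numeric(20)
  for (j in seq_len(20)) paao[j] <- sum(sc[, j]) / L
  sd_block <- c()
  for (from_c in c(FALSE, TRUE)) {
    for (f in c(0.25, 0.5)) {
      v <- numeric(20)
      for (j in seq_len(20)) {
        a <- abs(sc[, j])
        if (from_c) a <- rev(a)
        tot <- sum(a)
        if (tot == 0) next
        run <- 0
        for (i in seq_len(L)) {
          run <- run + a[i]
          if (run >= f * tot) { v[j] <- i / L; break }
        }
      }
      sd_block <- c(sd_block, v)
    }
  }
  sac <- c()
  for (g in 1:5) {
    v <- numeric(20)
    for (j in seq_len(20)) {
      mu <- mean(sc[, j])
      acc <- 0
      for (i in seq_len(L - g)) acc <- acc + (sc[i, j] - mu) * (sc[i + g, j] - mu)
      v[j] <- acc / (L - g)
    }
    sac <- c(sac, v)
  }
  c(aao, paao, sd_block, sac)
}

# Rayleigh quotient of the fitted discriminant problem
rayleigh <- function(v, between, within, mu) {
  as.numeric(t(v) %*% between %*% v) /
    as.numeric(t(v) %*% (within + mu * diag(nrow(within))) %*% v)
}
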