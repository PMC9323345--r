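# Independent brute-force oracles. These deliberately re-derive every
# quantity with explicit loops and must stay independent of the package's
# vectorized implementations.

naive_glcm <- function(lev, L) {
  counts <- matrix(0L, L, L)
  for (r in seq_len(nrow(lev)))
    for (c in seq_len(ncol(lev) - 1))
      counts[lev[r, c], lev[r, c + 1]] <- counts[lev[r, c], lev[r, c + 1]] + 1L
  counts
}

# All 14 Haralick features from a probability matrix, by direct summation.
naive_haralick <- function(p) {
  L <- nrow(p)
  eps <- 1e-12
  px <- numeric(L); py <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  psum <- numeric(2 * L - 1) # index k-1, k = 2..2L
  pdif <- numeric(L)         # index k+1, k = 0..L-1
  for (i in 1:L) for (j in 1:L) {
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  ent <- function(v) {
    s <- 0
    for (x in v) if (x > 0) s <- s - x * log(x)
    s
  }
  f1 <- sum(p * p)
  f2 <- 0
  for (i in 1:L) for (j in 1:L) f2 <- f2 + (i - j)^2 * p[i, j]
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sigx <- sqrt(sum(((1:L) - mux)^2 * px))
  sigy <- sqrt(sum(((1:L) - muy)^2 * py))
  cov <- 0
  for (i in 1:L) for (j in 1:L) cov <- cov + i * j * p[i, j]
  f3 <- if (sigx * sigy < eps) 0 else (cov - mux * muy) / (sigx * sigy)
  f4 <- 0
  for (i in 1:L) for (j in 1:L) f4 <- f4 + (i - mux)^2 * p[i, j]
  f5 <- 0
  for (i in 1:L) for (j in 1:L) f5 <- f5 + p[i, j] / (1 + (i - j)^2)
  f6 <- sum((2:(2 * L)) * psum)
  f7 <- sum(((2:(2 * L)) - f6)^2 * psum)
  f8 <- ent(psum)
  f9 <- ent(p)
  mud <- sum((0:(L - 1)) * pdif)
  f10 <- sum(((0:(L - 1)) - mud)^2 * pdif)
  f11 <- ent(pdif)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    hxy1 <- hxy1 - p[i, j] * log(px[i] * py[j] + eps)
    hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j] + eps)
  }
  hx <- ent(px); hy <- ent(py)
  f12 <- if (max(hx, hy) < eps) 0 else (f9 - hxy1) / max(hx, hy)
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9))))
  nzr <- which(px > 0); nzc <- which(py > 0)
  f14 <- if (length(nzr) < 2 || length(nzc) < 2) 0 else {
    Q <- matrix(0, length(nzr), length(nzr))
    for (a in seq_along(nzr)) for (b in seq_along(nzr)) {
      s <- 0
      for (k in nzc)
        s <- s + p[nzr[a], k] * p[nzr[b], k] / (px[nzr[a]] * py[k])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13, f14)
}

naive_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- 0; m3 <- 0; m4 <- 0
  for (xi in x) {
    m2 <- m2 + (xi - m)^2 / n
    m3 <- m3 + (xi - m)^3 / n
    m4 <- m4 + (xi - m)^4 / n
  }
  list(mean = m, m2 = m2, m3 = m3, m4 = m4)
}

# One-vs-rest pixel metrics by raw loops over aligned rasters.
naive_class_metrics <- function(target, predicted, class) {
  TP <- TN <- FP <- FN <- 0L
  for (i in seq_along(target)) {
    t <- target[i]; p <- predicted[i]
    if (t == 0L) next
    if (t == class && p == class) TP <- TP + 1L
    else if (t == class && p != class) FN <- FN + 1L
    else if (t != class && p == class) FP <- FP + 1L
    else TN <- TN + 1L
  }
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       accuracy = (TP + TN) / (TP + TN + FP + FN),
       iou = if (TP + FP + FN > 0) TP / (TP + FP + FN) else NA_real_,
       precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_)
}

# Exhaustive two-sided permutation distribution of the pooled t statistic.
perm_t_stats <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pool), n1)
  apply(idx, 2, function(ii) {
    x <- pool[ii]; y <- pool[-ii]
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  })
}

random_trimmed_glcm <- function(L = 8) {
  # random valid probability matrix wrapped as the package's type
  cts <- matrix(rpois(L * L, 2), L, L)
  if (sum(cts) == 0) cts[1, 1] <- 1
  g <- structure(list(counts = rbind(0, cbind(0, cts)), levels = L + 1,
                      offset = c(0L, 1L)), class = "glcm")
  bccmorph::trim_and_normalize(g)
}
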