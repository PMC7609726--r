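# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: naive loops and textbook formulas only.

# Naive per-pair Pearson correlation via the raw covariance formula.
naive_abs_cor <- function(expr) {
  p <- nrow(expr)
  out <- diag(1, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      x <- expr[i, ]; y <- expr[j, ]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      cov <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
      out[i, j] <- abs(cov / (sd(x) * sd(y)))
    }
  }
  dimnames(out) <- list(rownames(expr), rownames(expr))
  out
}

# Triple-loop TOM straight from the formula (diagonal treated as 0).
naive_tom <- function(adj) {
  A <- adj
  diag(A) <- 0
  p <- nrow(A)
  k <- rowSums(A)
  out <- diag(1, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(p)) {
        if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      }
      out[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  out
}

# Recursive UPGMA on a dissimilarity matrix; returns sorted merge heights.
naive_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1L)) {
        if (d[active[a], active[b]] < bh) {
          bh <- d[active[a], active[b]]
          best <- c(active[b], active[a])
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bh)
    # average-linkage update of row i; deactivate j
    for (m in active) {
      if (m != i && m != j) {
        d[i, m] <- d[m, i] <-
          (sizes[i] * d[i, m] + sizes[j] * d[j, m]) / (sizes[i] + sizes[j])
      }
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# Hand product-limit estimator (events before censorings at tied times).
naive_km <- function(time, event) {
  ut <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ut, survival = surv)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Construct y with an exact sample correlation r0 to x (n >= 3).
exact_cor_pair <- function(n, r0, seed = 1) {
  set.seed(seed)
  x <- as.numeric(scale(rnorm(n)))
  z <- residuals(stats::lm(rnorm(n) ~ x))
  z <- as.numeric(scale(z))
  list(x = x, y = r0 * x + sqrt(1 - r0^2) * z)
}

# Reference scenario used by the module-recovery checks: 5 planted
# modules, member loading 0.8, 50 samples, 50 background noise features.
reference_design <- function(seed) {
  synthetic_design(n_samples = 50, module_sizes = c(20, 18, 15, 12, 10),
                   loading = 0.8, n_background = 50, seed = seed)
}

detect_modules <- function(expr, min_size = 5, merge_similarity = 0.75) {
  sim <- similarity_matrix(expr)
  st <- pick_soft_threshold(sim)
  diss <- tom_dissimilarity(tom_matrix(adjacency_matrix(sim, st$beta)))
  dend <- average_linkage(diss)
  a0 <- dynamic_cut(dend, diss, min_size = min_size)
  merge_close_modules(expr, a0, merge_similarity)$assignment
}
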