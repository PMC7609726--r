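# Weighted unsigned co-expression network construction:
# absolute-correlation similarity -> soft-thresholded adjacency ->
# topological overlap matrix (TOM), with scale-free topology diagnostics
# for choosing the soft-thresholding power.

#' Co-expression similarity matrix
#'
#' Unsigned similarity: s_ij = |Pearson correlation| between the
#' expression profiles of features i and j, computed over pairwise
#' complete samples.  Anti-correlated features are therefore treated as
#' strongly connected.  The diagonal is set to 1.
#'
#' @param expr Numeric matrix, features x samples (at least 3 samples,
#'   no zero-variance features).
#' @return Symmetric matrix in [0, 1] with unit diagonal.
#' @export
similarity_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("at least 3 samples required", call. = FALSE)
  X <- t(expr)                      # samples x features
  npairs <- crossprod(!is.na(X))    # complete-pair counts per feature pair
  short <- npairs < 3L
  diag(short) <- FALSE
  if (any(short)) {
    idx <- which(short, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "fewer than 3 complete sample pairs for features '%s' and '%s'",
      colnames(X)[idx[1L]], colnames(X)[idx[2L]]), call. = FALSE)
  }
  s <- abs(stats::cor(X, use = "pairwise.complete.obs"))
  if (anyNA(s)) {
    bad <- unique(colnames(s)[which(is.na(s), arr.ind = TRUE)[, 1L]])
    stop("zero-variance feature(s); drop before network construction: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s <- (s + t(s)) / 2
  s[s > 1] <- 1
  diag(s) <- 1
  s
}

#' Soft-thresholded adjacency matrix
#'
#' Power adjacency function: a_ij = s_ij ^ beta.  Raising the similarity
#' to a power suppresses weak correlations and pushes the connectivity
#' distribution towards a scale-free form.
#'
#' @param sim Similarity matrix from \code{\link{similarity_matrix}}.
#' @param beta Integer soft-thresholding power, >= 1.
#' @return Adjacency matrix in [0, 1] with unit diagonal; the power used
#'   is stored in the \code{"beta"} attribute.
#' @export
adjacency_matrix <- function(sim, beta) {
  if (length(beta) != 1L || is.na(beta) || !is.numeric(beta) ||
      beta < 1 || beta != round(beta)) {
    stop("beta must be a single integer >= 1", call. = FALSE)
  }
  .check_square_symmetric(sim, what = "similarity")
  a <- sim ^ beta
  diag(a) <- 1
  attr(a, "beta") <- as.integer(beta)
  a
}

#' Whole-network connectivity
#'
#' k_i = sum over j != i of a_ij.  The stored unit diagonal is excluded.
#'
#' @param adj Adjacency (or similarity) matrix.
#' @return Numeric vector of connectivities, one per feature.
#' @export
connectivity <- function(adj) {
  rowSums(adj) - diag(adj)
}

#' Scale-free topology fit of an adjacency matrix
#'
#' Bins the connectivities k_i into \code{n_bins} equal-width bins and
#' regresses log10(frequency) on log10(mean k) over the non-empty bins.
#' The reported index is the regression R^2 signed by minus the slope, so
#' that a decreasing, power-law-like frequency curve yields a positive
#' index.  Fewer than 3 usable bins (e.g. a regular graph where all k are
#' equal) makes the fit invalid: the index and slope are reported as NaN
#' rather than raising an error.
#'
#' @param adj Adjacency matrix with >= 10 features.
#' @param n_bins Number of equal-width connectivity bins (default 10).
#' @return List with \code{beta} (if recorded on \code{adj}),
#'   \code{r_squared} (signed fit index in [-1, 1] or NaN),
#'   \code{slope}, \code{mean_connectivity} and \code{n_bins_used}.
#' @export
scale_free_fit <- function(adj, n_bins = 10) {
  if (nrow(adj) < 10L) stop("at least 10 features required", call. = FALSE)
  k <- connectivity(adj)
  out <- list(beta = attr(adj, "beta"), r_squared = NaN, slope = NaN,
              mean_connectivity = mean(k), n_bins_used = 0L)
  if (max(k) - min(k) < .Machine$double.eps^0.5) return(out)  # regular graph
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  kmean <- as.numeric(tapply(k, bin, mean))
  keep <- cnt > 0L & !is.na(kmean) & kmean > 0
  out$n_bins_used <- sum(keep)
  if (out$n_bins_used < 3L) return(out)
  x <- log10(kmean[keep])
  y <- log10(cnt[keep] / length(k))
  fit <- stats::lm(y ~ x)
  sl <- unname(stats::coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  out$slope <- sl
  out$r_squared <- -sign(sl) * r2
  out
}

#' Choose the soft-thresholding power by scale-free fit
#'
#' Sweeps the candidate powers in ascending order and returns the
#' smallest beta whose signed scale-free fit index reaches
#' \code{target_r2}.  If no candidate reaches the target, the beta
#' maximising the index is returned with a warning.  The full diagnostic
#' table (one row per candidate) is returned alongside for plotting or
#' export.
#'
#' @param sim Similarity matrix.
#' @param candidate_betas Ascending integer powers to try (default 1:20).
#' @param target_r2 Signed fit index required (default 0.80).
#' @param n_bins Passed to \code{\link{scale_free_fit}}.
#' @return List with \code{beta} (the chosen power) and \code{fits}
#'   (data.frame: beta, r_squared, slope, mean_connectivity).
#' @export
pick_soft_threshold <- function(sim, candidate_betas = 1:20,
                                target_r2 = 0.80, n_bins = 10) {
  if (!length(candidate_betas)) stop("no candidate powers supplied")
  if (is.unsorted(candidate_betas, strictly = TRUE)) {
    stop("candidate_betas must be strictly ascending")
  }
  fits <- lapply(candidate_betas, function(b) {
    scale_free_fit(adjacency_matrix(sim, b), n_bins = n_bins)
  })
  tab <- data.frame(
    beta = as.integer(candidate_betas),
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    slope = vapply(fits, `[[`, 0, "slope"),
    mean_connectivity = vapply(fits, `[[`, 0, "mean_connectivity"))
  ok <- which(!is.nan(tab$r_squared) & tab$r_squared >= target_r2)
  if (length(ok)) {
    beta <- tab$beta[ok[1L]]
  } else {
    idx <- replace(tab$r_squared, is.nan(tab$r_squared), -Inf)
    if (all(!is.finite(idx))) {
      warning("no valid scale-free fit for any candidate; returning the ",
              "smallest power", call. = FALSE)
      beta <- tab$beta[1L]
    } else {
      warning(sprintf(
        "no candidate power reaches the target fit index %.2f; returning ",
        target_r2), "the power with the best fit", call. = FALSE)
      beta <- tab$beta[which.max(idx)]
    }
  }
  list(beta = beta, fits = tab)
}

#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) for i != j, where
#' l_ij = sum over u != i, j of a_iu * a_uj and k_i is the connectivity.
#' The stored unit diagonal of the adjacency is treated as 0 inside the
#' formula; TOM_ii = 1.  Entries lie in [0, 1] whenever the adjacency
#' does, and 1 - TOM is the clustering dissimilarity.
#'
#' @param adj Adjacency matrix in [0, 1].
#' @return Symmetric TOM matrix in [0, 1] with unit diagonal.
#' @export
tom_matrix <- function(adj) {
  .check_square_symmetric(adj, what = "adjacency")
  if (min(adj) < -1e-12 || max(adj) > 1 + 1e-12) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  A <- adj
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A                     # l_ij (the u = i, j terms vanish: diag 0)
  den <- outer(k, k, pmin) + 1 - A
  stopifnot(all(den > 0))
  tomv <- (L + A) / den
  diag(tomv) <- 1
  tomv <- (tomv + t(tomv)) / 2
  tomv[tomv < 0] <- 0
  tomv[tomv > 1] <- 1
  tomv
}

#' TOM dissimilarity
#'
#' @param tom TOM matrix from \code{\link{tom_matrix}}.
#' @return 1 - TOM with an exactly zero diagonal.
#' @export
tom_dissimilarity <- function(tom) {
  d <- 1 - tom
  diag(d) <- 0
  d
}
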