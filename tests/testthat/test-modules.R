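two_block_diss <- function(n1 = 3, n2 = 3) {
  n <- n1 + n2
  d <- matrix(1, n, n)
  d[seq_len(n1), seq_len(n1)] <- 0
  d[(n1 + 1):n, (n1 + 1):n] <- 0
  diag(d) <- 0
  dimnames(d) <- list(paste0("f", 1:n), paste0("f", 1:n))
  d
}

test_that("average linkage reproduces a naive UPGMA on fixtures", {
  d <- two_block_diss()
  hc <- average_linkage(d)
  expect_equal(max(hc$height), 1)

  set.seed(14)
  pts <- matrix(rnorm(10), 5, 2)
  dm <- as.matrix(dist(pts))
  hc2 <- average_linkage(dm)
  expect_equal(sort(hc2$height), naive_upgma_heights(dm), tolerance = 1e-12)
})

test_that("average linkage heights are invariant under leaf permutation", {
  set.seed(15)
  pts <- matrix(rnorm(16), 8, 2)
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(paste0("f", 1:8), paste0("f", 1:8))
  perm <- sample(8)
  h1 <- sort(average_linkage(dm)$height)
  h2 <- sort(average_linkage(dm[perm, perm])$height)
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("average linkage rejects asymmetric or non-zero-diagonal input", {
  d <- two_block_diss()
  d[1, 2] <- 0.5
  expect_error(average_linkage(d), "symmetric")
  d2 <- two_block_diss()
  diag(d2) <- 0.1
  expect_error(average_linkage(d2), "diagonal")
})

test_that("dynamic cut recovers planted modules and leaves noise grey", {
  for (s in 1:2) {
    g <- generate_expression(reference_design(s))
    asn <- detect_modules(g$expression)
    expect_identical(length(setdiff(unique(asn), "grey")), 5L)
    expect_gte(ari(g$truth$labels, asn), 0.9)
    # background noise features stay in the grey bucket
    bg <- names(g$truth$labels)[g$truth$labels == 0]
    expect_gte(mean(asn[bg] == "grey"), 0.9)
  }
})

test_that("dynamic cut degenerate paths: oversized min_size and pure noise", {
  d <- two_block_diss()
  hc <- average_linkage(d)
  expect_warning(a <- dynamic_cut(hc, d, min_size = 10), "grey")
  expect_true(all(a == "grey"))

  set.seed(31)
  noise <- matrix(rnorm(60 * 30), 60, 30,
                  dimnames = list(paste0("m", 1:60), paste0("S", 1:30)))
  asn <- suppressWarnings(detect_modules(noise))
  planted <- rep(0L, 60)
  expect_lt(abs(ari(planted, asn)), 0.1)
})

test_that("anti-correlated planted members land in the same module", {
  des <- synthetic_design(n_samples = 60, module_sizes = c(12, 10),
                          loading = 0.85, n_background = 10,
                          neg_loading_frac = 0.3, seed = 5)
  g <- generate_expression(des)
  asn <- suppressWarnings(detect_modules(g$expression))
  for (m in 1:2) {
    members <- names(g$truth$labels)[g$truth$labels == m]
    pos <- members[g$truth$loadings[members] > 0]
    neg <- members[g$truth$loadings[members] < 0]
    expect_gt(length(neg), 0)
    # the dominant colour of the positive side must also host the negatives
    col <- names(which.max(table(asn[pos])))
    expect_true(all(asn[neg] == col))
  }
})

test_that("module detection is deterministic", {
  g <- generate_expression(reference_design(3))
  expect_identical(detect_modules(g$expression), detect_modules(g$expression))
})

test_that("eigengene of a rank-1 module is the standardized profile", {
  prof <- rnorm(10)
  expr <- rbind(a = prof, b = prof, c = prof)
  colnames(expr) <- paste0("S", 1:10)
  eg <- module_eigengene(expr, c("a", "b", "c"))
  expect_equal(eg$variance_explained, 1)
  zp <- as.numeric(scale(prof))
  expect_equal(abs(cor(eg$eigengene, zp)), 1, tolerance = 1e-12)
  expect_gt(cor(eg$eigengene, zp), 0)  # sign aligned to the mean profile

  singleton <- module_eigengene(expr, "a")
  expect_equal(singleton$variance_explained, 1)
  expect_equal(singleton$eigengene, eg$eigengene, tolerance = 1e-12)
})

test_that("eigengene recovers a planted factor at loading 0.9", {
  des <- synthetic_design(n_samples = 50, module_sizes = 10, loading = 0.9,
                          neg_loading_frac = 0, seed = 2)
  g <- generate_expression(des)
  eg <- module_eigengene(g$expression, rownames(g$expression))
  expect_gte(abs(cor(eg$eigengene, g$truth$factors[1, ])), 0.95)
})

test_that("eigengene guards: zero-variance members and unknown ids", {
  expr <- rbind(a = rnorm(6), b = rep(1, 6), c = rnorm(6))
  colnames(expr) <- paste0("S", 1:6)
  expect_warning(eg <- module_eigengene(expr, c("a", "b")), "b")
  expect_identical(eg$members, "a")
  expect_error(suppressWarnings(module_eigengene(expr, "b")), "no members")
  expect_error(module_eigengene(expr, "zz"), "zz")
})

test_that("modules with identical eigengenes merge; independent ones do not", {
  set.seed(8)
  n <- 100
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- rbind(t(replicate(6, f1 + 0.1 * rnorm(n))),
             t(replicate(6, f1 + 0.1 * rnorm(n))),
             t(replicate(6, f2 + 0.1 * rnorm(n))))
  rownames(X) <- paste0("f", 1:18)
  colnames(X) <- paste0("S", 1:n)
  asn <- stats::setNames(rep(c("blue", "brown", "turquoise"), each = 6),
                         rownames(X))
  merged <- merge_close_modules(X, asn)$assignment
  mods <- setdiff(unique(merged), "grey")
  expect_identical(length(mods), 2L)
  # the two f1-driven modules fused, the f2 module stayed apart
  expect_identical(length(unique(merged[1:12])), 1L)
  expect_false(merged[13] == merged[1])
})

test_that("merging respects the similarity threshold on a planted hierarchy", {
  set.seed(42)
  n <- 200
  parent <- rnorm(n)
  f1 <- sqrt(0.9) * parent + sqrt(0.1) * rnorm(n)
  f2 <- sqrt(0.9) * parent + sqrt(0.1) * rnorm(n)   # cor(f1, f2) ~ 0.9
  X <- rbind(t(replicate(10, 0.95 * f1 + sqrt(1 - 0.95^2) * rnorm(n))),
             t(replicate(10, 0.95 * f2 + sqrt(1 - 0.95^2) * rnorm(n))))
  rownames(X) <- paste0("f", 1:20)
  colnames(X) <- paste0("S", 1:n)
  asn <- stats::setNames(rep(c("blue", "brown"), each = 10), rownames(X))
  expect_identical(
    length(setdiff(unique(merge_close_modules(X, asn, 0.75)$assignment),
                   "grey")), 1L)
  expect_identical(
    length(setdiff(unique(merge_close_modules(X, asn, 0.95)$assignment),
                   "grey")), 2L)
})

test_that("colour assignment follows the canonical size order", {
  expect_identical(assign_colors(c(46, 30, 5)),
                   c("turquoise", "blue", "brown"))
  expect_identical(assign_colors(integer(0)), character(0))
  # ties broken by first-seen order
  expect_identical(assign_colors(c(10, 10, 20)),
                   c("blue", "brown", "turquoise"))
  # overflow past the palette gets indexed labels
  many <- assign_colors(rep(5, 40))
  expect_identical(anyDuplicated(many), 0L)
  expect_true(any(grepl("^module", many)))
  expect_false("grey" %in% many)
})
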