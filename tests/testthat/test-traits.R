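test_that("correlation test matches the Student transform and cor.test", {
  x <- rnorm(12, sd = 2) + 1:12
  expect_equal(correlation_test(x, x), list(r = 1, p = 0, n_used = 12))

  pair <- exact_cor_pair(20, -0.59)
  res <- correlation_test(pair$x, pair$y)
  expect_equal(res$r, -0.59, tolerance = 1e-12)
  # t = -3.10 on 18 df -> p ~ 0.006 (0.007 after coarser rounding)
  expect_equal(res$p, 0.00617, tolerance = 1e-3)
  ref <- stats::cor.test(pair$x, pair$y)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)

  set.seed(77)
  a <- rnorm(15); b <- rnorm(15); b[c(2, 9)] <- NA
  res2 <- correlation_test(a, b)
  expect_identical(res2$n_used, 13L)
  expect_equal(res2$p,
               stats::cor.test(a[!is.na(b)], b[!is.na(b)])$p.value,
               tolerance = 1e-12)
})

test_that("correlation test matches a permutation null on a small fixture", {
  set.seed(123)
  x <- rnorm(10)
  y <- 0.5 * x + rnorm(10)
  res <- correlation_test(x, y)
  nperm <- 4000
  robs <- abs(cor(x, y))
  rperm <- replicate(nperm, abs(cor(x, sample(y))))
  pperm <- (1 + sum(rperm >= robs)) / (nperm + 1)
  expect_lt(abs(res$p - pperm), 3 * sqrt(pperm * (1 - pperm) / nperm) + 0.005)
})

test_that("correlation test guards its preconditions", {
  expect_error(correlation_test(1:2, 2:1), "3 complete pairs")
  expect_error(correlation_test(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(correlation_test(1:4, 1:5), "equal length")
})

test_that("module-trait matrix recovers planted trait links", {
  des <- synthetic_design(
    n_samples = 100, module_sizes = c(15, 12), loading = 0.85,
    neg_loading_frac = 0,
    trait_links = list(list(trait = "marker", module = 1, rho = 0.6)),
    n_noise_traits = 1, seed = 6)
  g <- generate_expression(des)
  traits <- generate_traits(g$truth)
  asn <- stats::setNames(
    c("turquoise", "blue")[pmax(g$truth$labels, 1)], names(g$truth$labels))
  eig <- module_eigengenes(g$expression, asn)
  mt <- module_trait_matrix(eig, traits)
  hit <- mt[mt$module == "turquoise" & mt$trait == "marker", ]
  expect_lt(abs(abs(hit$r) - 0.6), 0.15)
  # direct-correlation oracle: eigengene vs trait, computed independently
  expect_equal(hit$r, cor(eig$eigengenes[, "turquoise"], traits[, "marker"]),
               tolerance = 1e-12)
})

test_that("module-trait matrix handles self-trait, NAs, and degenerate traits", {
  set.seed(4)
  expr <- matrix(rnorm(8 * 20), 8, 20,
                 dimnames = list(paste0("m", 1:8), paste0("S", 1:20)))
  asn <- stats::setNames(rep(c("turquoise", "blue"), each = 4),
                         rownames(expr))
  eig <- module_eigengenes(expr, asn)
  traits <- cbind(me_copy = eig$eigengenes[, "turquoise"],
                  other = rnorm(20))
  rownames(traits) <- colnames(expr)
  mt <- module_trait_matrix(eig, traits)
  expect_equal(mt[mt$module == "turquoise" & mt$trait == "me_copy", "r"], 1)
  traits2 <- cbind(traits, flat = 5)
  expect_error(module_trait_matrix(eig, traits2), "flat")
  mtadj <- module_trait_matrix(eig, traits, adjust = "BH")
  expect_equal(mtadj$p_adj, stats::p.adjust(mtadj$p, "BH"))
})

test_that("module-trait matrix is equivariant under joint sample permutation", {
  set.seed(19)
  expr <- matrix(rnorm(10 * 15), 10, 15,
                 dimnames = list(paste0("m", 1:10), paste0("S", 1:15)))
  asn <- stats::setNames(rep(c("turquoise", "blue"), each = 5),
                         rownames(expr))
  eig <- module_eigengenes(expr, asn)
  traits <- matrix(rnorm(30), 15, 2,
                   dimnames = list(colnames(expr), c("t1", "t2")))
  perm <- sample(15)
  eg2 <- eig$eigengenes[perm, ]
  mt1 <- module_trait_matrix(eig$eigengenes, traits)
  mt2 <- module_trait_matrix(eg2, traits[perm, ])
  expect_equal(mt1, mt2, tolerance = 1e-12)
})

test_that("GS/MM behaves on planted data and guards the grey module", {
  des <- synthetic_design(
    n_samples = 60, module_sizes = 12, loading = 0.85,
    neg_loading_frac = 0.25,
    trait_links = list(list(trait = "survival", module = 1, rho = -0.6)),
    seed = 9)
  g <- generate_expression(des)
  traits <- generate_traits(g$truth)
  asn <- stats::setNames(rep("turquoise", 12), rownames(g$expression))
  eig <- module_eigengenes(g$expression, asn)
  res <- gs_mm(g$expression, asn, eig, traits[, "survival"], "turquoise")
  expect_true(!is.unsorted(res$table$gs_p))
  # positive-loading members inherit the negative trait link, and vice versa
  pos_load <- res$table$feature_id %in%
    names(g$truth$loadings)[g$truth$loadings > 0]
  expect_lt(mean(res$table$gs_r[pos_load]), 0)
  expect_gt(mean(res$table$gs_r[!pos_load]), 0)
  expect_error(
    gs_mm(g$expression, asn, eig, traits[, "survival"], "grey"), "grey")
})

test_that("members identical to the eigengene have unit module membership", {
  prof <- rnorm(12)
  expr <- rbind(a = prof, b = prof, c = prof, d = prof)
  colnames(expr) <- paste0("S", 1:12)
  asn <- stats::setNames(rep("turquoise", 4), rownames(expr))
  eig <- module_eigengenes(expr, asn)
  trait <- rnorm(12)
  # all mm_r identical, so the GS-MM correlation is degenerate and flagged
  expect_warning(res <- gs_mm(expr, asn, eig, trait, "turquoise"),
                 "GS-MM correlation undefined")
  expect_equal(res$table$mm_r, rep(1, 4), tolerance = 1e-12)
  expect_true(is.na(res$gs_mm_cor$r))
})

test_that("candidate ranking splits by sign and sorts by GS p-value", {
  tab <- data.frame(feature_id = paste0("m", 1:4),
                    gs_r = c(0.9, 0.8, -0.7, -0.85),
                    gs_p = c(0.01, 0.02, 0.03, 0.04),
                    mm_r = 0.5, mm_p = 0.1)
  rc <- rank_candidates(tab, k = 2)
  expect_identical(rc$positive$feature_id, c("m1", "m2"))
  expect_identical(rc$negative$feature_id, c("m3", "m4"))

  all_pos <- tab[tab$gs_r > 0, ]
  expect_warning(rc2 <- rank_candidates(all_pos, k = 2), "negatively")
  expect_identical(nrow(rc2$negative), 0L)

  # brute-force sort oracle on a 16-member module-like table
  set.seed(33)
  big <- data.frame(feature_id = sprintf("miR-%02d", 1:16),
                    gs_r = runif(16, -1, 1), gs_p = runif(16),
                    mm_r = runif(16, -1, 1), mm_p = runif(16))
  rc3 <- rank_candidates(big, k = 3)
  pos <- big[big$gs_r > 0, ]
  pos <- pos[order(pos$gs_p, -abs(pos$gs_r), pos$feature_id), ]
  expect_identical(rc3$positive$feature_id, head(pos$feature_id, 3))
})
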