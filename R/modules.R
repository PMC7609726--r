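# Module detection from the TOM dissimilarity: average-linkage
# dendrogram, deterministic dynamic branch cut with a minimum module
# size and a PAM-like rescue step, module eigengenes, and merging of
# modules with highly correlated eigengenes.

#' Average-linkage (UPGMA) clustering of a dissimilarity matrix
#'
#' @param diss Square symmetric dissimilarity matrix with zero diagonal
#'   (typically \code{\link{tom_dissimilarity}} output).
#' @return An \code{hclust} object.
#' @export
average_linkage <- function(diss) {
  diss <- as.matrix(diss)
  .check_square_symmetric(diss, what = "dissimilarity")
  if (any(abs(diag(diss)) > 1e-8)) {
    stop("dissimilarity diagonal must be zero", call. = FALSE)
  }
  stats::hclust(stats::as.dist(diss), method = "average")
}

#' Deterministic dynamic branch cut
#'
#' Detects modules by analysing the branch structure of an
#' average-linkage dendrogram of the TOM dissimilarity, rather than by
#' cutting at one fixed height.  Every subtree is a candidate branch; a
#' branch qualifies as a module when (a) it has at least
#' \code{min_size} leaves and (b) it detaches from the rest of the tree
#' well above its own top internal merge: the gap between the height at
#' which the branch joins its parent and the branch's own merge height,
#' normalised by the dendrogram height range (maximum merge height
#' minus its 5th percentile), must reach \code{min_gap}.  The
#' normalisation makes the criterion invariant to the strong
#' compression of the 1 - TOM scale at high soft-thresholding powers.
#' Modules are the maximal qualifying branches; all other leaves go to
#' "grey" (unassigned).  If \code{pam_stage}, each grey leaf is then
#' reassigned to the module with the smallest average dissimilarity to
#' its members, provided that average is below the grand mean of all
#' within-module dissimilarities.  Module colours are assigned by
#' decreasing size from \code{\link{module_palette}}.  The procedure
#' contains no randomness.  Over-split fragments of one underlying
#' module are re-fused downstream by \code{\link{merge_close_modules}}.
#'
#' @param dendro \code{hclust} object from \code{\link{average_linkage}}.
#' @param diss The dissimilarity matrix the dendrogram was built from.
#' @param min_size Minimum module size (default 5, suited to the small
#'   miRNA transcriptome).
#' @param min_gap Minimum normalised detachment gap for a branch to
#'   qualify (default 0.02); pure-noise branches sit an order of
#'   magnitude below this, cohesive modules an order above.
#' @param pam_stage Run the grey-leaf rescue step (default TRUE).
#' @return Named character vector: feature id -> module colour, with
#'   "grey" for unassigned features.
#' @export
dynamic_cut <- function(dendro, diss, min_size = 5, min_gap = 0.02,
                        pam_stage = TRUE) {
  if (min_size < 2) stop("min_size must be >= 2", call. = FALSE)
  n <- length(dendro$order)
  ids <- dendro$labels %||% as.character(seq_len(n))
  lab <- stats::setNames(rep("grey", n), ids)
  if (min_size > n) {
    warning("min_size exceeds the number of features; all features grey",
            call. = FALSE)
    return(lab)
  }
  nm <- n - 1L
  h <- dendro$height
  rng <- max(h) - stats::quantile(h, 0.05, names = FALSE)
  if (rng <= 0) {
    warning("degenerate dendrogram (all merge heights equal); ",
            "all features grey", call. = FALSE)
    return(lab)
  }
  # leaves under each internal node, and each node's parent height
  members <- vector("list", nm)
  parent_h <- rep(NA_real_, nm)
  for (i in seq_len(nm)) {
    ch <- dendro$merge[i, ]
    members[[i]] <- c(if (ch[1L] < 0) -ch[1L] else members[[ch[1L]]],
                      if (ch[2L] < 0) -ch[2L] else members[[ch[2L]]])
    for (cc in ch) if (cc > 0) parent_h[cc] <- h[i]
  }
  gap <- (parent_h - h) / rng              # NA at the root
  qualifies <- lengths(members) >= min_size & !is.na(gap) & gap >= min_gap
  branch <- integer(n)                     # 0 = unassigned
  for (i in rev(seq_len(nm))) {            # ancestors first: maximal branches
    if (qualifies[i] && all(branch[members[[i]]] == 0L)) {
      branch[members[[i]]] <- i
    }
  }
  mod_codes <- sort(unique(branch[branch > 0L]))
  if (!length(mod_codes)) {
    warning("no branch qualified as a module; all features grey",
            call. = FALSE)
    return(lab)
  }
  diss <- as.matrix(diss)
  if (!is.null(rownames(diss))) diss <- diss[ids, ids]
  if (pam_stage) {
    branch0 <- branch                      # membership before any rescue
    within <- unlist(lapply(mod_codes, function(m) {
      d <- diss[branch0 == m, branch0 == m, drop = FALSE]
      d[upper.tri(d)]
    }))
    grand <- mean(within)
    for (g in which(branch0 == 0L)) {
      avg <- vapply(mod_codes,
                    function(m) mean(diss[g, branch0 == m]), 0)
      best <- which.min(avg)
      if (avg[best] < grand) branch[g] <- mod_codes[best]
    }
  }
  final_sizes <- vapply(mod_codes, function(m) sum(branch == m), 0L)
  colors <- assign_colors(final_sizes)
  for (i in seq_along(mod_codes)) {
    lab[branch == mod_codes[i]] <- colors[i]
  }
  lab
}

#' Assign canonical colours to modules by decreasing size
#'
#' Largest module gets the first palette colour ("turquoise"), and so on.
#' Ties are broken by first-seen order, so the labelling is
#' deterministic.  If there are more modules than palette colours, the
#' overflow is labelled "module<k>".
#'
#' @param sizes Integer vector of per-module sizes.
#' @return Character vector of colour labels, parallel to \code{sizes}.
#' @export
assign_colors <- function(sizes) {
  if (!length(sizes)) return(character(0))
  pal <- module_palette()
  pool <- if (length(sizes) > length(pal)) {
    c(pal, paste0("module", seq.int(length(pal) + 1L, length(sizes))))
  } else pal
  ord <- order(-sizes)   # stable: equal sizes keep first-seen order
  labels <- character(length(sizes))
  labels[ord] <- pool[seq_along(sizes)]
  labels
}

#' Module eigengene
#'
#' First principal component of the module's standardized expression:
#' member features are standardized to zero mean and unit variance
#' across samples, and the eigengene is the first right-singular vector
#' of the resulting members x samples matrix (one value per sample, unit
#' norm).  The sign is aligned so the eigengene correlates positively
#' with the mean standardized member profile, making module-trait
#' correlation signs reproducible.  Variance explained is the first
#' squared singular value over the total.
#'
#' @param expr Expression matrix, features x samples.
#' @param members Character vector of member feature ids (>= 1).
#' @return List with \code{eigengene} (named numeric vector over
#'   samples), \code{variance_explained} in [0, 1] and \code{members}
#'   actually used.
#' @export
module_eigengene <- function(expr, members) {
  expr <- as.matrix(expr)
  if (!length(members)) stop("empty module", call. = FALSE)
  missing <- setdiff(members, rownames(expr))
  if (length(missing)) {
    stop("unknown feature id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (ncol(expr) < 3L) stop("at least 3 samples required", call. = FALSE)
  X <- expr[members, , drop = FALSE]
  sds <- apply(X, 1L, stats::sd, na.rm = TRUE)
  drop <- is.na(sds) | sds == 0
  if (any(drop)) {
    warning("zero-variance member(s) dropped: ",
            paste(rownames(X)[drop], collapse = ", "), call. = FALSE)
    X <- X[!drop, , drop = FALSE]
  }
  if (!nrow(X)) stop("no members left after dropping zero-variance features",
                     call. = FALSE)
  Xs <- t(scale(t(X)))
  Xs[is.na(Xs)] <- 0               # mean-impute isolated missing values
  sv <- svd(Xs)
  v1 <- sv$v[, 1L]
  varexp <- sv$d[1L]^2 / sum(sv$d^2)
  mp <- colMeans(Xs)
  al <- suppressWarnings(stats::cor(v1, mp))
  if (is.na(al) || al == 0) al <- sum(sv$u[, 1L])
  if (al < 0) v1 <- -v1
  names(v1) <- colnames(expr)
  list(eigengene = v1, variance_explained = varexp, members = rownames(X))
}

#' Eigengenes for every (non-grey) module
#'
#' @param expr Expression matrix, features x samples.
#' @param assignment Named character vector, feature id -> module colour.
#' @param exclude_grey Skip the unassigned bucket (default TRUE).
#' @return List with \code{eigengenes} (samples x modules matrix, columns
#'   ordered by decreasing module size), \code{variance_explained} and
#'   \code{sizes} (both named by module colour).
#' @export
module_eigengenes <- function(expr, assignment, exclude_grey = TRUE) {
  mods <- unique(assignment)
  if (exclude_grey) mods <- setdiff(mods, "grey")
  if (!length(mods)) stop("no modules to summarise", call. = FALSE)
  sizes <- vapply(mods, function(m) sum(assignment == m), 0L)
  mods <- mods[order(-sizes, mods)]
  sizes <- sizes[order(-sizes, names(sizes))]
  egs <- lapply(mods, function(m) {
    module_eigengene(expr, names(assignment)[assignment == m])
  })
  E <- vapply(egs, `[[`, numeric(ncol(expr)), "eigengene")
  dimnames(E) <- list(colnames(expr), mods)
  list(eigengenes = E,
       variance_explained = stats::setNames(
         vapply(egs, `[[`, 0, "variance_explained"), mods),
       sizes = sizes)
}

#' Merge modules with highly correlated eigengenes
#'
#' Iterates until stable: compute eigengenes, cluster them by average
#' linkage on the dissimilarity 1 - cor(ME_a, ME_b), and fuse every
#' group of modules linked below 1 - \code{similarity_threshold} (the
#' conventional merge-cut-height reading of "similarity higher than
#' 75\%").  Grey is never merged.  Final labels are re-assigned by
#' decreasing module size.
#'
#' @param expr Expression matrix, features x samples.
#' @param assignment Named character vector, feature id -> module colour.
#' @param similarity_threshold Eigengene correlation above which modules
#'   merge (default 0.75).
#' @return List with the merged \code{assignment} and the final
#'   \code{eigengenes} (as from \code{\link{module_eigengenes}}).
#' @export
merge_close_modules <- function(expr, assignment,
                                similarity_threshold = 0.75) {
  if (similarity_threshold <= 0 || similarity_threshold >= 1) {
    stop("similarity_threshold must lie in (0, 1)", call. = FALSE)
  }
  repeat {
    mods <- setdiff(unique(assignment), "grey")
    if (length(mods) < 2L) break
    ME <- module_eigengenes(expr, assignment)$eigengenes
    d <- 1 - stats::cor(ME)
    d[d < 0] <- 0
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(hc, h = 1 - similarity_threshold)
    if (max(tabulate(grp)) == 1L) break
    for (g in unique(grp)) {
      members <- colnames(ME)[grp == g]
      if (length(members) > 1L) {
        # ME columns are ordered by decreasing size: keep the largest label
        assignment[assignment %in% members] <- members[1L]
      }
    }
  }
  mods <- setdiff(unique(assignment), "grey")
  eig <- NULL
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(assignment == m), 0L)
    map <- stats::setNames(assign_colors(sizes), mods)
    keep <- assignment != "grey"
    assignment[keep] <- map[assignment[keep]]
    eig <- module_eigengenes(expr, assignment)
  }
  list(assignment = assignment, eigengenes = eig)
}
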