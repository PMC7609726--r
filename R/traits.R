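# Module-trait correlation and hub-candidate ranking by gene
# significance (GS, feature vs trait) and module membership (MM, feature
# vs module eigengene).

#' Pearson correlation with a Student-t p-value
#'
#' Correlation over complete pairs; the two-sided p-value comes from
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.  A
#' numerically perfect correlation (|r| = 1) reports p = 0.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs; no
#'   zero variance).
#' @return List with \code{r}, \code{p} and \code{n_used}.
#' @export
correlation_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  x <- x[ok]
  y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (1 - r^2 < 1e-14) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n_used = n)
}

#' Module-trait correlation matrix (long form)
#'
#' Correlates every module eigengene with every clinical trait on the
#' shared samples, with missing trait values handled pairwise.  Raw
#' p-values are reported by default; set \code{adjust = "BH"} to add a
#' Benjamini-Hochberg column (many modules x many traits invites false
#' positives, so the adjusted view is worth inspecting even when module
#' selection uses the raw cut-off).
#'
#' @param eigengenes Samples x modules matrix, or the list returned by
#'   \code{\link{module_eigengenes}}.
#' @param traits Samples x traits numeric matrix with sample rownames.
#' @param adjust "none" (default) or "BH".
#' @return data.frame with columns module, trait, r, p, n_used (and
#'   p_adj when requested).
#' @export
module_trait_matrix <- function(eigengenes, traits, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.list(eigengenes) && !is.data.frame(eigengenes)) {
    eigengenes <- eigengenes$eigengenes
  }
  traits <- as.matrix(traits)
  shared <- intersect(rownames(eigengenes), rownames(traits))
  if (length(shared) < 3L) {
    stop("fewer than 3 shared samples between eigengenes and traits",
         call. = FALSE)
  }
  E <- eigengenes[shared, , drop = FALSE]
  Tm <- traits[shared, , drop = FALSE]
  rows <- list()
  for (m in colnames(E)) {
    for (tr in colnames(Tm)) {
      res <- tryCatch(correlation_test(E[, m], Tm[, tr]),
                      error = function(e) {
                        stop(sprintf("module '%s' vs trait '%s': %s",
                                     m, tr, conditionMessage(e)),
                             call. = FALSE)
                      })
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = tr, r = res$r, p = res$p, n_used = res$n_used)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Gene significance and module membership for one module
#'
#' For every member of the module: GS = correlation of its expression
#' with the trait (kept signed; the absolute value is the conventional
#' definition, but ranking positively and negatively trait-correlated
#' candidates separately needs the sign), and MM = correlation of its
#' expression with the module eigengene.  Also returns the GS-MM
#' correlation across members (the intramodular association statistic).
#'
#' @param expr Expression matrix, features x samples.
#' @param assignment Named character vector, feature id -> module colour.
#' @param eigengenes Samples x modules matrix or
#'   \code{\link{module_eigengenes}} output containing the module.
#' @param trait Numeric trait vector, either named by sample id or in
#'   expression column order.
#' @param module Module colour (non-grey).
#' @return List with \code{table} (data.frame feature_id, gs_r, gs_p,
#'   mm_r, mm_p, sorted by gs_p), \code{gs_mm_cor} (list r, p, n_used;
#'   NA and flagged when the module has fewer than 3 members) and
#'   \code{module}.
#' @export
gs_mm <- function(expr, assignment, eigengenes, trait, module) {
  if (identical(module, "grey")) {
    stop("the grey (unassigned) bucket is not a module", call. = FALSE)
  }
  if (is.list(eigengenes) && !is.data.frame(eigengenes)) {
    eigengenes <- eigengenes$eigengenes
  }
  members <- names(assignment)[assignment == module]
  if (!length(members)) stop("module '", module, "' not found", call. = FALSE)
  if (!module %in% colnames(eigengenes)) {
    stop("no eigengene for module '", module, "'", call. = FALSE)
  }
  expr <- as.matrix(expr)
  samples <- colnames(expr)
  if (!is.null(names(trait))) {
    trait <- trait[samples]
  } else if (length(trait) != length(samples)) {
    stop("trait length does not match the number of samples", call. = FALSE)
  }
  me <- eigengenes[samples, module]
  rows <- lapply(members, function(f) {
    gs <- correlation_test(expr[f, ], trait)
    mm <- correlation_test(expr[f, ], me)
    data.frame(feature_id = f, gs_r = gs$r, gs_p = gs$p,
               mm_r = mm$r, mm_p = mm$p)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$gs_p, -abs(tab$gs_r), tab$feature_id), ]
  rownames(tab) <- NULL
  gsmm <- if (nrow(tab) >= 3L) {
    tryCatch(correlation_test(tab$gs_r, tab$mm_r), error = function(e) {
      warning("GS-MM correlation undefined (", conditionMessage(e), ")",
              call. = FALSE)
      list(r = NA_real_, p = NA_real_, n_used = nrow(tab))
    })
  } else {
    warning("GS-MM correlation undefined for a module with < 3 members",
            call. = FALSE)
    list(r = NA_real_, p = NA_real_, n_used = nrow(tab))
  }
  list(table = tab, gs_mm_cor = gsmm, module = module)
}

#' Rank hub biomarker candidates within a module
#'
#' Splits the members by the sign of their gene significance and, within
#' each sign, orders by GS p-value ascending (ties: |GS| descending, then
#' feature id).  Returns the top k per sign; when fewer than k members of
#' a sign exist, what exists is returned with a warning.
#'
#' @param table The \code{table} component of \code{\link{gs_mm}} output
#'   (or the whole \code{gs_mm} list).
#' @param k Candidates per sign (default 2).
#' @return List with data.frames \code{positive} and \code{negative}.
#' @export
rank_candidates <- function(table, k = 2) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (is.list(table) && !is.data.frame(table)) table <- table$table
  ord <- order(table$gs_p, -abs(table$gs_r), table$feature_id)
  tab <- table[ord, , drop = FALSE]
  pos <- tab[tab$gs_r > 0, , drop = FALSE]
  neg <- tab[tab$gs_r < 0, , drop = FALSE]
  if (nrow(pos) < k) {
    warning(sprintf("only %d positively trait-correlated member(s)",
                    nrow(pos)), call. = FALSE)
  }
  if (nrow(neg) < k) {
    warning(sprintf("only %d negatively trait-correlated member(s)",
                    nrow(neg)), call. = FALSE)
  }
  list(positive = utils::head(pos, k), negative = utils::head(neg, k))
}
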