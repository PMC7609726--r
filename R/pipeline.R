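# End-to-end orchestration: network -> modules -> module-trait ->
# hub candidates -> optional qPCR/survival validation, with TSV/JSON
# outputs.  All analysis stages are deterministic; randomness lives only
# in the synthetic generators.

#' Pipeline configuration
#'
#' Collects the inputs and the tunable thresholds of the discovery and
#' validation pipeline.  Defaults: soft threshold chosen automatically
#' against a scale-free fit target of 0.80; minimum module size 5;
#' module merge at eigengene similarity 0.75; module selection at raw
#' correlation p < 0.05; 2 hub candidates per correlation sign;
#' overall-survival bins at 12 and 24 months.
#'
#' @param expression Path to an expression table or a features x samples
#'   matrix.
#' @param traits Optional path or samples x traits matrix.
#' @param qpcr Optional qPCR Cq table (path, data.frame, or a named list
#'   of them, one per candidate assay).
#' @param survival Optional survival table (path or data.frame with
#'   sample_id, time, event).
#' @param beta "auto" or a fixed integer power.
#' @param target_r2 Scale-free fit target used when beta = "auto".
#' @param candidate_betas Powers swept when beta = "auto".
#' @param min_module_size Minimum branch size kept as a module.
#' @param merge_similarity Eigengene correlation above which modules
#'   merge.
#' @param module_p_cutoff Raw p-value cut-off for calling a module
#'   trait-associated.
#' @param candidate_k Hub candidates reported per correlation sign.
#' @param os_bins Two OS boundaries in months.
#' @param trait_of_interest Trait used to pick the hub module.
#' @param module_of_interest Optional explicit module colour overriding
#'   the trait-based choice.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @param seed Seed recorded in outputs (the analysis itself is
#'   deterministic).
#' @param delimiter Optional delimiter override for file inputs.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(expression, traits = NULL, qpcr = NULL,
                            survival = NULL, beta = "auto",
                            target_r2 = 0.80, candidate_betas = 1:20,
                            min_module_size = 5,
                            merge_similarity = 0.75,
                            module_p_cutoff = 0.05, candidate_k = 2,
                            os_bins = c(12, 24),
                            trait_of_interest = "survival",
                            module_of_interest = NULL, out_dir = NULL,
                            seed = 1, delimiter = NULL) {
  if (!identical(beta, "auto") &&
      (!is.numeric(beta) || beta < 1 || beta != round(beta))) {
    stop("beta must be \"auto\" or an integer >= 1", call. = FALSE)
  }
  stopifnot(target_r2 > 0, target_r2 <= 1,
            min_module_size >= 2,
            merge_similarity > 0, merge_similarity < 1,
            module_p_cutoff > 0, module_p_cutoff <= 1,
            candidate_k >= 1,
            length(os_bins) == 2, os_bins[1] < os_bins[2])
  structure(list(expression = expression, traits = traits, qpcr = qpcr,
                 survival = survival, beta = beta, target_r2 = target_r2,
                 candidate_betas = candidate_betas,
                 min_module_size = min_module_size,
                 merge_similarity = merge_similarity,
                 module_p_cutoff = module_p_cutoff,
                 candidate_k = candidate_k, os_bins = os_bins,
                 trait_of_interest = trait_of_interest,
                 module_of_interest = module_of_interest,
                 out_dir = out_dir, seed = seed, delimiter = delimiter),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  message(sprintf("[stage:%s]", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.as_expression <- function(x, delimiter) {
  if (is.character(x) && length(x) == 1L) read_expression(x, delimiter)
  else validate_expression(as.matrix(x))
}

.as_traits <- function(x, delimiter) {
  if (is.character(x) && length(x) == 1L) read_trait_table(x, delimiter)
  else as.matrix(x)
}

#' Run the full discovery (and optional validation) pipeline
#'
#' Executes similarity -> soft-threshold selection -> adjacency -> TOM
#' -> average-linkage dendrogram -> dynamic branch cut -> module merging
#' -> module-trait correlation -> hub-module selection -> GS/MM ranking
#' of hub candidates, and, when Cq and survival tables are provided, the
#' validation statistics (relative expression, OS-bin comparisons with
#' pairwise Mann-Whitney plus a Kruskal-Wallis omnibus, dichotomised
#' Kaplan-Meier with log-rank and hazard ratio).  When
#' \code{config$out_dir} is set, every table is written as TSV alongside
#' a machine-readable \code{summary.json} that records all applied
#' settings, so a run is reconstructible from the summary alone.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return The summary list, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  expr <- .stage("input", {
    e <- .as_expression(config$expression, config$delimiter)
    flat <- attr(e, "constant_features")
    if (length(flat)) {
      message("dropping ", length(flat), " constant feature(s)")
      e <- e[setdiff(rownames(e), flat), , drop = FALSE]
    }
    e
  })

  sim <- .stage("similarity", similarity_matrix(expr))

  fit_table <- NULL
  beta <- config$beta
  if (identical(beta, "auto")) {
    st <- .stage("soft_threshold",
                 pick_soft_threshold(sim, config$candidate_betas,
                                     config$target_r2))
    beta <- st$beta
    fit_table <- st$fits
  }

  adj <- .stage("adjacency", adjacency_matrix(sim, beta))
  tomv <- .stage("tom", tom_matrix(adj))
  diss <- tom_dissimilarity(tomv)
  dend <- .stage("dendrogram", average_linkage(diss))
  assign0 <- .stage("dynamic_cut",
                    dynamic_cut(dend, diss, config$min_module_size))
  merged <- .stage("merge_modules", {
    if (all(assign0 == "grey")) stop("no modules detected")
    merge_close_modules(expr, assign0, config$merge_similarity)
  })

  summary <- list(
    settings = config[c("beta", "target_r2", "min_module_size",
                        "merge_similarity",
                        "module_p_cutoff", "candidate_k", "os_bins",
                        "trait_of_interest", "seed")],
    beta = beta,
    n_features = nrow(expr),
    n_samples = ncol(expr),
    n_modules = length(setdiff(unique(merged$assignment), "grey")),
    n_grey = sum(merged$assignment == "grey"),
    module_sizes = as.list(merged$eigengenes$sizes))

  mt <- target_module <- hub <- candidates <- NULL
  if (!is.null(config$traits)) {
    traits <- .stage("traits", .as_traits(config$traits, config$delimiter))
    mt <- .stage("module_trait", module_trait_matrix(merged$eigengenes,
                                                     traits))
    sig <- unique(mt$module[mt$p < config$module_p_cutoff])
    summary$significant_modules <- sig

    target_module <- config$module_of_interest
    ti <- config$trait_of_interest
    if (is.null(target_module)) {
      cand_rows <- mt[mt$trait == ti, , drop = FALSE]
      if (!nrow(cand_rows)) {
        stop("trait of interest '", ti, "' not found in the trait table",
             call. = FALSE)
      }
      in_sig <- cand_rows$module %in% sig
      if (any(in_sig)) cand_rows <- cand_rows[in_sig, , drop = FALSE]
      else message("no module passes the p cut-off for '", ti,
                   "'; using the smallest p overall")
      target_module <- cand_rows$module[which.min(cand_rows$p)]
    }
    summary$target_module <- target_module
    summary$target_module_trait <- as.list(
      mt[mt$module == target_module & mt$trait == ti,
         c("r", "p", "n_used")])

    hub <- .stage("gs_mm",
                  gs_mm(expr, merged$assignment, merged$eigengenes,
                        traits[colnames(expr), ti], target_module))
    candidates <- .stage("rank_candidates",
                         rank_candidates(hub$table, config$candidate_k))
    summary$gs_mm_cor <- hub$gs_mm_cor
    summary$candidates <- list(
      positive = candidates$positive$feature_id,
      negative = candidates$negative$feature_id)
  } else {
    message("no trait table supplied; module-trait stage skipped")
  }

  validation <- NULL
  if (!is.null(config$qpcr) && !is.null(config$survival)) {
    validation <- .stage("validation", {
      surv <- if (is.character(config$survival)) {
        read_survival_table(config$survival, config$delimiter)
      } else config$survival
      qlist <- config$qpcr
      if (!is.list(qlist) || is.data.frame(qlist) || is.character(qlist)) {
        qlist <- list(candidate = qlist)
      }
      lapply(qlist, function(q) {
        if (is.character(q)) q <- read_qpcr_table(q, config$delimiter)
        rel <- relative_expression(q)
        dat <- merge(rel, surv, by = "sample_id")
        osg <- split_by_os(dat$time, config$os_bins)
        lv <- levels(osg)
        pairwise <- list()
        for (i in 1:2) for (j in (i + 1):3) {
          a <- dat$relative_expression[osg == lv[i]]
          b <- dat$relative_expression[osg == lv[j]]
          if (length(a) && length(b)) {
            mw <- mann_whitney(a, b)
            fold <- mean(b) / mean(a)
            pairwise[[paste(lv[i], "vs", lv[j])]] <-
              list(U = mw$U, p = mw$p, fold_change = fold)
          }
        }
        omnibus <- if (nlevels(droplevels(osg)) >= 2) {
          kw <- stats::kruskal.test(dat$relative_expression,
                                    droplevels(osg))
          list(statistic = unname(kw$statistic), p = kw$p.value)
        }
        dic <- dichotomize(stats::setNames(dat$relative_expression,
                                           dat$sample_id))
        lr <- log_rank(dat$time, dat$event, dic$group)
        km <- lapply(split(seq_len(nrow(dat)), dic$group), function(idx) {
          kaplan_meier(dat$time[idx], dat$event[idx])
        })
        list(relative_expression = rel, os_groups = table(osg),
             pairwise = pairwise, omnibus = omnibus,
             cutoff = dic$cutoff, log_rank = lr, km = km)
      })
    })
    summary$validation <- lapply(validation, function(v) {
      list(cutoff = v$cutoff,
           log_rank_p = v$log_rank$p,
           hazard_ratio = v$log_rank$hazard_ratio,
           ci = c(v$log_rank$ci_lower, v$log_rank$ci_upper),
           pairwise = v$pairwise,
           omnibus = v$omnibus)
    })
  } else if (!is.null(config$qpcr) || !is.null(config$survival)) {
    message("validation stage skipped: both a Cq table and a survival ",
            "table are required")
  }

  if (!is.null(config$out_dir)) {
    .stage("write_outputs", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      out <- function(f) file.path(config$out_dir, f)
      write_module_assignment(merged$assignment, out("modules.tsv"),
                              seed = config$seed)
      eg <- merged$eigengenes$eigengenes
      .write_with_header(data.frame(sample_id = rownames(eg), eg,
                                    check.names = FALSE),
                         out("eigengenes.tsv"), seed = config$seed)
      if (!is.null(fit_table)) {
        .write_with_header(fit_table, out("soft_threshold.tsv"),
                           seed = config$seed)
      }
      if (!is.null(mt)) {
        .write_with_header(mt, out("module_trait.tsv"), seed = config$seed)
      }
      if (!is.null(hub)) {
        .write_with_header(hub$table, out("gs_mm.tsv"), seed = config$seed)
      }
      jsonlite::write_json(summary, out("summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }

  summary$assignment <- merged$assignment
  summary$module_trait <- mt
  summary$hub_table <- if (!is.null(hub)) hub$table
  summary$validation_detail <- validation
  invisible(summary)
}
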