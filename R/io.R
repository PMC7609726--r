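# Tabular input/output for all pipeline artifacts.
#
# All tables are plain TSV/CSV.  Expression: feature rows x sample columns
# (array-export orientation); traits: sample rows x trait columns; qPCR:
# long format, one row per (sample, replicate); survival: one row per
# patient.  Writers emit a leading comment line with the tool version (and
# seed where one applies); readers skip lines starting with '#'.

.detect_delimiter <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

.read_raw <- function(path, delimiter = NULL, as_character = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- delimiter %||% .detect_delimiter(path)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#",
                    quote = "\"",
                    colClasses = if (as_character) "character" else NA)
}

# Convert all but the first column of `df` to numeric, naming the first
# offending cell by its row id and column header on failure.
.numeric_body <- function(df) {
  ids <- df[[1L]]
  out <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                dimnames = list(ids, colnames(df)[-1L]))
  for (j in seq_len(ncol(df) - 1L)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(is.na(raw) | raw %in% c("NA", "NaN", "")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in row '%s', column '%s'",
                   raw[bad[1L]], ids[bad[1L]], colnames(df)[j + 1L]),
           call. = FALSE)
    }
    out[, j] <- num
  }
  out
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicated ", what, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  invisible(ids)
}

.write_with_header <- function(df, path, seed = NULL, delimiter = NULL) {
  sep <- delimiter %||% .detect_delimiter(path)
  con <- file(path, open = "wt")
  on.exit(close(con))
  ver <- tryCatch(as.character(utils::packageVersion("mircomod")),
                  error = function(e) "dev")
  seedtxt <- if (is.null(seed)) "" else paste0("; seed=", seed)
  writeLines(sprintf("# mircomod %s%s", ver, seedtxt), con)
  utils::write.table(df, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read an expression matrix
#'
#' Reads a features x samples table of log-scale expression values.  The
#' first column holds feature identifiers, the header row holds sample
#' identifiers.  Missing values may be encoded as \code{NA} or empty
#' cells.  Constant (zero-variance) features are flagged with a warning
#' and recorded in the \code{"constant_features"} attribute; they must be
#' dropped before network construction.
#'
#' @param path Path to a TSV or CSV file; the delimiter is inferred from
#'   the extension unless \code{delimiter} is given.
#' @param delimiter Optional field separator overriding the inference.
#' @return Numeric matrix (features x samples) with dimnames.
#' @export
read_expression <- function(path, delimiter = NULL) {
  df <- .read_raw(path, delimiter)
  if (ncol(df) < 2L) stop("expression file needs an id column plus data")
  .check_unique(df[[1L]], "feature id(s)")
  .check_unique(colnames(df)[-1L], "sample id(s)")
  validate_expression(.numeric_body(df))
}

#' Validate an expression matrix
#'
#' Checks the invariants assumed throughout the pipeline: named rows
#' (features) and columns (samples), unique ids, at least 2 features and
#' 3 samples.  Zero-variance features are flagged, not removed.
#'
#' @param m Numeric matrix, features x samples.
#' @return The validated matrix (with a \code{"constant_features"}
#'   attribute when applicable).
#' @export
validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must carry feature rownames and sample colnames")
  }
  .check_unique(rownames(m), "feature id(s)")
  .check_unique(colnames(m), "sample id(s)")
  if (nrow(m) < 2L) stop("at least 2 features required")
  if (ncol(m) < 3L) stop("at least 3 samples required")
  v <- apply(m, 1L, stats::var, na.rm = TRUE)
  flat <- rownames(m)[!is.na(v) & v == 0]
  if (length(flat)) {
    warning("constant (zero-variance) feature(s) flagged: ",
            paste(flat, collapse = ", "), call. = FALSE)
    attr(m, "constant_features") <- flat
  }
  m
}

#' Write an expression matrix
#'
#' @param expr Numeric matrix, features x samples, with dimnames.
#' @param path Output path (.tsv or .csv).
#' @param seed Optional seed recorded in the header comment.
#' @param delimiter Optional field separator.
#' @return The path, invisibly.
#' @export
write_expression <- function(expr, path, seed = NULL, delimiter = NULL) {
  df <- data.frame(feature_id = rownames(expr), expr,
                   check.names = FALSE, row.names = NULL)
  .write_with_header(df, path, seed, delimiter)
}

#' Read a sample trait table
#'
#' Samples x traits; first column sample ids, remaining columns numeric
#' clinical traits (ordinal scores encoded as integers).  Missing values
#' allowed.
#'
#' @inheritParams read_expression
#' @return Numeric matrix (samples x traits) with dimnames.
#' @export
read_trait_table <- function(path, delimiter = NULL) {
  df <- .read_raw(path, delimiter)
  if (ncol(df) < 2L) stop("trait file needs an id column plus data")
  .check_unique(df[[1L]], "sample id(s)")
  .check_unique(colnames(df)[-1L], "trait name(s)")
  .numeric_body(df)
}

#' Write a sample trait table
#' @param traits Numeric matrix, samples x traits, with dimnames.
#' @inheritParams write_expression
#' @return The path, invisibly.
#' @export
write_trait_table <- function(traits, path, seed = NULL, delimiter = NULL) {
  df <- data.frame(sample_id = rownames(traits), traits,
                   check.names = FALSE, row.names = NULL)
  .write_with_header(df, path, seed, delimiter)
}

#' Read a qPCR Cq table
#'
#' Long format, one row per (sample, replicate) with columns
#' \code{sample_id}, \code{replicate}, \code{target_cq},
#' \code{reference_cq} and optionally \code{target_efficiency} and
#' \code{reference_efficiency} (fold change per cycle, in [1, 2];
#' default 2, i.e. perfect doubling).  Replicates are averaged downstream
#' before quantification.
#'
#' @inheritParams read_expression
#' @return data.frame sorted by (sample_id, replicate).
#' @export
read_qpcr_table <- function(path, delimiter = NULL) {
  df <- .read_raw(path, delimiter, as_character = FALSE)
  need <- c("sample_id", "replicate", "target_cq", "reference_cq")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("qPCR table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"target_efficiency" %in% colnames(df)) df$target_efficiency <- 2
  if (!"reference_efficiency" %in% colnames(df)) df$reference_efficiency <- 2
  for (cc in c("target_efficiency", "reference_efficiency")) {
    if (any(df[[cc]] < 1 | df[[cc]] > 2, na.rm = TRUE)) {
      stop("amplification efficiencies must lie in [1, 2] (column ", cc, ")")
    }
  }
  if (any(df$target_cq <= 0 | df$reference_cq <= 0, na.rm = TRUE)) {
    stop("Cq values must be positive")
  }
  df <- df[order(df$sample_id, df$replicate),
           c(need, "target_efficiency", "reference_efficiency")]
  rownames(df) <- NULL
  df
}

#' Read a survival table
#'
#' Columns \code{sample_id}, \code{time} (months, > 0), \code{event}
#' (1/0 or TRUE/FALSE; FALSE = censored) and optionally \code{group}.
#'
#' @inheritParams read_expression
#' @return data.frame with logical \code{event}.
#' @export
read_survival_table <- function(path, delimiter = NULL) {
  df <- .read_raw(path, delimiter, as_character = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("survival table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$time <= 0, na.rm = TRUE)) stop("follow-up times must be positive")
  df$event <- as.logical(df$event)
  .check_unique(df$sample_id, "sample id(s)")
  df
}

#' Write a module assignment
#'
#' Two-column TSV/CSV (\code{feature_id}, \code{module}), rows ordered by
#' feature id for reproducible output.  An empty assignment yields a
#' header-only file.
#'
#' @param assignment Named character vector mapping feature ids to module
#'   colours ("grey" = unassigned).
#' @inheritParams write_expression
#' @return The path, invisibly.
#' @export
write_module_assignment <- function(assignment, path, seed = NULL,
                                    delimiter = NULL) {
  df <- data.frame(feature_id = names(assignment) %||% character(0),
                   module = unname(assignment))
  df <- df[order(df$feature_id), , drop = FALSE]
  rownames(df) <- NULL
  .write_with_header(df, path, seed, delimiter)
}

#' Read a module assignment written by \code{write_module_assignment}
#' @inheritParams read_expression
#' @return Named character vector (feature id -> module colour).
#' @export
read_module_assignment <- function(path, delimiter = NULL) {
  df <- .read_raw(path, delimiter)
  if (!all(c("feature_id", "module") %in% colnames(df))) {
    stop("module assignment file must have columns feature_id, module")
  }
  stats::setNames(as.character(df$module), df$feature_id)
}
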