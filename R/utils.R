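`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical module colour palette
#'
#' Ordered palette used to name co-expression modules by decreasing size
#' (largest module = "turquoise", second = "blue", ...).  "grey" is never
#' part of the palette: it is reserved for unassigned features.
#'
#' @return Character vector of colour names.
#' @export
module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown",
    "steelblue", "paleturquoise", "violet", "darkolivegreen",
    "darkmagenta")
}

# Stop unless `m` is a square symmetric numeric matrix (within tol).
.check_square_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) != ncol(m)) stop(what, " must be square", call. = FALSE)
  if (max(abs(m - t(m))) > tol) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  invisible(m)
}
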