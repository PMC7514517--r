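#' Build a set of linear constraints for the maximum-entropy problem
#'
#' A constraint set collects the linear restrictions \eqn{\sum_i p_i
#' g_r(i) = C_r} imposed on a discrete distribution over \eqn{N}
#' territorial units. The natural restriction \eqn{\sum_i p_i = 1} is
#' always implicit and never stored as a row. Each row is assigned a
#' positive scale factor (its maximum absolute value) used internally to
#' condition the solver; rescaling a row and its target by the same
#' factor leaves the maximum-entropy solution unchanged.
#'
#' @param G numeric matrix with one row per constraint and one column per
#'   territorial unit, holding \eqn{g_r(i)}; a numeric vector is treated
#'   as a single row.
#' @param C numeric vector of constraint targets, one per row of `G`.
#' @param labels optional character vector naming each constraint.
#'
#' @return An object of class `constraint_set`: a list with elements
#'   `G`, `C`, `labels` and `scale`.
#'
#' @examples
#' cs <- constraint_set(matrix(1:4, nrow = 1), C = 2.5, labels = "mean index")
#' cs
#' @export
constraint_set <- function(G, C, labels = NULL) {
  if (is.null(dim(G))) G <- matrix(G, nrow = 1L)
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  C <- as.numeric(C)
  if (nrow(G) != length(C)) {
    abort(sprintf("`G` has %d rows but `C` has %d targets.", nrow(G), length(C)))
  }
  if (!all(is.finite(G))) abort("`G` contains non-finite entries.")
  if (!all(is.finite(C))) abort("`C` contains non-finite targets.")
  if (is.null(labels)) {
    labels <- if (nrow(G)) paste0("r", seq_len(nrow(G))) else character(0)
  }
  if (length(labels) != nrow(G)) abort("`labels` must have one entry per row of `G`.")
  scale <- apply(abs(G), 1L, max)
  if (nrow(G) && any(scale == 0)) {
    abort(sprintf(
      "constraint row(s) %s are identically zero.",
      paste(labels[scale == 0], collapse = ", ")
    ))
  }
  structure(
    list(G = G, C = C, labels = as.character(labels), scale = as.numeric(scale)),
    class = "constraint_set"
  )
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf(
    "<constraint_set: %d constraint(s) on %d territorial units>\n",
    nrow(x$G), ncol(x$G)
  ))
  if (nrow(x$G)) {
    df <- tibble(
      label = x$labels, target = x$C, scale = x$scale,
      g_min = apply(x$G, 1, min), g_max = apply(x$G, 1, max)
    )
    print(df, ...)
  }
  invisible(x)
}

#' @export
dim.constraint_set <- function(x) dim(x$G)

#' Combine constraint sets row-wise
#'
#' @param ... `constraint_set` objects over the same territorial units.
#' @return A single `constraint_set` with the rows of all inputs.
#' @export
c.constraint_set <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  for (s in sets) {
    if (!inherits(s, "constraint_set")) abort("can only combine `constraint_set` objects.")
  }
  ncols <- vapply(sets, function(s) ncol(s$G), integer(1))
  if (length(unique(ncols)) > 1) abort("constraint sets cover different numbers of territorial units.")
  constraint_set(
    do.call(rbind, lapply(sets, `[[`, "G")),
    unlist(lapply(sets, `[[`, "C")),
    unlist(lapply(sets, `[[`, "labels"))
  )
}

#' Convert a constraint set to a tibble
#'
#' One row per constraint: label, target, scale, then `g_1 ... g_N`.
#'
#' @param x a `constraint_set`.
#' @param ... unused.
#' @export
as_tibble.constraint_set <- function(x, ...) {
  gcols <- as_tibble(x$G, .name_repair = ~ paste0("g_", seq_along(.x)))
  dplyr::bind_cols(tibble(label = x$labels, target = x$C, scale = x$scale), gcols)
}

# Feasibility pre-check: each target must be attainable by some distribution,
# i.e. lie strictly inside the range of its row (constant rows must match
# their constant). Returns invisibly or aborts naming the offending row.
check_feasibility <- function(cs, tol = 1e-9) {
  if (!nrow(cs$G)) return(invisible(cs))
  for (r in seq_len(nrow(cs$G))) {
    g <- cs$G[r, ]
    lo <- min(g); hi <- max(g); sc <- cs$scale[r]
    if ((hi - lo) <= tol * sc) {
      if (abs(cs$C[r] - lo) > tol * max(1, sc)) {
        abort(sprintf(
          "constraint '%s' is a constant row with value %g but target %g: infeasible.",
          cs$labels[r], lo, cs$C[r]
        ), class = "maxentpop_infeasible")
      }
    } else if (cs$C[r] <= lo + tol * sc * 1e-3 || cs$C[r] >= hi - tol * sc * 1e-3) {
      abort(sprintf(
        "constraint '%s' has target %g outside the attainable open range (%g, %g).",
        cs$labels[r], cs$C[r], lo, hi
      ), class = "maxentpop_infeasible")
    }
  }
  invisible(cs)
}

#' Write or read a constraint set as CSV
#'
#' The CSV dialect has one row per constraint with columns `label`,
#' `target`, then `g_1 ... g_N`. Scales are recomputed on read.
#'
#' @param cs a `constraint_set`.
#' @param path file path.
#' @return `read_constraints()` returns a `constraint_set`;
#'   `write_constraints()` returns `path` invisibly.
#' @export
write_constraints <- function(cs, path) {
  df <- as_tibble(cs)
  df$scale <- NULL
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("label", "target")
  if (!all(need %in% names(df))) abort("constraint CSV must have columns `label` and `target`.")
  gcols <- grep("^g_[0-9]+$", names(df), value = TRUE)
  if (!length(gcols)) abort("constraint CSV has no `g_<i>` columns.")
  gcols <- gcols[order(as.integer(sub("^g_", "", gcols)))]
  constraint_set(as.matrix(df[gcols]), df$target, df$label)
}
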