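#' Territorial reordering schemes for index-moment constraints
#'
#' Index-moment restrictions act on the position of each territorial
#' unit, so the permutation assigning TUs to indices 1..N is part of the
#' model. Three schemes are supported:
#'
#' * `original` — TUs in ascending `tu_id` order (the official code
#'   arrangement);
#' * `descending` — index 1 holds the most populated TU at the
#'   reference year, ties broken by ascending `tu_id`;
#' * `bell` — the most populated TU sits at the central index and
#'   populations decrease toward both ends; ranks are placed
#'   center-outward, alternating right then left of the center.
#'
#' The permutation is meant to be frozen at a reference year and reused
#' for every model year, so moment series stay comparable over time.
#'
#' @param populations a data frame with columns `tu_id` and
#'   `population` (one row per TU), or a full panel together with
#'   `reference_year`.
#' @param scheme one of `"original"`, `"descending"`, `"bell"`.
#' @param reference_year year whose populations define the ordering;
#'   required when `populations` holds several years.
#' @return A tibble of class `tu_ordering` with columns `tu_id` and
#'   `index`, plus attributes `scheme` and `reference_year`.
#' @examples
#' pops <- tibble::tibble(tu_id = c("TU1", "TU2", "TU3"),
#'                        population = c(10, 50, 20))
#' make_ordering(pops, "descending")
#' make_ordering(pops, "bell") # largest ends up at the central index
#' @export
make_ordering <- function(populations, scheme = c("descending", "bell", "original"),
                          reference_year = NULL) {
  scheme <- arg_match(scheme)
  df <- as_tibble(populations)
  if (!all(c("tu_id", "population") %in% names(df))) {
    abort("`populations` needs columns `tu_id` and `population`.")
  }
  if ("year" %in% names(df) && length(unique(df$year)) > 1) {
    if (is.null(reference_year)) {
      abort("`populations` covers several years; supply `reference_year`.")
    }
    df <- filter(df, .data$year == !!reference_year)
    if (!nrow(df)) abort(sprintf("no rows at reference year %d.", reference_year))
  } else if (is.null(reference_year) && "year" %in% names(df)) {
    reference_year <- df$year[1]
  }
  df$tu_id <- as.character(df$tu_id)
  if (anyDuplicated(df$tu_id)) {
    abort(sprintf("duplicate tu_id: %s.", df$tu_id[duplicated(df$tu_id)][1]))
  }
  n <- nrow(df)
  if (n < 2) abort("need at least 2 territorial units.")
  idx <- switch(
    scheme,
    original = {
      o <- order(df$tu_id)
      ranks <- integer(n); ranks[o] <- seq_len(n); ranks
    },
    descending = {
      o <- order(-df$population, df$tu_id)
      ranks <- integer(n); ranks[o] <- seq_len(n); ranks
    },
    bell = {
      o <- order(-df$population, df$tu_id)   # rank 1 = largest
      pos <- bell_positions(n)               # position of rank k
      ranks <- integer(n); ranks[o] <- pos; ranks
    }
  )
  out <- tibble(tu_id = df$tu_id, index = idx)
  out <- arrange(out, .data$index)
  structure(out, class = c("tu_ordering", class(out)),
            scheme = scheme, reference_year = reference_year)
}

# Center-outward placement for the bell scheme: rank 1 at the central
# index floor(N/2) + 1, subsequent ranks alternating right, left, right,
# ... spilling over to the remaining side once an end is reached.
bell_positions <- function(n) {
  center <- floor(n / 2) + 1L
  pos <- integer(n)
  pos[1] <- center
  left <- center; right <- center
  go_right <- TRUE
  for (k in seq_len(n)[-1]) {
    if (go_right && right < n) {
      right <- right + 1L; pos[k] <- right
    } else if (!go_right && left > 1L) {
      left <- left - 1L; pos[k] <- left
    } else if (right < n) {
      right <- right + 1L; pos[k] <- right
    } else {
      left <- left - 1L; pos[k] <- left
    }
    go_right <- !go_right
  }
  pos
}

#' Write or read an ordering as a two-column CSV
#'
#' @param ordering a `tu_ordering`.
#' @param path file path.
#' @export
write_ordering <- function(ordering, path) {
  readr::write_csv(tibble(tu_id = ordering$tu_id, index = ordering$index), path)
  invisible(path)
}

#' @rdname write_ordering
#' @export
read_ordering <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(tu_id = readr::col_character(),
                                                index = readr::col_integer()))
  if (!setequal(df$index, seq_len(nrow(df)))) {
    abort("ordering CSV indices are not a permutation of 1..N.")
  }
  structure(arrange(df, .data$index), class = c("tu_ordering", class(df)),
            scheme = "original", reference_year = NA_integer_)
}
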