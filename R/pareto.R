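#' Min-max normalization of an objective table
#'
#' Rescales each objective column onto 0-100 by
#' `(y - min) / (max - min) * 100`. Minimize-sense columns are negated before
#' rescaling, so 100 is always "best". A degenerate column (max == min) is
#' set to 0 with a warning. Missing values are an error.
#'
#' @param df Tibble of candidate solutions (rows) by objectives (columns).
#' @param objectives Character vector of objective column names; defaults to
#'   all numeric columns.
#' @param sense Character vector (`"maximize"`/`"minimize"`), recycled to the
#'   number of objectives. Default all maximize.
#' @return `df` with the objective columns replaced by normalized scores
#'   (all maximize-sense after the call).
#' @examples
#' minmax_normalize(tibble::tibble(y = c(10, 20)))
#' @export
minmax_normalize <- function(df, objectives = NULL, sense = "maximize") {
  if (nrow(df) < 1) abort("Need at least one row.")
  if (is.null(objectives)) {
    objectives <- names(df)[vapply(df, is.numeric, logical(1))]
  }
  stopifnot(all(objectives %in% names(df)))
  sense <- check_sense(sense, objectives)
  for (j in objectives) {
    y <- df[[j]]
    if (any(is.na(y))) abort(paste0("Missing values in objective '", j, "'."))
    if (sense[[j]] == "minimize") y <- -y
    rng <- range(y)
    if (rng[1] == rng[2]) {
      warn(paste0("Objective '", j, "' is constant; normalized to 0."))
      df[[j]] <- rep(0, length(y))
    } else {
      df[[j]] <- (y - rng[1]) / (rng[2] - rng[1]) * 100
    }
  }
  df
}

check_sense <- function(sense, objectives) {
  sense <- match.arg(sense, c("maximize", "minimize"), several.ok = TRUE)
  if (length(sense) == 1) sense <- rep(sense, length(objectives))
  if (length(sense) != length(objectives)) {
    abort("sense must have length 1 or one entry per objective.")
  }
  setNames(sense, objectives)
}

#' Strict Pareto dominance between two objective vectors
#'
#' `a` dominates `b` iff `a >= b` in every component and `a > b` in at least
#' one. Both vectors must be maximize-sense (negate minimize objectives
#' first). Identical vectors do not dominate each other.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Logical scalar.
#' @examples
#' dominates(c(2, 2), c(1, 2))  # TRUE
#' dominates(c(2, 1), c(1, 2))  # FALSE (incomparable)
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) abort("Objective vectors differ in length.")
  if (any(is.na(a)) || any(is.na(b))) abort("Missing values in objectives.")
  all(a >= b) && any(a > b)
}

#' Pareto frontier of a finite candidate set
#'
#' Identifies the non-dominated subset of the rows of `df` under strict
#' Pareto dominance over the selected objectives, by an exhaustive all-pairs
#' scan (the candidate sets here are small). Rows with identical objective
#' vectors are all retained: neither strictly dominates the other. Output
#' preserves input row order.
#'
#' @inheritParams minmax_normalize
#' @param within Optional character vector of grouping columns; the frontier
#'   is then extracted separately inside each group (e.g. per cultivar).
#' @return An object of class `pareto_front`: the input tibble plus
#'   `.frontier` (logical) and `.dominated_by` (how many rows dominate this
#'   one), with attributes `objectives` and `sense`. Methods: [tidy()],
#'   [glance()], [ggplot2::autoplot()].
#' @examples
#' m <- tibble::tibble(quality = c(90, 40), yield = c(2700, 4300))
#' pareto_front(m)
#' @export
pareto_front <- function(df, objectives = NULL, sense = "maximize",
                         within = NULL) {
  if (nrow(df) < 1) abort("Need at least one candidate row.")
  if (is.null(objectives)) {
    objectives <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                          within)
  }
  stopifnot(all(objectives %in% names(df)))
  sense <- check_sense(sense, objectives)
  m <- as.matrix(df[objectives])
  if (any(is.na(m))) abort("Missing values in objectives.")
  for (j in objectives) if (sense[[j]] == "minimize") m[, j] <- -m[, j]

  groups <- if (is.null(within)) {
    rep(1L, nrow(df))
  } else {
    as.integer(factor(do.call(paste, c(df[within], sep = "\r"))))
  }
  dominated_by <- integer(nrow(df))
  for (i in seq_len(nrow(m))) {
    same <- which(groups == groups[i])
    dominated_by[i] <- sum(vapply(
      same, function(j) j != i && dominates(m[j, ], m[i, ]), logical(1)
    ))
  }
  out <- mutate(as_tibble(df),
    .dominated_by = dominated_by,
    .frontier = dominated_by == 0L
  )
  structure(out,
    objectives = objectives, sense = sense, within = within,
    class = c("pareto_front", class(out))
  )
}

#' @method tidy pareto_front
#' @export
tidy.pareto_front <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pareto_front")
  attr(out, "objectives") <- NULL
  attr(out, "sense") <- NULL
  attr(out, "within") <- NULL
  out
}

#' @method glance pareto_front
#' @export
glance.pareto_front <- function(x, ...) {
  tibble(
    n_candidates = nrow(x),
    n_frontier = sum(x$.frontier),
    n_objectives = length(attr(x, "objectives"))
  )
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("Pareto frontier over objectives: ",
      paste(attr(x, "objectives"), collapse = ", "),
      " (", sum(x$.frontier), "/", nrow(x), " non-dominated)\n", sep = "")
  NextMethod()
}

#' Two-objective projection of a Pareto analysis
#'
#' Projects all candidates onto a pair of objective axes, carrying the
#' frontier membership flags from the full-dimensional analysis (projection
#' never re-computes dominance).
#'
#' @param x A [pareto_front()] object.
#' @param axes Character vector of two objective names.
#' @return Tibble with the two axis columns, `.frontier` and any
#'   non-objective identifier columns.
#' @export
frontier_projection <- function(x, axes) {
  stopifnot(inherits(x, "pareto_front"))
  if (length(axes) != 2) abort("axes must name exactly two objectives.")
  unknown <- setdiff(axes, attr(x, "objectives"))
  if (length(unknown) > 0) {
    abort(paste0("Unknown axis: ", paste(unknown, collapse = ", ")))
  }
  keep <- c(setdiff(names(x), c(attr(x, "objectives"), ".dominated_by")), axes)
  tidy(x)[unique(keep)]
}
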