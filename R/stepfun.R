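#' Right-continuous step function
#'
#' Lightweight carrier for Breslow-type survivor estimates: a value before
#' the first knot (1 for survivor functions) and right-continuous values at
#' strictly increasing positive knots.
#'
#' @param knots strictly increasing positive jump locations.
#' @param values value taken on `[knots[i], knots[i+1])`.
#' @param value_start value on `[0, knots[1])`; defaults to 1.
#' @param survivor if `TRUE`, values are checked to be non-increasing and
#'   within `[0, 1]` starting from 1.
#' @return An object of class `step_function`.
#' @export
step_function <- function(knots, values, value_start = 1, survivor = FALSE) {
  knots <- as.numeric(knots); values <- as.numeric(values)
  if (length(knots) != length(values))
    stop("knots and values must have equal length")
  if (length(knots) && (any(knots <= 0) || any(diff(knots) <= 0)))
    stop("knots must be strictly increasing and positive")
  if (survivor) {
    v <- c(value_start, values)
    if (any(v < -1e-12) || any(v > 1 + 1e-12) || any(diff(v) > 1e-12))
      stop("survivor step function must be non-increasing within [0, 1]")
    if (abs(value_start - 1) > 1e-12)
      stop("survivor step function must equal 1 at t = 0")
  }
  structure(list(knots = knots, values = values, value_start = value_start,
                 survivor = survivor),
            class = "step_function")
}

#' Evaluate a step function
#'
#' @param sf a [step_function()].
#' @param t evaluation times (>= 0).
#' @param side `"right"` for the right-continuous value at `t`, `"left"` for
#'   the limit from below (the value just before `t`).
#' @return numeric vector of values.
#' @export
eval_step <- function(sf, t, side = c("right", "left")) {
  side <- match.arg(side)
  if (!length(sf$knots)) return(rep(sf$value_start, length(t)))
  idx <- findInterval(t, sf$knots, left.open = (side == "left"))
  c(sf$value_start, sf$values)[idx + 1L]
}

#' @export
print.step_function <- function(x, ...) {
  cat(sprintf("step_function with %d knots%s\n", length(x$knots),
              if (x$survivor) " (survivor)" else ""))
  if (length(x$knots)) {
    k <- utils::head(cbind(t = x$knots, value = x$values), 6L)
    print(k)
    if (length(x$knots) > 6L) cat("...\n")
  }
  invisible(x)
}

#' Export a step function as a two-column data frame
#' @param sf a [step_function()].
#' @export
step_as_table <- function(sf) {
  data.frame(t = c(0, sf$knots), value = c(sf$value_start, sf$values))
}
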