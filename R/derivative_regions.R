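## Posterior first-derivative inference for fitted smooths: forward finite
## differences applied per posterior draw, and detection of predictor
## intervals where the pointwise credible interval of the slope excludes
## zero (credibly rising or falling stretches of the response).

#' Finite-difference first derivatives of a posterior smooth
#'
#' For each posterior draw, evaluates the smooth at the grid and at the
#' grid shifted forward by `eps`, and differences:
#' `slope(x) = (f(x + eps) - f(x)) / eps`. Exact for linear smooths; the
#' default step is `1e-4` times the grid range.
#'
#' @param object either a `gamm_fit` (evaluated via [posterior_smooth()])
#'   or a function `f(x)` returning a draws x `length(x)` matrix.
#' @param grid strictly increasing predictor values.
#' @param eps forward-difference step; must be positive and no larger
#'   than half the minimum grid spacing.
#' @return object of class `slope_draws`: list with `grid`, `slopes`
#'   (draws x grid matrix), `eps`.
#' @export
finite_difference_slopes <- function(object, grid, eps = NULL) {
  if (is.unsorted(grid, strictly = TRUE))
    stop_nutgeom("grid must be strictly increasing")
  eps <- eps %||% (1e-4 * diff(range(grid)))
  if (eps <= 0) stop_nutgeom("eps must be positive")
  if (length(grid) > 1 && eps > min(diff(grid)) / 2)
    stop_nutgeom("eps larger than half the minimum grid spacing")
  f <- if (inherits(object, "gamm_fit"))
    function(x) posterior_smooth(object, x)
  else if (is.function(object)) object
  else stop_nutgeom("object must be a gamm_fit or a function")
  f0 <- f(grid)
  f1 <- f(grid + eps)
  if (!is.matrix(f0)) f0 <- matrix(f0, nrow = 1)
  if (!is.matrix(f1)) f1 <- matrix(f1, nrow = 1)
  structure(list(grid = grid, slopes = (f1 - f0) / eps, eps = eps),
            class = "slope_draws")
}

#' Detect predictor regions with credibly nonzero slope
#'
#' At each grid point the central credible interval of the slope draws is
#' computed; contiguous runs of points whose interval excludes zero form
#' regions labeled by the shared slope sign. Single-point runs are
#' retained. Intervals are pointwise, matching the per-point exclusion
#' rule.
#'
#' @param slopes a [finite_difference_slopes()] result.
#' @param level credible level in (0.5, 1).
#' @return object of class `credible_regions`: data.frame with columns
#'   `x_start`, `x_end`, `sign` (`"increasing"`/`"decreasing"`), plus
#'   attributes `level` and `flagged` (logical per grid point).
#' @export
detect_nonflat_regions <- function(slopes, level = 0.95) {
  stopifnot(inherits(slopes, "slope_draws"))
  if (level <= 0.5 || level >= 1) stop_nutgeom("level must be in (0.5, 1)")
  if (length(slopes$grid) < 2) stop_nutgeom("need >= 2 grid points")
  a <- (1 - level) / 2
  lo <- apply(slopes$slopes, 2, quantile, probs = a, names = FALSE)
  hi <- apply(slopes$slopes, 2, quantile, probs = 1 - a, names = FALSE)
  sgn <- ifelse(lo > 0, 1L, ifelse(hi < 0, -1L, 0L))
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  out <- data.frame(
    x_start = slopes$grid[starts[keep]],
    x_end = slopes$grid[ends[keep]],
    sign = ifelse(r$values[keep] > 0, "increasing", "decreasing"))
  attr(out, "level") <- level
  attr(out, "flagged") <- sgn != 0L
  class(out) <- c("credible_regions", "data.frame")
  out
}
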