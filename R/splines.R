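# M-spline / I-spline bases for baseline-hazard modelling, built on
# base splineDesign. An M-spline basis function is a B-spline rescaled
# to integrate to one over the boundary span (so nonnegative weights
# give a valid hazard); its running integral (I-spline) is nondecreasing
# from 0 to 1 and yields the cumulative hazard in closed form.

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * (e$vectors[1, idx])^2)
}

#' Construct an M-spline basis
#'
#' @param degree polynomial degree (0 gives a piecewise-constant basis).
#' @param boundary_knots length-2 numeric, the support of the basis.
#' @param internal_knots ordered interior knot positions (may be empty).
#' @return Object of class `spline_basis` (kind `"M"`); the number of
#'   basis functions is `length(internal_knots) + degree + 1`.
#' @details Each basis function is nonnegative and integrates to one
#'   over the boundary span; evaluating with `kind = "I"` gives the
#'   integrated (I-spline) basis, nondecreasing from 0 at the lower
#'   boundary to 1 at the upper.
#' @export
mspline_basis <- function(degree = 3, boundary_knots = c(0, 1),
                          internal_knots = numeric(0)) {
  if (length(boundary_knots) != 2 || boundary_knots[1] >= boundary_knots[2]) {
    stop("boundary_knots must be an increasing pair", call. = FALSE)
  }
  internal_knots <- as.numeric(internal_knots)
  if (is.unsorted(internal_knots, strictly = FALSE)) {
    stop("internal knots must be ordered", call. = FALSE)
  }
  if (length(internal_knots) &&
      (min(internal_knots) <= boundary_knots[1] ||
       max(internal_knots) >= boundary_knots[2])) {
    stop("internal knots must lie strictly inside the boundary knots",
         call. = FALSE)
  }
  order <- degree + 1L
  knots <- c(rep(boundary_knots[1], order), internal_knots,
             rep(boundary_knots[2], order))
  structure(list(degree = as.integer(degree), order = order,
                 boundary_knots = boundary_knots,
                 internal_knots = internal_knots, knots = knots,
                 n_basis = length(internal_knots) + order, kind = "M"),
            class = "spline_basis")
}

#' Construct a (normalized) B-spline basis
#'
#' Used for coefficient splines of time-varying effects: values are the
#' usual B-splines that sum to one, with no density normalization.
#'
#' @inheritParams mspline_basis
#' @return Object of class `spline_basis` (kind `"B"`).
#' @export
bspline_basis <- function(degree = 2, boundary_knots = c(0, 1),
                          internal_knots = numeric(0)) {
  b <- mspline_basis(degree, boundary_knots, internal_knots)
  b$kind <- "B"
  b
}

.bspline_values <- function(basis, times) {
  times <- pmin(pmax(times, basis$boundary_knots[1]), basis$boundary_knots[2])
  splines::splineDesign(basis$knots, times, ord = basis$order,
                        outer.ok = TRUE)
}

#' Evaluate a spline basis at a set of times
#'
#' @param basis a `spline_basis`.
#' @param times numeric vector; values outside the boundary knots are
#'   clamped to them.
#' @param kind `"M"` (densities), `"I"` (their running integrals) or
#'   `"B"` (plain normalized B-splines); defaults to the basis's own
#'   kind.
#' @return Matrix with one row per time and one column per basis
#'   function.
#' @export
evaluate_basis <- function(basis, times, kind = basis$kind) {
  kind <- match.arg(kind, c("M", "I", "B"))
  if (kind == "B") return(.bspline_values(basis, times))
  N <- .bspline_values(basis, times)
  k <- basis$order
  n <- basis$n_basis
  widths <- basis$knots[seq_len(n) + k] - basis$knots[seq_len(n)]
  Mmat <- sweep(N, 2, k / widths, `*`)
  if (kind == "M") return(Mmat)
  .ispline_values(basis, times)
}

# exact integrals of the M-basis: Gauss-Legendre per knot span is exact
# because each M-spline is a polynomial of degree <= 3 on each span
.ispline_values <- function(basis, times) {
  lo <- basis$boundary_knots[1]
  times <- pmin(pmax(times, lo), basis$boundary_knots[2])
  breaks <- unique(c(lo, basis$internal_knots, basis$boundary_knots[2]))
  gl <- gauss_legendre(max(3L, ceiling((basis$degree + 1) / 2)))

  span_int <- function(a, b_) {
    # integral of each M function over [a, b_] (within one span)
    if (b_ <= a) return(numeric(basis$n_basis))
    mid <- (a + b_) / 2; half <- (b_ - a) / 2
    pts <- mid + half * gl$nodes
    vals <- evaluate_basis(basis, pts, kind = "M")
    drop(half * crossprod(gl$weights, vals))
  }
  # cumulative integral up to each breakpoint
  cum <- matrix(0, length(breaks), basis$n_basis)
  for (j in seq_along(breaks)[-1]) {
    cum[j, ] <- cum[j - 1, ] + span_int(breaks[j - 1], breaks[j])
  }
  out <- matrix(0, length(times), basis$n_basis)
  span_of <- findInterval(times, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
  for (r in seq_along(times)) {
    j <- span_of[r]
    out[r, ] <- cum[j, ] + span_int(breaks[j], times[r])
  }
  out
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("%s-spline basis: degree %d, %d function(s)\n", x$kind,
              x$degree, x$n_basis))
  cat(sprintf("  boundary knots: [%g, %g]\n", x$boundary_knots[1],
              x$boundary_knots[2]))
  if (length(x$internal_knots)) {
    cat("  internal knots:", paste(signif(x$internal_knots, 4),
                                   collapse = ", "), "\n")
  }
  invisible(x)
}
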