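#' Build a ROAR surface for a significant 2x2 table
#'
#' The Region of Attainable Redaction is the set of nonnegative redaction
#' pairs (x, y) for which the restored table is no longer significant at
#' the chosen level.  Restoring x subjects to the experimental arm and y to
#' the control arm (to the cells selected by `direction`, see
#' [classify_direction()]) and subtracting the critical value from the
#' restored chi-squared statistic defines the surface function
#' \deqn{g(x, y) = \frac{(n + x + y)\,\mathrm{cross}(x,y)^2}
#'   {r_1 r_2 c_1 c_2} - \nu_c,}
#' where cross is `ad - (b+x)(c+y)` (direction `rr_gt_1`) or
#' `(a+x)(d+y) - bc` (direction `rr_lt_1`) and the denominator is the
#' product of the restored table's margins.  `g <= 0` exactly on the region.
#'
#' The object precomputes the denominator-cleared cubic polynomial
#' \eqn{(n+x+y)\,\mathrm{cross}^2 - \nu_c r_1 r_2 c_1 c_2}, its gradient,
#' and the Lagrange elimination polynomial
#' \eqn{h = y\,\partial g/\partial x - x\,\partial g/\partial y}
#' used by the FOCK solver.  Because the denominator is strictly positive
#' for x, y >= 0, the polynomial and rational forms share their sign
#' everywhere on the domain.
#'
#' @inheritParams chi_square_statistic
#' @param alpha Significance level defining the critical value.
#' @param direction `"auto"` (classify from the relative risk),
#'   `"rr_gt_1"`, or `"rr_lt_1"`.
#' @return An object of class `roar_surface`.
#' @examples
#' s <- roar_surface(dichotomous_table(70, 30, 50, 50))
#' g_value(s, 0, 0) # chi-squared minus critical value
#' @export
roar_surface <- function(table, alpha = 0.05, direction = "auto") {
  t <- as_dichotomous_table(table)
  nu_c <- critical_value(alpha)
  direction <- match.arg(direction, c("auto", "rr_gt_1", "rr_lt_1"))
  if (direction == "auto") direction <- classify_direction(t)

  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d); n <- as.numeric(t$n)
  n_lin <- poly_bilinear(n, 1, 1)
  r1 <- poly_bilinear(a + b, 1, 0)
  r2 <- poly_bilinear(c + d, 0, 1)
  if (direction == "rr_gt_1") {
    cross <- poly_bilinear(a * d - b * c, -c, -b, -1)
    c1 <- poly_bilinear(a + c, 0, 1)
    c2 <- poly_bilinear(b + d, 1, 0)
  } else {
    cross <- poly_bilinear(a * d - b * c, d, a, 1)
    c1 <- poly_bilinear(a + c, 1, 0)
    c2 <- poly_bilinear(b + d, 0, 1)
  }
  g_poly <- poly_trim(poly_add(
    poly_mul(n_lin, poly_mul(cross, cross)),
    poly_scale(poly_mul(poly_mul(r1, r2), poly_mul(c1, c2)), -nu_c)
  ))
  gx <- poly_dx(g_poly)
  gy <- poly_dy(g_poly)
  h_poly <- poly_trim(poly_add(poly_shift_y(gx),
                               poly_scale(poly_shift_x(gy), -1)))

  structure(
    list(
      table = t, direction = direction, alpha = alpha, nu_c = nu_c,
      g_poly = g_poly, gx_poly = gx, gy_poly = gy,
      h_poly = h_poly, hx_poly = poly_dx(h_poly), hy_poly = poly_dy(h_poly),
      scale = abs(g_poly[1L, 1L])
    ),
    class = "roar_surface"
  )
}

#' @export
print.roar_surface <- function(x, ...) {
  cat("ROAR surface: direction ", x$direction,
      ", alpha = ", format(x$alpha),
      ", critical value = ", format(x$nu_c, digits = 7), "\n", sep = "")
  cat("g(0, 0) = ", format(g_value(x, 0, 0), digits = 7),
      " (positive means the reported table is significant)\n", sep = "")
  invisible(x)
}

restored_cells <- function(surface, x, y) {
  t <- surface$table
  if (surface$direction == "rr_gt_1") {
    list(a = t$a, b = t$b + x, c = t$c + y, d = t$d)
  } else {
    list(a = t$a + x, b = t$b, c = t$c, d = t$d + y)
  }
}

#' Evaluate the ROAR surface function g
#'
#' Returns the rational-form value: the restored table's uncorrected
#' chi-squared statistic minus the critical value.  Vectorised over paired
#' `x`, `y`; `g_value(s, 0, 0)` equals the reported table's statistic minus
#' the critical value.
#'
#' @param surface A [roar_surface()].
#' @param x,y Nonnegative redaction counts (recycled to a common length).
#' @export
g_value <- function(surface, x, y) {
  stopifnot(inherits(surface, "roar_surface"))
  r <- restored_cells(surface, x, y)
  n_res <- r$a + r$b + r$c + r$d
  cross <- r$a * r$d - r$b * r$c
  n_res * cross^2 /
    ((r$a + r$b) * (r$c + r$d) * (r$a + r$c) * (r$b + r$d)) - surface$nu_c
}

#' Monomial expansion of the denominator-cleared surface polynomial
#'
#' Expands \eqn{(n+x+y)\,\mathrm{cross}^2 - \nu_c r_1 r_2 c_1 c_2}
#' programmatically into its monomial coefficients.  The result has degree
#' at most 3 in each variable, at most 15 nonzero coefficients, and the
#' coefficient of \eqn{x^3 y^3} is identically zero.
#'
#' @param surface A [roar_surface()].
#' @return A tibble with columns `i`, `j` (monomial exponents of x and y)
#'   and `coefficient`, nonzero entries only.
#' @export
expand_polynomial <- function(surface) {
  stopifnot(inherits(surface, "roar_surface"))
  p <- surface$g_poly
  idx <- which(p != 0, arr.ind = TRUE)
  tibble::tibble(
    i = idx[, 1L] - 1L,
    j = idx[, 2L] - 1L,
    coefficient = p[idx]
  ) |>
    dplyr::arrange(.data$i, .data$j)
}

#' Gradient of the surface polynomial
#'
#' Analytic partial derivatives of the denominator-cleared polynomial form
#' of g, vectorised over paired `x`, `y`.
#'
#' @inheritParams g_value
#' @return A tibble with columns `dg_dx`, `dg_dy`.
#' @export
grad_g <- function(surface, x, y) {
  stopifnot(inherits(surface, "roar_surface"))
  tibble::tibble(
    dg_dx = poly_eval(surface$gx_poly, x, y),
    dg_dy = poly_eval(surface$gy_poly, x, y)
  )
}

#' Lagrange elimination function h
#'
#' \eqn{h(x, y) = y\,\partial g/\partial x - x\,\partial g/\partial y},
#' obtained by eliminating the Lagrange multiplier from the stationarity
#' conditions of the distance minimisation.  Its zero locus contains every
#' point where the distance gradient is parallel to the constraint
#' gradient; the FOCK point solves g = 0, h = 0 simultaneously.
#'
#' @inheritParams g_value
#' @export
h_value <- function(surface, x, y) {
  stopifnot(inherits(surface, "roar_surface"))
  poly_eval(surface$h_poly, x, y)
}

#' Does a redaction pair fall inside the region?
#'
#' `TRUE` exactly when `g_value(surface, x, y) <= 0`, i.e. when restoring
#' x experimental-arm and y control-arm subjects leaves a table that is not
#' significant at the surface's level.  Vectorised.
#'
#' @inheritParams g_value
#' @export
roar_contains <- function(surface, x, y) {
  g_value(surface, x, y) <= 0
}

# All nonnegative real roots (ascending) of the cubic g(x0, y) = 0 for a
# vector of x0 values; returned as a matrix with up to 3 columns.
slice_roots <- function(surface, x0) {
  co <- poly_y_coefs(surface$g_poly, x0)
  if (ncol(co) < 4L) co <- cbind(co, matrix(0, nrow(co), 4L - ncol(co)))
  roots <- cubic_roots_real(co)
  tol <- 1e-7 * pmax(1, abs(roots))
  roots[!is.na(roots) & roots < 0 & roots > -tol] <- 0
  roots[!is.na(roots) & roots < 0] <- NA_real_
  roots
}

#' Vertical slice of the region boundary
#'
#' All nonnegative real roots y of the cubic `g(x_fixed, y) = 0`, in
#' ascending order; an empty vector when the vertical line at `x_fixed`
#' misses the region.
#'
#' @param surface A [roar_surface()].
#' @param x_fixed A single nonnegative x position.
#' @export
boundary_slice <- function(surface, x_fixed) {
  stopifnot(inherits(surface, "roar_surface"),
            length(x_fixed) == 1L, x_fixed >= 0)
  r <- slice_roots(surface, x_fixed)[1L, ]
  sort(r[!is.na(r)])
}

# x-extent scan limit: beyond the largest real root of g(x, 0) = 0 the
# region can still bulge slightly, so pad the scan window.
x_scan_limit <- function(surface) {
  co <- surface$g_poly[, 1L]
  co <- c(co, rep(0, 4L - length(co)))
  r <- cubic_roots_real(matrix(co, 1L))
  r <- r[!is.na(r) & r > 0]
  if (!length(r)) {
    stop("surface has no positive axis crossing; is the table significant?",
         call. = FALSE)
  }
  1.25 * max(r)
}

#' Trace the region boundary as an ordered polyline
#'
#' Samples the boundary `g = 0` on a grid of vertical slices and returns an
#' ordered polyline covering the near (origin-side) and far branches,
#' always including the two axis intercepts.  Suitable for plotting the
#' shaded region or exporting to CSV.
#'
#' @param surface A [roar_surface()].
#' @param n Number of slice positions (>= 2).
#' @return A tibble with columns `x`, `y` and a `branch` label
#'   (`"lower"`/`"upper"`).
#' @export
roar_boundary <- function(surface, n = 512L) {
  stopifnot(inherits(surface, "roar_surface"), n >= 2L)
  if (g_value(surface, 0, 0) <= 0) {
    stop("reported table is not significant: the region touches the origin",
         call. = FALSE)
  }
  xs <- seq(0, x_scan_limit(surface), length.out = n)
  roots <- slice_roots(surface, xs)
  lower <- apply(roots, 1L, function(r) suppressWarnings(min(r, na.rm = TRUE)))
  upper <- apply(roots, 1L, function(r) suppressWarnings(max(r, na.rm = TRUE)))
  keep <- is.finite(lower)
  pts <- dplyr::bind_rows(
    tibble::tibble(x = xs[keep], y = lower[keep], branch = "lower"),
    tibble::tibble(x = rev(xs[keep]), y = rev(upper[keep]), branch = "upper")
  )
  # guarantee exact axis intercepts are present
  xc <- axis_intercept_x(surface)
  yc <- axis_intercept_y(surface)
  dplyr::bind_rows(
    tibble::tibble(x = 0, y = yc, branch = "lower"),
    pts[pts$branch == "lower" & pts$x > 0, ],
    tibble::tibble(x = xc, y = 0, branch = "lower"),
    pts[pts$branch == "upper", ]
  ) |>
    dplyr::distinct()
}
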