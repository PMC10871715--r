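#' Minimal experimental-arm-only redaction
#'
#' The smallest positive root xc of the cubic `g(x, 0) = 0`: the fewest
#' subjects that need to have been redacted from the experimental arm
#' alone for the reported significance to be lost.
#'
#' @param surface A [roar_surface()] of a significant table.
#' @export
axis_intercept_x <- function(surface) {
  stopifnot(inherits(surface, "roar_surface"))
  co <- surface$g_poly[, 1L]
  smallest_positive_root(co, surface)
}

#' Minimal control-arm-only redaction
#'
#' The smallest positive root yc of the cubic `g(0, y) = 0`.
#'
#' @inheritParams axis_intercept_x
#' @export
axis_intercept_y <- function(surface) {
  stopifnot(inherits(surface, "roar_surface"))
  co <- surface$g_poly[1L, ]
  smallest_positive_root(co, surface)
}

smallest_positive_root <- function(co, surface) {
  if (g_value(surface, 0, 0) <= 0) {
    stop("reported table is not significant at this level", call. = FALSE)
  }
  co <- c(co, rep(0, max(0L, 4L - length(co))))[1:4]
  r <- cubic_roots_real(matrix(co, 1L))
  r <- r[!is.na(r) & r > 1e-12]
  if (!length(r)) {
    stop("no positive axis crossing found; input table appears degenerate",
         call. = FALSE)
  }
  min(r)
}

#' Solve for the FOCK point
#'
#' The FOCK (Fewest Observations/Censored Knowledge) point is the point of
#' the region boundary `g = 0` in the nonnegative quadrant closest to the
#' origin; its coordinates (xe, ye) are the minimal joint redactions that
#' nullify significance.  Interior minima satisfy the Lagrange system
#' `g = 0, h = 0`; a minimum may also sit on an axis, where only `g = 0`
#' holds and the point coincides with an axis intercept.
#'
#' The solver scans the boundary with vertical slices across the region's
#' x-extent to seed damped Newton iteration on the square system
#' `{g = 0, h = 0}`, filters candidates to the (numerically) nonnegative
#' real quadrant, appends the two axis intercepts, and returns the
#' minimum-norm candidate.
#'
#' @param surface A [roar_surface()] of a significant table.
#' @param slices Number of scan slices used to seed and cross-check the
#'   Newton solve.
#' @return A list with `x`, `y`, `distance`, and a `diagnostics` list
#'   (`g_residual`, `h_residual`, `iterations`, `candidates`, `converged`).
#' @export
fock_point <- function(surface, slices = 2000L) {
  stopifnot(inherits(surface, "roar_surface"))
  if (g_value(surface, 0, 0) <= 0) {
    stop("reported table is not significant at this level", call. = FALSE)
  }
  tol <- 1e-9 * max(1, surface$scale)

  xs <- seq(0, x_scan_limit(surface), length.out = slices)
  roots <- slice_roots(surface, xs)
  dist2 <- xs^2 + roots^2
  best_idx <- which(dist2 == min(dist2, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  seed <- c(xs[best_idx[1L]], roots[best_idx[1L], best_idx[2L]])
  scan_best <- list(x = seed[1L], y = seed[2L],
                    distance = sqrt(sum(seed^2)))

  newton <- newton_gh(surface, seed, tol = tol)
  xc <- axis_intercept_x(surface)
  yc <- axis_intercept_y(surface)

  candidates <- list(
    list(x = xc, y = 0, source = "axis_x"),
    list(x = 0, y = yc, source = "axis_y"),
    list(x = scan_best$x, y = scan_best$y, source = "scan")
  )
  if (newton$converged && newton$x > -1e-9 && newton$y > -1e-9) {
    candidates <- c(
      list(list(x = max(0, newton$x), y = max(0, newton$y),
                source = "newton")),
      candidates
    )
  }
  # keep only candidates that truly sit on the boundary
  on_boundary <- vapply(
    candidates,
    function(p) abs(poly_eval(surface$g_poly, p$x, p$y)) <
      max(tol, 1e-6 * surface$scale),
    logical(1L)
  )
  candidates <- candidates[on_boundary]
  norms <- vapply(candidates, function(p) sqrt(p$x^2 + p$y^2), numeric(1L))
  pick <- candidates[[which.min(norms)]]

  list(
    x = pick$x, y = pick$y, distance = min(norms),
    diagnostics = list(
      source = pick$source,
      g_residual = abs(poly_eval(surface$g_poly, pick$x, pick$y)) /
        max(1, surface$scale),
      h_residual = abs(poly_eval(surface$h_poly, pick$x, pick$y)) /
        max(1, surface$scale),
      iterations = newton$iterations,
      candidates = length(candidates),
      converged = newton$converged
    )
  )
}

# damped Newton iteration on {g = 0, h = 0}
newton_gh <- function(surface, start, tol, max_iter = 100L) {
  p <- start
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    g <- poly_eval(surface$g_poly, p[1L], p[2L])
    h <- poly_eval(surface$h_poly, p[1L], p[2L])
    if (abs(g) < tol && abs(h) < tol) {
      converged <- TRUE
      break
    }
    jac <- matrix(
      c(poly_eval(surface$gx_poly, p[1L], p[2L]),
        poly_eval(surface$hx_poly, p[1L], p[2L]),
        poly_eval(surface$gy_poly, p[1L], p[2L]),
        poly_eval(surface$hy_poly, p[1L], p[2L])),
      2L, 2L
    )
    step <- tryCatch(solve(jac, c(g, h)), error = function(e) NULL)
    if (is.null(step) || anyNA(step)) break
    # damp steps that would fly far outside the seed's scale
    limit <- 0.5 * max(1, sqrt(sum(start^2)))
    if (sqrt(sum(step^2)) > limit) step <- step * limit / sqrt(sum(step^2))
    p <- p - step
    if (sqrt(sum(step^2)) < 1e-13 * max(1, sqrt(sum(p^2)))) {
      converged <- abs(poly_eval(surface$g_poly, p[1L], p[2L])) < tol
      break
    }
  }
  list(x = p[1L], y = p[2L], iterations = it, converged = converged)
}

#' Minimal combined redaction count
#'
#' The FOCK coordinates summed and rounded to the nearest integer: the
#' minimal total number of redacted subjects jointly attributable to the
#' two arms.  (Nearest-integer rounding of xe + ye reproduces the reference
#' worked values; the raw real sum is kept alongside it in [roar()] output.)
#'
#' @param x,y FOCK coordinates.
#' @export
r_min <- function(x, y) {
  as.integer(round(x + y))
}

#' Redaction tolerance metrics
#'
#' Fractions of each arm and of the total sample that must have been
#' redacted for significance to be lost:
#' \eqn{\rho_E = 1 - (a+b)/(a+b+x_c)},
#' \eqn{\rho_C = 1 - (c+d)/(c+d+y_c)},
#' \eqn{\rho_A = 1 - n/(n+r_{min})}.
#' The real-valued axis intercepts feed the per-arm tolerances; the integer
#' minimal count feeds the absolute tolerance.
#'
#' @inheritParams chi_square_statistic
#' @param xc,yc Real-valued axis intercepts.
#' @param rmin Integer minimal combined redaction.
#' @return A one-row tibble with columns `rho_e`, `rho_c`, `rho_a`
#'   (fractions in `[0, 1)`).
#' @export
redaction_metrics <- function(table, xc, yc, rmin) {
  t <- as_dichotomous_table(table)
  stopifnot(xc >= 0, yc >= 0, rmin >= 0)
  tibble::tibble(
    rho_e = 1 - (t$a + t$b) / (t$a + t$b + xc),
    rho_c = 1 - (t$c + t$d) / (t$c + t$d + yc),
    rho_a = 1 - t$n / (t$n + rmin)
  )
}

#' Full redaction analysis of a single 2x2 table
#'
#' Composes the whole pipeline: effect estimate, significance check,
#' surface construction, FOCK solve, axis intercepts, and tolerance
#' metrics.  A table that is not significant at `alpha` is returned as a
#' flagged result (`significant = FALSE`, all redaction quantities zero)
#' rather than an error, so batch and meta-analysis callers can proceed.
#'
#' @param a,b,c,d Nonnegative integer cell counts (experimental
#'   event/non-event, control event/non-event).
#' @param alpha Significance level, default 0.05.
#' @param level Confidence level for the relative-risk interval.
#' @param direction `"auto"`, `"rr_gt_1"`, or `"rr_lt_1"`.
#' @param slices Scan resolution handed to [fock_point()].
#' @return An object of class `roar_fit`; see [tidy.roar_fit()] and
#'   [glance.roar_fit()] for tabular views and [autoplot.roar_fit()] for a
#'   picture of the region.
#' @examples
#' fit <- roar(70, 30, 50, 50)
#' fit
#' glance(fit)
#' @export
roar <- function(a, b, c, d, alpha = 0.05, level = 0.95,
                 direction = "auto", slices = 2000L) {
  tab <- dichotomous_table(a, b, c, d)
  chi <- chi_square_statistic(tab)
  nu_c <- critical_value(alpha)
  eff <- relative_risk(tab, level = level)
  warnings <- character()

  if (chi <= nu_c) {
    warnings <- c(warnings, paste0(
      "reported table is not significant at alpha = ", format(alpha),
      " (chi-squared = ", format(chi, digits = 4),
      " <= ", format(nu_c, digits = 7), "); redaction analysis skipped"
    ))
    out <- list(
      table = tab, alpha = alpha, nu_c = nu_c,
      direction = if (eff$rr != 1) {
        if (eff$rr > 1) "rr_gt_1" else "rr_lt_1"
      } else NA_character_,
      effect = eff, chi_square = chi,
      p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
      significant = FALSE,
      surface = NULL,
      xe = 0, ye = 0, distance = 0, rmin_raw = 0, rmin = 0L,
      xc = 0, yc = 0, rho_e = 0, rho_c = 0, rho_a = 0,
      diagnostics = NULL, warnings = warnings
    )
    return(structure(out, class = "roar_fit"))
  }

  surface <- roar_surface(tab, alpha = alpha, direction = direction)
  fock <- fock_point(surface, slices = slices)
  xc <- axis_intercept_x(surface)
  yc <- axis_intercept_y(surface)
  rmin <- r_min(fock$x, fock$y)
  metrics <- redaction_metrics(tab, xc, yc, rmin)

  structure(
    list(
      table = tab, alpha = alpha, nu_c = nu_c,
      direction = surface$direction,
      effect = eff, chi_square = chi,
      p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
      significant = TRUE,
      surface = surface,
      xe = fock$x, ye = fock$y, distance = fock$distance,
      rmin_raw = fock$x + fock$y, rmin = rmin,
      xc = xc, yc = yc,
      rho_e = metrics$rho_e, rho_c = metrics$rho_c, rho_a = metrics$rho_a,
      diagnostics = fock$diagnostics, warnings = warnings
    ),
    class = "roar_fit"
  )
}

#' @export
print.roar_fit <- function(x, ...) {
  t <- x$table
  cat("Region of Attainable Redaction analysis\n")
  cat(sprintf("  table: a=%d b=%d c=%d d=%d (n=%d), alpha=%s\n",
              t$a, t$b, t$c, t$d, t$n, format(x$alpha)))
  cat(sprintf("  RR = %.2f (%.2f-%.2f), chi-squared = %.3f, p = %.3g\n",
              x$effect$rr, x$effect$ci_low, x$effect$ci_high,
              x$chi_square, x$p_value))
  if (!x$significant) {
    cat("  not significant at this level: no redaction needed to nullify\n")
    return(invisible(x))
  }
  cat(sprintf("  FOCK point (xe, ye) = (%.2f, %.2f), |FOCK| = %.2f\n",
              x$xe, x$ye, x$distance))
  cat(sprintf("  rmin = %d subjects (raw %.2f)\n", x$rmin, x$rmin_raw))
  cat(sprintf("  axis intercepts: xc = %.2f, yc = %.2f\n", x$xc, x$yc))
  cat(sprintf(
    "  tolerances: rho_E = %.2f%%, rho_C = %.2f%%, rho_A = %.2f%%\n",
    100 * x$rho_e, 100 * x$rho_c, 100 * x$rho_a))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Tidy a redaction analysis
#'
#' One row per reported quantity with its value; long format in the broom
#' tradition.
#'
#' @param x A [roar()] fit.
#' @param ... Unused.
#' @export
tidy.roar_fit <- function(x, ...) {
  tibble::tibble(
    quantity = c("rr", "ci_low", "ci_high", "chi_square", "p_value",
                 "xe", "ye", "fock_distance", "rmin", "xc", "yc",
                 "rho_e", "rho_c", "rho_a"),
    value = c(x$effect$rr, x$effect$ci_low, x$effect$ci_high,
              x$chi_square, x$p_value,
              x$xe, x$ye, x$distance, x$rmin, x$xc, x$yc,
              x$rho_e, x$rho_c, x$rho_a)
  )
}

#' Glance at a redaction analysis
#'
#' One-row wide summary of the fit, suitable for binding across many
#' tables.
#'
#' @inheritParams tidy.roar_fit
#' @export
glance.roar_fit <- function(x, ...) {
  t <- x$table
  tibble::tibble(
    a = t$a, b = t$b, c = t$c, d = t$d, n = t$n,
    alpha = x$alpha, nu_c = x$nu_c,
    direction = x$direction,
    rr = x$effect$rr, ci_low = x$effect$ci_low, ci_high = x$effect$ci_high,
    chi_square = x$chi_square, p_value = x$p_value,
    significant = x$significant,
    xe = x$xe, ye = x$ye, fock_distance = x$distance,
    rmin = x$rmin, rmin_raw = x$rmin_raw,
    xc = x$xc, yc = x$yc,
    rho_e = x$rho_e, rho_c = x$rho_c, rho_a = x$rho_a
  )
}

#' Redaction analysis over a data frame of tables
#'
#' Data-frame-first driver: runs [roar()] on every row of `data` (columns
#' `a`, `b`, `c`, `d`) and binds the [glance.roar_fit()] summaries.  Extra
#' columns of `data` (for example study labels) are carried through.
#'
#' @param data A data frame with integer columns `a`, `b`, `c`, `d`.
#' @inheritParams roar
#' @return A tibble, one row per input table.
#' @examples
#' tibble::tibble(a = c(70, 50), b = c(30, 50),
#'                c = c(50, 70), d = c(50, 30)) |>
#'   roar_analyze()
#' @export
roar_analyze <- function(data, alpha = 0.05, level = 0.95,
                         slices = 2000L) {
  check_table_columns(data)
  extra <- dplyr::select(tibble::as_tibble(data),
                         -dplyr::all_of(c("a", "b", "c", "d")))
  fits <- purrr::pmap(
    dplyr::select(data, "a", "b", "c", "d"),
    function(a, b, c, d) {
      glance(roar(a, b, c, d, alpha = alpha, level = level,
                  slices = slices))
    }
  )
  dplyr::bind_cols(extra, dplyr::bind_rows(fits))
}
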