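# Brute-force oracles.  These live in the installed package (not only the
# test-suite) so the CLI can expose on-demand verification, but they never
# produce headline outputs: they exist to validate the Lagrange solution
# and the rounding conventions against exhaustive search.

#' Exhaustive integer-redaction minimum
#'
#' Scans all integer redaction pairs with `x + y <= max_total` and returns
#' the smallest total count whose restored table is not significant, with
#' one minimising pair (ties broken by smallest x).  This is the integer
#' L1 analogue of the Euclidean FOCK summary and can legitimately be
#' smaller than `rmin`; it is exposed as a diagnostic only.
#'
#' @param surface A [roar_surface()] of a significant table.
#' @param max_total Upper bound on the total scanned (raised by the caller
#'   on a bound-exceeded error).
#' @return A list with `min_total`, `x`, `y`.
#' @export
integer_min_redaction <- function(surface, max_total = 200L) {
  stopifnot(inherits(surface, "roar_surface"), max_total >= 1L)
  if (g_value(surface, 0, 0) <= 0) {
    stop("reported table is not significant at this level", call. = FALSE)
  }
  for (total in seq_len(max_total)) {
    x <- 0:total
    y <- total - x
    hit <- which(roar_contains(surface, x, y))
    if (length(hit)) {
      i <- hit[1L] # smallest x among ties
      return(list(min_total = total, x = x[i], y = y[i]))
    }
  }
  stop("no feasible integer redaction with total <= ", max_total,
       "; raise max_total", call. = FALSE)
}

#' Grid-scan minimum boundary distance
#'
#' Samples the region boundary with vertical slices across the region's
#' x-extent (plus the two axis intercepts), then re-scans locally around
#' the incumbent minimum, and returns the boundary sample closest to the
#' origin.  Serves as the independent oracle for [fock_point()]: every
#' sample is a true boundary point, so the scan minimum converges to the
#' FOCK distance from above as the slice count grows.
#'
#' @param surface A [roar_surface()] of a significant table.
#' @param slices Number of slice positions (>= 100).
#' @return A list with `distance`, `x`, `y`.
#' @export
grid_min_distance <- function(surface, slices = 10000L) {
  stopifnot(inherits(surface, "roar_surface"), slices >= 100L)
  if (g_value(surface, 0, 0) <= 0) {
    stop("reported table is not significant at this level", call. = FALSE)
  }
  x_max <- x_scan_limit(surface)
  lo <- 0
  hi <- x_max
  best_pt <- c(NA_real_, NA_real_)
  # coarse pass plus local refinements around the incumbent minimum, so the
  # scan resolves the minimum even when the region sits close to the origin
  for (pass in 1:3) {
    xs <- seq(lo, hi, length.out = slices)
    roots <- slice_roots(surface, xs)
    dist2 <- xs^2 + roots^2
    best <- which(dist2 == min(dist2, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    best_pt <- c(xs[best[1L]], roots[best[1L], best[2L]])
    dx <- (hi - lo) / (slices - 1L)
    lo <- max(0, best_pt[1L] - 2 * dx)
    hi <- min(x_max, best_pt[1L] + 2 * dx)
  }
  # axis intercepts are boundary points too
  xc <- axis_intercept_x(surface)
  yc <- axis_intercept_y(surface)
  cand <- rbind(best_pt, c(xc, 0), c(0, yc), deparse.level = 0)
  d <- sqrt(cand[, 1L]^2 + cand[, 2L]^2)
  i <- which.min(d)
  list(distance = d[i], x = cand[i, 1L], y = cand[i, 2L])
}

#' Generate random significant 2x2 tables
#'
#' Rejection sampler used to build test fixtures: draws a total sample
#' size uniformly from `n_range`, allocates it to the four cells by a
#' symmetric multinomial, and keeps the table only when all margins are
#' positive, the risk ratio differs from 1, and the uncorrected
#' chi-squared statistic exceeds the critical value at `alpha`.
#' Deterministic for a fixed RNG seed (set `seed`, or call `set.seed()`
#' beforehand).
#'
#' @param n_tables Number of tables to generate.
#' @param n_range Inclusive range of total sample sizes.
#' @param alpha Significance level every emitted table must beat.
#' @param seed Optional integer seed applied before sampling.
#' @param max_draws Rejection-sampling budget per table.
#' @return A tibble with columns `a`, `b`, `c`, `d`.
#' @examples
#' simulate_significant_tables(3, seed = 1)
#' @export
simulate_significant_tables <- function(n_tables = 1L,
                                        n_range = c(40L, 400L),
                                        alpha = 0.05,
                                        seed = NULL,
                                        max_draws = 1e5) {
  stopifnot(length(n_range) == 2L, n_range[1L] >= 8L,
            n_range[2L] >= n_range[1L], n_tables >= 1L)
  if (!is.null(seed)) set.seed(seed)
  nu_c <- critical_value(alpha)
  draw_one <- function() {
    for (i in seq_len(max_draws)) {
      n <- sample(n_range[1L]:n_range[2L], 1L)
      cells <- as.vector(stats::rmultinom(1L, n, rep(0.25, 4L)))
      a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
      margins <- c(a + b, c + d, a + c, b + d)
      if (any(margins == 0) || a == 0 || c == 0) next
      if (a * d == b * c) next
      tab <- list(a = a, b = b, c = c, d = d, n = n)
      if (chi_square_statistic(tab) > nu_c) {
        return(tibble::tibble(a = a, b = b, c = c, d = d))
      }
    }
    stop("failed to draw a significant table within ", max_draws,
         " attempts; widen n_range", call. = FALSE)
  }
  dplyr::bind_rows(purrr::map(seq_len(n_tables), function(i) draw_one()))
}
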