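test_that("vectorised closed-form cubic solver agrees with polyroot", {
  set.seed(7)
  for (rep in 1:200) {
    co <- round(stats::rnorm(4, sd = 10), 3)
    if (all(co == 0)) next
    got <- roar:::cubic_roots_real(matrix(co, 1L))
    got <- sort(got[!is.na(got)])
    cr <- polyroot(co[seq_len(max(which(co != 0)))])
    want <- sort(Re(cr[abs(Im(cr)) < 1e-7 * pmax(1, abs(cr))]))
    expect_equal(length(got), length(want), info = paste(co, collapse = ","))
    if (length(want)) {
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("g at the origin is the reported statistic minus the critical value", {
  for (s in list(surf_gt(), surf_lt(), surf_meta())) {
    expect_equal(g_value(s, 0, 0),
                 chi_square_statistic(s$table) - s$nu_c)
    expect_gt(g_value(s, 0, 0), 0) # sign anchor for significant tables
  }
})

test_that("equal-risk restoration x = ad/c - b zeroes the restored statistic", {
  s <- surf_gt()
  x_eq <- with(s$table, a * d / c - b) # 40 for the worked table
  expect_equal(x_eq, 40)
  expect_equal(g_value(s, x_eq, 0), -s$nu_c)
  expect_equal(restored_chisq_oracle(s$table, s$direction, x_eq, 0), 0)
})

test_that("monomial expansion is cubic with at most 15 terms and a zero (3,3) term", {
  for (s in list(surf_gt(), surf_lt(), surf_meta())) {
    coefs <- expand_polynomial(s)
    expect_lte(nrow(coefs), 15L)
    expect_true(all(coefs$i <= 3L & coefs$j <= 3L))
    expect_false(any(coefs$i == 3L & coefs$j == 3L))
    # constant term: n (ad - bc)^2 - nu_c (a+b)(c+d)(a+c)(b+d)
    t <- s$table
    expect_equal(
      coefs$coefficient[coefs$i == 0L & coefs$j == 0L],
      t$n * (t$a * t$d - t$b * t$c)^2 -
        s$nu_c * (t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d)
    )
  }
})

test_that("polynomial form equals the denominator-cleared rational form", {
  set.seed(11)
  for (s in list(surf_gt(), surf_lt(), surf_meta())) {
    x <- stats::runif(1000, 0, 50)
    y <- stats::runif(1000, 0, 50)
    r <- roar:::restored_cells(s, x, y)
    denom <- (r$a + r$b) * (r$c + r$d) * (r$a + r$c) * (r$b + r$d)
    cleared <- g_value(s, x, y) * denom
    poly <- roar:::poly_eval(s$g_poly, x, y)
    expect_equal(poly, cleared, tolerance = 1e-9)
  }
})

test_that("a unit table at a vanishing threshold reduces to (4+x+y)(1-(1+x)(1+y))^2", {
  s <- roar_surface(dichotomous_table(1, 1, 1, 1), alpha = 1 - 1e-13,
                    direction = "rr_gt_1")
  pts <- expand.grid(x = 0:4, y = 0:4)
  expect_equal(
    roar:::poly_eval(s$g_poly, pts$x, pts$y),
    (4 + pts$x + pts$y) * (1 - (1 + pts$x) * (1 + pts$y))^2,
    tolerance = 1e-8
  )
})

test_that("arm-swapped surface mirrors g across the diagonal", {
  set.seed(23)
  tabs <- fixture_tables(10L)
  for (k in seq_len(nrow(tabs))) {
    t <- dichotomous_table(tabs$a[k], tabs$b[k], tabs$c[k], tabs$d[k])
    s <- roar_surface(t)
    sm <- roar_surface(swap_arms(t))
    x <- stats::runif(50, 0, 30)
    y <- stats::runif(50, 0, 30)
    expect_equal(g_value(sm, x, y), g_value(s, y, x), tolerance = 1e-12)
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(31)
  for (s in list(surf_gt(), surf_meta())) {
    x <- stats::runif(100, 0.1, 30)
    y <- stats::runif(100, 0.1, 30)
    gr <- grad_g(s, x, y)
    hstep <- 1e-5 * pmax(1, abs(x))
    fd_x <- (roar:::poly_eval(s$g_poly, x + hstep, y) -
               roar:::poly_eval(s$g_poly, x - hstep, y)) / (2 * hstep)
    hstep <- 1e-5 * pmax(1, abs(y))
    fd_y <- (roar:::poly_eval(s$g_poly, x, y + hstep) -
               roar:::poly_eval(s$g_poly, x, y - hstep)) / (2 * hstep)
    expect_equal(gr$dg_dx, fd_x, tolerance = 1e-5)
    expect_equal(gr$dg_dy, fd_y, tolerance = 1e-5)
  }
})

test_that("gradient obeys the arm-swap mirror symmetry", {
  s <- surf_gt()
  sm <- roar_surface(swap_arms(tab_gt()))
  p <- c(3.2, 7.5)
  expect_equal(grad_g(s, p[1], p[2])$dg_dx,
               grad_g(sm, p[2], p[1])$dg_dy)
})

test_that("h eliminates the multiplier: zero at origin, single term on axes", {
  for (s in list(surf_gt(), surf_meta())) {
    expect_identical(h_value(s, 0, 0), 0)
    y <- c(1.5, 4, 9)
    expect_equal(h_value(s, 0, y), y * grad_g(s, 0, y)$dg_dx)
    x <- c(2.5, 6)
    expect_equal(h_value(s, x, 0), -x * grad_g(s, x, 0)$dg_dy)
    # polynomial in two variables with at most 18 monomials
    expect_lte(sum(s$h_poly != 0), 18L)
  }
})

test_that("membership agrees with exhaustive integer evaluation near the boundary", {
  s <- surf_gt()
  expect_false(roar_contains(s, 0, 0))
  expect_true(roar_contains(s, 40, 0))
  expect_true(roar_contains(s, 9, 2))
  expect_false(roar_contains(s, 8, 2))
  # cross-check the two frozen cases against the independent statistic
  expect_lte(restored_chisq_oracle(s$table, s$direction, 9, 2), s$nu_c)
  expect_gt(restored_chisq_oracle(s$table, s$direction, 8, 2), s$nu_c)
})

test_that("boundary slices return ordered nonnegative roots of g", {
  s <- surf_gt()
  expect_length(boundary_slice(s, 1e4), 0L)
  roots0 <- boundary_slice(s, 0)
  expect_gt(length(roots0), 0L)
  expect_gt(roots0[1L], 16)
  expect_lt(roots0[1L], 17)
  for (x0 in c(0, 2, 5, 10.5, 20)) {
    r <- boundary_slice(s, x0)
    expect_true(all(diff(r) >= 0))
    if (length(r)) {
      expect_lt(max(abs(roar:::poly_eval(s$g_poly, rep(x0, length(r)), r))),
                1e-8 * s$scale)
    }
  }
})

test_that("boundary polyline lies on g = 0 and contains both axis intercepts", {
  s <- surf_gt()
  pts <- roar_boundary(s, n = 256L)
  expect_lt(max(abs(roar:::poly_eval(s$g_poly, pts$x, pts$y))),
            1e-6 * s$scale)
  expect_true(any(pts$x == 0 & abs(pts$y - axis_intercept_y(s)) < 1e-8))
  expect_true(any(pts$y == 0 & abs(pts$x - axis_intercept_x(s)) < 1e-8))
})
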