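# Internal bivariate polynomial arithmetic.
#
# A polynomial p(x, y) is stored as a dense coefficient matrix C where
# C[i + 1, j + 1] is the coefficient of x^i * y^j.  The surfaces handled
# here never exceed degree 3 in either variable, so matrices stay tiny and
# dense arithmetic is both exact (plain double products of integer inputs)
# and fast.

poly_const <- function(value) matrix(value, 1L, 1L)

# linear form c0 + cx*x + cy*y + cxy*x*y
poly_bilinear <- function(c0, cx, cy, cxy = 0) {
  matrix(c(c0, cx, cy, cxy), nrow = 2L, ncol = 2L)
}

poly_add <- function(a, b) {
  nr <- max(nrow(a), nrow(b))
  nc <- max(ncol(a), ncol(b))
  out <- matrix(0, nr, nc)
  out[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  out[seq_len(nrow(b)), seq_len(ncol(b))] <-
    out[seq_len(nrow(b)), seq_len(ncol(b))] + b
  out
}

poly_scale <- function(a, k) a * k

poly_mul <- function(a, b) {
  out <- matrix(0, nrow(a) + nrow(b) - 1L, ncol(a) + ncol(b) - 1L)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] != 0) {
        ri <- i:(i + nrow(b) - 1L)
        rj <- j:(j + ncol(b) - 1L)
        out[ri, rj] <- out[ri, rj] + a[i, j] * b
      }
    }
  }
  out
}

# drop trailing all-zero rows/columns so matrix dimensions equal degree + 1
poly_trim <- function(a) {
  while (nrow(a) > 1L && all(a[nrow(a), ] == 0)) a <- a[-nrow(a), , drop = FALSE]
  while (ncol(a) > 1L && all(a[, ncol(a)] == 0)) a <- a[, -ncol(a), drop = FALSE]
  a
}

# partial derivatives
poly_dx <- function(a) {
  if (nrow(a) == 1L) return(matrix(0, 1L, ncol(a)))
  d <- a[-1L, , drop = FALSE]
  d * seq_len(nrow(d))
}

poly_dy <- function(a) {
  if (ncol(a) == 1L) return(matrix(0, nrow(a), 1L))
  d <- a[, -1L, drop = FALSE]
  t(t(d) * seq_len(ncol(d)))
}

# multiply by x or y (index shift)
poly_shift_x <- function(a) rbind(matrix(0, 1L, ncol(a)), a)
poly_shift_y <- function(a) cbind(matrix(0, nrow(a), 1L), a)

# vectorised Horner evaluation over paired (x, y)
poly_eval <- function(a, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  acc <- rep_len(0, n)
  for (i in rev(seq_len(nrow(a)))) {
    row_val <- rep_len(0, n)
    for (j in rev(seq_len(ncol(a)))) {
      row_val <- row_val * y + a[i, j]
    }
    acc <- acc * x + row_val
  }
  acc
}

# Coefficients of the univariate cubic in y obtained by fixing x = x0,
# vectorised over x0: returns a length(x0) x ncol(a) matrix, column k the
# coefficient of y^(k-1).
poly_y_coefs <- function(a, x0) {
  x0 <- as.numeric(x0)
  out <- matrix(0, length(x0), ncol(a))
  for (j in seq_len(ncol(a))) {
    acc <- rep_len(0, length(x0))
    for (i in rev(seq_len(nrow(a)))) acc <- acc * x0 + a[i, j]
    out[, j] <- acc
  }
  out
}

# Real roots of many cubics at once.  `coefs` is an n x 4 matrix, column k
# the coefficient of t^(k-1); rows may degenerate to quadratics/linears.
# Returns an n x 3 matrix of real roots (NA where absent), unsorted.
# Closed-form (trigonometric / Cardano) solution polished by Newton steps;
# stats::polyroot serves as the independent oracle in the test-suite.
cubic_roots_real <- function(coefs) {
  n <- nrow(coefs)
  roots <- matrix(NA_real_, n, 3L)
  scale <- pmax(apply(abs(coefs), 1L, max), .Machine$double.xmin)
  co <- coefs / scale
  c0 <- co[, 1L]; c1 <- co[, 2L]; c2 <- co[, 3L]; c3 <- co[, 4L]

  cubic <- abs(c3) > 1e-12
  # --- genuine cubics: depress t = s - c2/(3 c3)
  if (any(cubic)) {
    i <- which(cubic)
    b <- c2[i] / c3[i]; c <- c1[i] / c3[i]; d <- c0[i] / c3[i]
    p <- c - b^2 / 3
    q <- 2 * b^3 / 27 - b * c / 3 + d
    disc <- -4 * p^3 - 27 * q^2
    shift <- -b / 3

    three <- disc >= 0 & p < 0
    if (any(three)) {
      j <- which(three)
      m <- 2 * sqrt(-p[j] / 3)
      arg <- pmin(1, pmax(-1, 3 * q[j] / (p[j] * m)))
      theta <- acos(arg) / 3
      for (k in 0:2) {
        roots[i[j], k + 1L] <- m * cos(theta - 2 * pi * k / 3) + shift[j]
      }
    }
    one <- !three
    if (any(one)) {
      j <- which(one)
      # Cardano, numerically-stable branch for the single real root
      rt <- sqrt(pmax(0, q[j]^2 / 4 + p[j]^3 / 27))
      u <- -q[j] / 2 - sign(q[j]) * rt
      u[u == 0] <- (-q[j] / 2 + rt)[u == 0]
      cu <- sign(u) * abs(u)^(1 / 3)
      v <- ifelse(cu != 0, -p[j] / (3 * cu), 0)
      roots[i[j], 1L] <- cu + v + shift[j]
    }
  }
  # --- quadratic fallback rows
  quad <- !cubic & abs(c2) > 1e-12
  if (any(quad)) {
    i <- which(quad)
    disc <- c1[i]^2 - 4 * c2[i] * c0[i]
    ok <- disc >= 0
    j <- i[ok]
    if (length(j)) {
      sq <- sqrt(disc[ok])
      roots[j, 1L] <- (-c1[j] - sq) / (2 * c2[j])
      roots[j, 2L] <- (-c1[j] + sq) / (2 * c2[j])
    }
  }
  lin <- !cubic & !quad & abs(c1) > 1e-12
  if (any(lin)) {
    i <- which(lin)
    roots[i, 1L] <- -c0[i] / c1[i]
  }

  # Newton polish on the original (scaled) cubic
  for (step in 1:3) {
    f <- co[, 1L] + roots * (co[, 2L] + roots * (co[, 3L] + roots * co[, 4L]))
    fp <- co[, 2L] + roots * (2 * co[, 3L] + roots * 3 * co[, 4L])
    upd <- ifelse(is.na(roots) | abs(fp) < 1e-14, 0, f / fp)
    roots <- roots - upd
  }
  roots
}
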