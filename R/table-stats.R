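#' Construct a validated 2x2 dichotomous-outcome table
#'
#' The four cells follow the usual trial layout: `a` endpoint-positive and
#' `b` endpoint-negative subjects in the experimental (or exposure) arm,
#' `c` endpoint-positive and `d` endpoint-negative subjects in the control
#' arm.  All cells must be nonnegative integers and every margin (both arms
#' and both outcome columns) must be positive, otherwise the chi-squared
#' statistic and the relative risk are undefined.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @return An object of class `dichotomous_table`: a list with fields
#'   `a`, `b`, `c`, `d` and the derived total `n = a + b + c + d`.
#' @examples
#' tab <- dichotomous_table(70, 30, 50, 50)
#' chi_square_statistic(tab)
#' @export
dichotomous_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (length(cells) != 4L || !is.numeric(cells) || anyNA(cells)) {
    stop("cells a, b, c, d must be four non-missing numbers", call. = FALSE)
  }
  if (any(cells < 0) || any(abs(cells - round(cells)) > 1e-8)) {
    stop("cells a, b, c, d must be nonnegative integers", call. = FALSE)
  }
  if (sum(cells) > .Machine$integer.max) {
    stop("table total exceeds the representable integer range",
         call. = FALSE)
  }
  cells <- stats::setNames(as.integer(round(cells)), names(cells))
  margins <- c(cells["a"] + cells["b"], cells["c"] + cells["d"],
               cells["a"] + cells["c"], cells["b"] + cells["d"])
  if (any(margins == 0L)) {
    stop("all four margins of the 2x2 table must be positive", call. = FALSE)
  }
  structure(
    list(a = unname(cells["a"]), b = unname(cells["b"]),
         c = unname(cells["c"]), d = unname(cells["d"]),
         n = unname(sum(cells))),
    class = "dichotomous_table"
  )
}

as_dichotomous_table <- function(x) {
  if (inherits(x, "dichotomous_table")) return(x)
  if (is.list(x) || is.data.frame(x)) {
    return(dichotomous_table(x$a, x$b, x$c, x$d))
  }
  if (is.numeric(x) && length(x) == 4L) {
    return(dichotomous_table(x[1L], x[2L], x[3L], x[4L]))
  }
  stop("cannot interpret input as a 2x2 dichotomous table", call. = FALSE)
}

#' @export
print.dichotomous_table <- function(x, ...) {
  cat("2x2 dichotomous-outcome table (n = ", x$n, ")\n", sep = "")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2L, 2L,
              dimnames = list(c("experimental", "control"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Pearson chi-squared statistic of a 2x2 table
#'
#' Computes the uncorrected Pearson statistic
#' \eqn{n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))} with one degree of freedom.
#' No continuity correction is applied anywhere in this package.
#'
#' @param table A [dichotomous_table()], a list/data frame with fields
#'   `a`, `b`, `c`, `d`, or a length-4 numeric vector.
#' @return The chi-squared statistic, zero exactly when `ad = bc`.
#' @export
chi_square_statistic <- function(table) {
  t <- as_dichotomous_table(table)
  # double arithmetic: margin products overflow integer range for large trials
  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d)
  cross <- a * d - b * c
  (a + b + c + d) * cross^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

#' Chi-squared critical value for a significance level
#'
#' The \eqn{(1 - \alpha)} quantile of the chi-squared distribution with one
#' degree of freedom; the boundary value \eqn{\nu_c} that the restored-table
#' statistic is compared against throughout the redaction analysis.
#'
#' @param alpha Significance level in (0, 1); 0.05 gives 3.841459.
#' @export
critical_value <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  stats::qchisq(1 - alpha, df = 1L)
}

#' Relative risk with a Katz log-scale Wald confidence interval
#'
#' The relative risk of the experimental versus the control arm,
#' \eqn{RR = a(c+d) / (c(a+b))}, with the standard Katz interval
#' \eqn{\exp(\log RR \pm z \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)})}.
#'
#' @inheritParams chi_square_statistic
#' @param level Confidence level, default 0.95.
#' @return A one-row tibble with columns `rr`, `ci_low`, `ci_high`, `level`.
#' @export
relative_risk <- function(table, level = 0.95) {
  t <- as_dichotomous_table(table)
  if (t$a == 0 || t$c == 0) {
    stop("relative risk interval undefined: zero endpoint-positive cell",
         call. = FALSE)
  }
  rr <- t$a * (t$c + t$d) / (t$c * (t$a + t$b))
  se <- sqrt(1 / t$a - 1 / (t$a + t$b) + 1 / t$c - 1 / (t$c + t$d))
  z <- stats::qnorm((1 + level) / 2)
  tibble::tibble(
    rr = rr,
    ci_low = rr * exp(-z * se),
    ci_high = rr * exp(z * se),
    level = level
  )
}

#' Classify the effect direction of a 2x2 table
#'
#' Returns `"rr_gt_1"` when the experimental arm carries the greater risk
#' and `"rr_lt_1"` when it carries the lower risk.  The direction selects
#' which cells hypothetical redactions are restored to: for `rr_gt_1` the
#' restored table is `(a, b + x; c + y, d)`, for `rr_lt_1` it is
#' `(a + x, b; c, d + y)`.
#'
#' @inheritParams chi_square_statistic
#' @export
classify_direction <- function(table) {
  t <- as_dichotomous_table(table)
  if (t$a == 0 || t$c == 0) {
    stop("direction undefined: zero endpoint-positive cell", call. = FALSE)
  }
  rr <- t$a * (t$c + t$d) / (t$c * (t$a + t$b))
  if (rr > 1) return("rr_gt_1")
  if (rr < 1) return("rr_lt_1")
  stop("relative risk is exactly 1: no effect, redaction analysis undefined",
       call. = FALSE)
}

#' Effect summaries for one or more 2x2 tables
#'
#' Data-frame-first wrapper: takes a data frame with integer columns
#' `a`, `b`, `c`, `d` (one trial per row) and returns, per row, the
#' relative risk and its confidence interval, the uncorrected chi-squared
#' statistic, its one-degree-of-freedom p-value, and the effect direction.
#'
#' @param data A data frame with columns `a`, `b`, `c`, `d`.
#' @param level Confidence level for the relative-risk interval.
#' @return `data` with columns `rr`, `ci_low`, `ci_high`, `chi_square`,
#'   `p_value`, `direction` appended, as a tibble.
#' @examples
#' trial_effects(tibble::tibble(a = 70, b = 30, c = 50, d = 50))
#' @export
trial_effects <- function(data, level = 0.95) {
  check_table_columns(data)
  res <- purrr::pmap(
    dplyr::select(data, "a", "b", "c", "d"),
    function(a, b, c, d) {
      tab <- dichotomous_table(a, b, c, d)
      eff <- relative_risk(tab, level = level)
      chi <- chi_square_statistic(tab)
      tibble::tibble(
        rr = eff$rr, ci_low = eff$ci_low, ci_high = eff$ci_high,
        chi_square = chi,
        p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
        direction = if (eff$rr > 1) "rr_gt_1" else if (eff$rr < 1)
          "rr_lt_1" else NA_character_
      )
    }
  )
  dplyr::bind_cols(tibble::as_tibble(data), dplyr::bind_rows(res))
}

check_table_columns <- function(data, cols = c("a", "b", "c", "d")) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame", call. = FALSE)
  }
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("`data` is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(data)
}
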