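#' Crude pooled risk ratio of several 2x2 tables
#'
#' Cells are summed across studies and the relative risk of the pooled
#' table is taken:
#' \eqn{RR_C = \sum a_i \sum (c_i + d_i) / (\sum c_i \sum (a_i + b_i))}.
#'
#' @param data A data frame with one study per row and integer columns
#'   `a`, `b`, `c`, `d` (an optional `study` label column is ignored here).
#' @export
pooled_crude_rr <- function(data) {
  check_table_columns(data)
  a <- sum(data$a); b <- sum(data$b); c <- sum(data$c); d <- sum(data$d)
  if (a == 0 || c == 0) {
    stop("pooled risk ratio undefined: zero pooled endpoint-positive cell",
         call. = FALSE)
  }
  a * (c + d) / (c * (a + b))
}

#' Cochran-Mantel-Haenszel pooled risk ratio
#'
#' Stratum-weighted pooled risk ratio,
#' \eqn{RR_{CMH} = \sum a_i (c_i + d_i)/n_i \; / \; \sum c_i (a_i+b_i)/n_i},
#' which adjusts for between-study confounding.  Equals the crude ratio
#' exactly for a single stratum.
#'
#' @inheritParams pooled_crude_rr
#' @export
cmh_rr <- function(data) {
  check_table_columns(data)
  n_i <- data$a + data$b + data$c + data$d
  if (any(n_i == 0)) {
    stop("every study must have a positive total", call. = FALSE)
  }
  num <- sum(data$a * (data$c + data$d) / n_i)
  den <- sum(data$c * (data$a + data$b) / n_i)
  if (den == 0) {
    stop("CMH risk ratio undefined: zero denominator sum", call. = FALSE)
  }
  num / den
}

#' Pool studies and gate redaction analysis on confounding
#'
#' Sums the per-study tables cellwise, compares the crude pooled risk
#' ratio with the Cochran-Mantel-Haenszel adjusted ratio, and declares the
#' pooled redaction analysis applicable when the confounding magnitude
#' \eqn{|1 - RR_{CMH}/RR_C|} is strictly below `threshold` (default 10%).
#' When applicable (or when `gate_asserted = TRUE`, for pre-pooled tables
#' whose stratified data are unavailable), the pooled table is analysed
#' with [roar()].
#'
#' Studies with zero cells are accepted as long as the pooled margins are
#' positive; a warning is recorded since the CMH weights then lean on
#' sparse strata.
#'
#' @param data A data frame of studies with columns `a`, `b`, `c`, `d` and
#'   optionally `study` labels (must be unique when present).
#' @param threshold Confounding gate, a fraction; default 0.10.
#' @param alpha Significance level for the pooled redaction analysis.
#' @param gate_asserted Set `TRUE` when `data` is a single pre-pooled table
#'   and the confounding check has been established externally.
#' @return An object of class `roar_pool` with the pooled table, both risk
#'   ratios, the confounding magnitude, the applicability flag, and (when
#'   applicable) the pooled `roar_fit`.
#' @examples
#' studies <- tibble::tibble(
#'   study = c("s1", "s2"),
#'   a = c(35, 35), b = c(15, 15), c = c(25, 25), d = c(25, 25)
#' )
#' roar_pool(studies)
#' @export
roar_pool <- function(data, threshold = 0.10, alpha = 0.05,
                      gate_asserted = FALSE) {
  check_table_columns(data)
  if (!nrow(data)) stop("at least one study is required", call. = FALSE)
  if ("study" %in% names(data)) {
    labels <- as.character(data$study)
    if (anyDuplicated(labels) || any(!nzchar(labels)) || anyNA(labels)) {
      stop("study labels must be nonempty and unique", call. = FALSE)
    }
  } else {
    labels <- paste0("study_", seq_len(nrow(data)))
  }
  warnings <- character()
  if (any(data[c("a", "b", "c", "d")] == 0)) {
    warnings <- c(warnings,
                  "zero cells present in at least one study; CMH weights rely on sparse strata")
  }

  pooled <- dichotomous_table(sum(data$a), sum(data$b),
                              sum(data$c), sum(data$d))
  rr_crude <- pooled_crude_rr(data)
  rr_cmh <- cmh_rr(data)
  confounding <- abs(1 - rr_cmh / rr_crude)
  applicable <- confounding < threshold

  fit <- NULL
  if (applicable || gate_asserted) {
    fit <- roar(pooled$a, pooled$b, pooled$c, pooled$d, alpha = alpha)
  } else {
    warnings <- c(warnings, sprintf(
      "confounding magnitude %.4f >= threshold %.4f: direct redaction analysis of the pooled table is not applicable",
      confounding, threshold))
  }

  structure(
    list(
      studies = tibble::as_tibble(dplyr::mutate(
        dplyr::select(data, dplyr::any_of(c("a", "b", "c", "d"))),
        study = labels, .before = 1L)),
      pooled = pooled,
      rr_crude = rr_crude, rr_cmh = rr_cmh,
      confounding = confounding, threshold = threshold,
      roar_applicable = applicable, gate_asserted = gate_asserted,
      fit = fit, warnings = warnings
    ),
    class = "roar_pool"
  )
}

#' @export
print.roar_pool <- function(x, ...) {
  cat("Pooled redaction analysis (", nrow(x$studies), " stud",
      if (nrow(x$studies) == 1L) "y" else "ies", ")\n", sep = "")
  p <- x$pooled
  cat(sprintf("  pooled table: a=%d b=%d c=%d d=%d (n=%d)\n",
              p$a, p$b, p$c, p$d, p$n))
  cat(sprintf("  RR crude = %.4f, RR CMH = %.4f, confounding = %.4f%%\n",
              x$rr_crude, x$rr_cmh, 100 * x$confounding))
  cat("  redaction analysis of the pooled table is ",
      if (x$roar_applicable) "applicable" else "NOT applicable",
      if (x$gate_asserted) " (gate asserted externally)" else "",
      "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  if (!is.null(x$fit)) {
    cat("\n")
    print(x$fit)
  }
  invisible(x)
}

#' Tidy a pooled analysis
#'
#' The per-study tables with each study's own risk ratio.
#'
#' @param x A [roar_pool()] object.
#' @param ... Unused.
#' @export
tidy.roar_pool <- function(x, ...) {
  dplyr::mutate(
    x$studies,
    rr = .data$a * (.data$c + .data$d) / (.data$c * (.data$a + .data$b))
  )
}

#' Glance at a pooled analysis
#'
#' One-row summary: pooled cells, both pooled risk ratios, confounding
#' magnitude, gate outcome, and (when run) the pooled redaction summary.
#'
#' @inheritParams tidy.roar_pool
#' @export
glance.roar_pool <- function(x, ...) {
  base <- tibble::tibble(
    n_studies = nrow(x$studies),
    a = x$pooled$a, b = x$pooled$b, c = x$pooled$c, d = x$pooled$d,
    n = x$pooled$n,
    rr_crude = x$rr_crude, rr_cmh = x$rr_cmh,
    confounding = x$confounding, threshold = x$threshold,
    roar_applicable = x$roar_applicable
  )
  if (is.null(x$fit)) return(base)
  dplyr::bind_cols(
    base,
    dplyr::select(glance(x$fit), -dplyr::all_of(c("a", "b", "c", "d", "n")))
  )
}

#' Read a study CSV
#'
#' Reads a UTF-8 comma-separated file whose header is exactly
#' `study,a,b,c,d`, one study per row with integer cells, and returns a
#' tibble ready for [roar_pool()].
#'
#' @param path Path to the CSV file.
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (!identical(trimws(header), "study,a,b,c,d")) {
    stop("CSV header must be exactly 'study,a,b,c,d' (got '",
         trimws(header), "')", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  for (col in c("a", "b", "c", "d")) {
    if (!col %in% names(df)) {
      stop("CSV is missing column '", col, "'", call. = FALSE)
    }
    v <- df[[col]]
    if (!is.numeric(v)) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
    bad <- is.na(v) | v < 0 | abs(v - round(v)) > 1e-8
    if (any(bad)) {
      stop("column '", col, "' must contain nonnegative integers ",
           "(check row ", paste(which(bad), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}
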