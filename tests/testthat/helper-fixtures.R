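# Shared fixtures for the test-suite.  All tables are built in code; the
# three reference tables are the worked examples analysed throughout the
# documentation.

tab_gt <- function() dichotomous_table(70, 30, 50, 50)   # RR > 1
tab_lt <- function() dichotomous_table(50, 50, 70, 30)   # arm-swapped twin
tab_meta <- function() dichotomous_table(397, 19204, 468, 19128)

surf_gt <- function(alpha = 0.05) roar_surface(tab_gt(), alpha = alpha)
surf_lt <- function(alpha = 0.05) roar_surface(tab_lt(), alpha = alpha)
surf_meta <- function(alpha = 0.05) roar_surface(tab_meta(), alpha = alpha)

# chi-squared of the restored table via the independent base-R implementation
restored_chisq_oracle <- function(table, direction, x, y) {
  if (direction == "rr_gt_1") {
    m <- matrix(c(table$a, table$c + y, table$b + x, table$d), 2L, 2L)
  } else {
    m <- matrix(c(table$a + x, table$c, table$b, table$d + y), 2L, 2L)
  }
  unname(suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic))
}

# swap experimental and control arms
swap_arms <- function(t) dichotomous_table(t$c, t$d, t$a, t$b)

# deterministic batch of significant fixture tables
fixture_tables <- function(n = 30L, seed = 421L) {
  simulate_significant_tables(n, n_range = c(40L, 400L), seed = seed)
}
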