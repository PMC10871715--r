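test_that("one stratum: crude and CMH risk ratios both equal the study RR", {
  one <- tibble::tibble(a = 70, b = 30, c = 50, d = 50)
  expect_equal(pooled_crude_rr(one), 1.4)
  expect_equal(cmh_rr(one), 1.4)
  expect_equal(cmh_rr(one), pooled_crude_rr(one))
})

test_that("identical strata pool to the common RR with zero confounding", {
  for (k in c(2L, 5L)) {
    same <- tibble::tibble(a = rep(70, k), b = rep(30, k),
                           c = rep(50, k), d = rep(50, k))
    expect_equal(pooled_crude_rr(same), 1.4)
    expect_equal(cmh_rr(same), 1.4)
    pool <- roar_pool(same)
    expect_equal(pool$confounding, 0)
    expect_true(pool$roar_applicable)
  }
})

test_that("the pooled meta-analysis table reproduces the crude risk ratio", {
  # five studies whose cells sum to the published pooled table
  five <- tibble::tibble(
    study = paste0("rct", 1:5),
    a = c(80, 80, 80, 80, 77),
    b = c(3800, 3800, 3800, 3800, 4004),
    c = c(90, 90, 90, 90, 108),
    d = c(3800, 3800, 3800, 3800, 3928)
  )
  expect_equal(colSums(five[, c("a", "b", "c", "d")]),
               c(a = 397, b = 19204, c = 468, d = 19128))
  expect_equal(round(pooled_crude_rr(five), 4), 0.8481)
  pool <- roar_pool(five)
  expect_equal(
    unlist(pool$pooled[c("a", "b", "c", "d")]),
    c(a = 397, b = 19204, c = 468, d = 19128)
  )
  expect_equal(pool$confounding, abs(1 - pool$rr_cmh / pool$rr_crude))
})

test_that("heterogeneous strata move the CMH ratio off the crude ratio", {
  # unbalanced stratum sizes with differing control risks: Simpson-style
  # confounding, so the adjusted ratio leaves the crude one
  pair <- tibble::tibble(a = c(20, 30), b = c(80, 10),
                         c = c(10, 30), d = c(90, 30))
  expect_false(isTRUE(all.equal(cmh_rr(pair), pooled_crude_rr(pair))))
  strict <- roar_pool(pair, threshold = 0)
  expect_false(strict$roar_applicable)
  expect_null(strict$fit)
  expect_match(strict$warnings, "not applicable", all = FALSE)
})

test_that("pooling is order-invariant and sums cells exactly", {
  set.seed(5)
  tabs <- fixture_tables(6L, seed = 77L)
  pool1 <- roar_pool(tabs)
  pool2 <- roar_pool(tabs[sample(nrow(tabs)), ])
  expect_equal(pool1$rr_crude, pool2$rr_crude)
  expect_equal(pool1$rr_cmh, pool2$rr_cmh)
  expect_identical(unlist(pool1$pooled[c("a", "b", "c", "d")]),
                   unlist(pool2$pooled[c("a", "b", "c", "d")]))
  expect_identical(pool1$pooled$a, sum(tabs$a))
})

test_that("gate-asserted pre-pooled input runs the analysis regardless", {
  pooled <- tibble::tibble(study = "pooled",
                           a = 397, b = 19204, c = 468, d = 19128)
  pool <- roar_pool(pooled, gate_asserted = TRUE)
  expect_true(pool$gate_asserted)
  expect_s3_class(pool$fit, "roar_fit")
  expect_identical(pool$fit$rmin, 14L)
})

test_that("zero-cell studies are accepted with a warning when pooled margins hold", {
  withzero <- tibble::tibble(a = c(0, 30), b = c(20, 20),
                             c = c(10, 10), d = c(10, 30))
  pool <- roar_pool(withzero)
  expect_match(pool$warnings, "zero cells", all = FALSE)
  expect_equal(pool$pooled$a, 30)
})

test_that("study labels must be unique and nonempty", {
  dup <- tibble::tibble(study = c("s", "s"), a = c(5, 5), b = c(5, 5),
                        c = c(5, 5), d = c(5, 5))
  expect_error(roar_pool(dup), "unique")
})

test_that("study CSV round-trips through read_studies with strict schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  tabs <- tibble::tibble(study = c("x", "y"), a = c(70, 50), b = c(30, 50),
                         c = c(50, 70), d = c(50, 30))
  utils::write.csv(tabs, path, row.names = FALSE, quote = FALSE)
  back <- read_studies(path)
  expect_equal(as.data.frame(back), as.data.frame(tabs))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study,a,b,c", "x,1,2,3"), bad)
  expect_error(read_studies(bad), "header")

  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study,a,b,c,d", "x,1,2,-3,4"), bad2)
  expect_error(read_studies(bad2), "row 1")
})

test_that("tidy and glance summarise a pooled analysis", {
  studies <- tibble::tibble(study = c("s1", "s2"),
                            a = c(70, 35), b = c(30, 15),
                            c = c(50, 25), d = c(50, 25))
  pool <- roar_pool(studies)
  td <- tidy(pool)
  expect_equal(td$rr, rep(1.4, 2))
  gl <- glance(pool)
  expect_equal(gl$n_studies, 2L)
  expect_equal(gl$rr_crude, 1.4)
  expect_true(gl$roar_applicable)
  expect_true("rmin" %in% names(gl))
})
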