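# Published reference values for the 12-run CHO screen (range table and
# contrast ANOVA), at the precision of the printed report. The printed T
# rows were derived from level means rounded to 3 decimals (T = 2 *
# round(t, 3)); t and R rows round directly.
ref_range <- list(
  t1 = c(0.256, 0.230, 0.250, 0.276, 0.277, 0.242, 0.246),
  t2 = c(0.216, 0.243, 0.223, 0.196, 0.196, 0.231, 0.226),
  T1 = c(0.512, 0.46, 0.5, 0.552, 0.554, 0.484, 0.492),
  T2 = c(0.432, 0.486, 0.446, 0.392, 0.392, 0.462, 0.452),
  R  = c(0.04, 0.013, 0.027, 0.08, 0.081, 0.011, 0.02)
)
ref_anova <- list(
  SS = c(0.0048, 0.0005, 0.0022, 0.0192, 0.0198, 0.0004, 0.0012),
  F  = c(6.86, 0.72, 3.12, 27.42, 28.34, 0.55, 1.66),
  p  = c(0.0589, 0.4427, 0.1519, 0.0064, 0.0060, 0.4994, 0.2674)
)

test_that("range analysis reproduces the published level means and ranges", {
  scr <- fixture_screen()
  rt <- range_analysis(scr$design, scr$response)
  expect_equal(round_half_up(rt$t1, 3), ref_range$t1)
  expect_equal(round_half_up(rt$t2, 3), ref_range$t2)
  expect_equal(2 * round_half_up(rt$t1, 3), ref_range$T1)
  expect_equal(2 * round_half_up(rt$t2, 3), ref_range$T2)
  expect_equal(round_half_up(rt$R, 3), ref_range$R)
  # ferric citrate and BSA dominate the screen
  expect_identical(rt$factor[order(rt$rank)][1:2], c("X5", "X4"))
})

test_that("range analysis is permutation invariant and handles edge cases", {
  scr <- fixture_screen()
  perm <- sample(12)
  d2 <- screen_design(scr$design$coded[perm, ])
  rt1 <- range_analysis(scr$design, scr$response)
  rt2 <- range_analysis(d2, scr$response[perm])
  expect_equal(rt2$R, rt1$R)

  # constant response: every range collapses to zero
  rt0 <- range_analysis(scr$design, rep(0.2, 12))
  expect_equal(rt0$R, rep(0, 7))
  expect_equal(rt0$t1, rep(0.2, 7))

  # response equal to one coded column: orthogonality forces R = 2 e_j
  y <- scr$design$coded[, 3]
  rtj <- range_analysis(scr$design, y + 2)  # shift to keep growth rates >= 0
  expect_equal(rtj$R, c(0, 0, 2, 0, 0, 0, 0))

  # a factor held at one level has no contrast
  one_level <- screen_design(cbind(scr$design$coded[, 1:2],
                                   X9 = rep(1L, 12)), validate = FALSE)
  expect_error(range_analysis(one_level, scr$response), "single level")
})

test_that("contrast ANOVA reproduces the published decomposition", {
  scr <- fixture_screen()
  av <- pb_anova(scr$design, scr$response)
  fac <- av[1:7, ]
  expect_equal(round(fac$SS, 4), ref_anova$SS)
  expect_equal(round(fac$F, 2), ref_anova$F, tolerance = 0.02)
  expect_equal(fac$p, ref_anova$p, tolerance = 5e-4)
  expect_identical(av$df, c(rep(1L, 7), 4L, 11L))
})

test_that("the sum-of-squares decomposition is exact and equivariant", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- random_pb12()
    y <- stats::runif(12, 0.1, 0.4)
    av <- pb_anova(d, y)
    SS <- av$SS
    expect_equal(sum(SS[1:7]) + SS[8], SS[9], tolerance = 1e-10)
    expect_true(all(SS >= 0))

    # location invariance
    av2 <- pb_anova(d, y + 5)
    expect_equal(av2$SS[1:8], av$SS[1:8], tolerance = 1e-9)
    expect_equal(av2$F, av$F, tolerance = 1e-9)
    rt <- range_analysis(d, y); rt2 <- range_analysis(d, y + 5)
    expect_equal(rt2$R, rt$R)

    # scale equivariance: SS ~ k^2, F and p unchanged, R ~ |k|
    k <- 3.5
    av3 <- pb_anova(d, k * y)
    expect_equal(av3$SS, k^2 * av$SS, tolerance = 1e-9)
    expect_equal(av3$F, av$F, tolerance = 1e-9)
    expect_equal(av3$p, av$p, tolerance = 1e-9)
    expect_equal(range_analysis(d, k * y)$R, k * rt$R)
  }
})

test_that("factor sums of squares agree with a least-squares oracle", {
  # on an orthogonal design, SS_j equals the regression SS of y on column
  # j alone
  for (seed in 1:3) {
    set.seed(seed)
    d <- random_pb12()
    y <- stats::rnorm(12, 0.25, 0.05)
    av <- pb_anova(d, y)
    for (j in c(1, 4, 7)) {
      fit <- stats::lm(y ~ d$coded[, j])
      ss_reg <- sum((stats::fitted(fit) - mean(y))^2)
      expect_equal(av$SS[j], ss_reg, tolerance = 1e-10)
    }
  }
})

test_that("degenerate ANOVA inputs are reported, not mangled", {
  scr <- fixture_screen()
  expect_warning(av <- pb_anova(scr$design, rep(0.2, 12)), "undefined")
  expect_true(all(av$SS == 0))
  expect_true(all(is.nan(av$F[1:7])))

  # saturated design: no df left for error
  d11 <- pb_design(12, 11)
  expect_error(pb_anova(d11, scr$response), "saturated")
})

test_that("significance calls follow the F tests", {
  scr <- fixture_screen()
  av <- pb_anova(scr$design, scr$response)
  expect_identical(significant_factors(av, 0.05), c("X5", "X4"))
  expect_identical(significant_factors(av, 0.10), c("X5", "X4", "X1"))
  expect_identical(significant_factors(av, 0), character(0))
})
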