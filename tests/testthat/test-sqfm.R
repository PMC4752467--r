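test_that("qualitative similarity is the cosine of the area vectors", {
  expect_equal(qualitative_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(qualitative_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(qualitative_similarity(c(1, 2, 3), c(3, 2, 1)), 10 / 14)
  expect_error(qualitative_similarity(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(qualitative_similarity(c(0, 0), c(1, 2)), "zero-norm")
})

test_that("ratio similarity weights every peak equally", {
  set.seed(21)
  for (i in 1:5) {
    y <- rlnorm(6)
    expect_equal(ratio_similarity(0.5 * y, y), 1)
  }
  # hand-computed: r = (1/3, 1, 3), sum r / (sqrt(3) sqrt(sum r^2))
  r <- c(1 / 3, 1, 3)
  expect_equal(ratio_similarity(c(1, 2, 3), c(3, 2, 1)),
               sum(r) / (sqrt(3) * sqrt(sum(r^2))))
  expect_equal(ratio_similarity(c(1, 1), c(1, 4)),
               1.25 / (sqrt(2) * sqrt(1.0625)))

  expect_error(ratio_similarity(c(1, 2), c(0, 1)), "zero entries")
  expect_warning(
    s <- ratio_similarity(c(1, 2, 3), c(0, 1, 3), zero_policy = "drop"),
    "dropping")
  expect_equal(s, ratio_similarity(c(2, 3), c(1, 3)))
})

test_that("sqfm_evaluate satisfies identity and scale laws", {
  set.seed(7)
  y <- rlnorm(8, log(50), 0.6)
  r <- sqfm_evaluate(y, y)
  expect_equal(r$s_m, 1)
  expect_equal(r$p_m, 100)
  expect_equal(r$alpha, 0)

  for (k in c(0.8, 1.5, 2)) {
    rk <- sqfm_evaluate(k * y, y)
    expect_equal(rk$s_m, 1)
    expect_equal(rk$p_m, 100 * k)
    expect_equal(rk$alpha, 0, tolerance = 1e-12)
  }
})

test_that("sqfm_evaluate matches hand arithmetic on x=(4,1), y=(2,2)", {
  r <- sqfm_evaluate(c(4, 1), c(2, 2))
  s_f <- 10 / (sqrt(17) * sqrt(8))
  expect_equal(r$s_f, s_f)
  expect_equal(r$c, 10 / 8 * 100)                  # projection content
  expect_equal(r$p, 5 / 4 * s_f * 100)             # content corrected by S_F
  expect_equal(r$p_m, (125 + 125 * s_f) / 2)
  expect_equal(r$alpha, abs(1 - s_f))
})

test_that("all five quantities agree with the literal-formula oracle", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    x <- rlnorm(n, log(20), 0.8)
    y <- rlnorm(n, log(20), 0.8)
    got <- sqfm_evaluate(x, y)
    exp <- sqfm_oracle(x, y)
    for (f in names(exp)) {
      expect_equal(got[[f]], exp[[f]], tolerance = 1e-12, label = f)
    }
  }
})

test_that("grade assignment reproduces the worked examples", {
  expect_identical(assign_grade(0.96, 95.6, 0.02), 1L)
  expect_identical(assign_grade(0.89, 89.5, 0.07), 3L)
  expect_identical(assign_grade(0.87, 104.6, 0.25), 5L)
})

test_that("grade bands take the worst component and resolve ties upward", {
  # band-edge values belong to the better grade
  expect_identical(assign_grade(0.95, 105, 0.05), 1L)
  expect_identical(assign_grade(0.90, 90, 0.10), 2L)
  # grade 8 is the catch-all
  expect_identical(assign_grade(0.30, 200, 2), 8L)
  # worst of the three components wins
  expect_identical(assign_grade(0.99, 100, 0.22), 5L)
  expect_identical(assign_grade(0.99, 58, 0.01), 7L)
  expect_error(assign_grade(NA, 100, 0), "finite")
})

test_that("grade tables validate band monotonicity on load", {
  tab <- default_grade_table()
  expect_s3_class(tab, "grade_table")
  expect_equal(nrow(tab), 8)

  bad <- tab
  bad$min_sm[2] <- 0.96  # not decreasing
  f <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_grade_table(f), "strictly decreasing")
})

test_that("channel integration is the quadratic mean and grades the result", {
  t3 <- ishi_sqfm_table()
  s1 <- t3[t3$batch_id == "S1" & t3$wavelength != "integrated", ]
  r <- integrate_channels(s1)
  expect_equal(round_half_up(r$s_m_prime, 2), 0.94)
  expect_equal(round_half_up(r$p_m_prime, 1), 91.8)
  expect_equal(round_half_up(r$alpha_prime, 2), 0.06)
  expect_equal(r$channel_count, 5L)

  s22 <- t3[t3$batch_id == "S22" & t3$wavelength != "integrated", ]
  expect_equal(round_half_up(integrate_channels(s22)$p_m_prime, 1), 114.6)

  # single channel: integration is the identity
  one <- s1[1, ]
  r1 <- integrate_channels(one)
  expect_equal(r1$s_m_prime, one$s_m)
  expect_equal(r1$p_m_prime, one$p_m)
  expect_equal(r1$alpha_prime, one$alpha)

  expect_error(integrate_channels(t3[t3$wavelength == "260", ]),
               "mixed batch ids")
})

test_that("integrated values sit between the channel mean and maximum", {
  set.seed(9)
  for (i in 1:20) {
    m <- sample(2:6, 1)
    d <- data.frame(batch_id = "B", s_m = runif(m, 0.5, 1),
                    p_m = runif(m, 60, 140), alpha = runif(m, 0, 0.4))
    r <- integrate_channels(d)
    for (pair in list(c(r$s_m_prime, "s_m"), c(r$p_m_prime, "p_m"),
                      c(r$alpha_prime, "alpha"))) {
      v <- d[[pair[2]]]
      expect_gte(as.numeric(pair[1]), mean(v))
      expect_lte(as.numeric(pair[1]), max(v))
    }
  }
})

test_that("report rounding is half-up at table precision", {
  df <- data.frame(s_m = 0.945, p_m = 91.85, alpha = 0.055)
  out <- format_sqfm(df)
  expect_equal(out$s_m, 0.95)
  expect_equal(out$p_m, 91.9)
  expect_equal(out$alpha, 0.06)
})

test_that("matrix-level evaluation grades every batch against the mean", {
  fm <- fingerprint_matrix(260, c("S1", "S2"), c("a", "b", "c"),
                           rbind(c(10, 20, 30), c(30, 20, 10)), 1:3)
  res <- sqfm_evaluate_matrix(fm)
  expect_equal(nrow(res), 2)
  # x1 + x2 = 2y, so the projection similarities must sum to exactly 200
  expect_equal(res$c[1] + res$c[2], 200)
  # reference vs itself would be grade 1
  ref <- build_reference_fingerprint(fm)
  self <- sqfm_evaluate(ref$areas, ref)
  expect_identical(assign_grade(self$s_m, self$p_m, self$alpha), 1L)
})
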