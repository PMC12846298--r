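test_that("Bland-Altman bias and LOA follow the 1.96-SD convention", {
  x <- c(0.2, 0.4, 0.6, 0.8)
  ba <- bland_altman(x, x)
  expect_equal(c(ba$bias, ba$loa_lower, ba$loa_upper), c(0, 0, 0))
  ba2 <- bland_altman(c(1, -1), c(0, 0))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$loa_upper, 1.96 * sqrt(2))
  expect_equal(ba2$loa_lower, -1.96 * sqrt(2))
  expect_error(bland_altman(1, 2), "at least 2")
  # antisymmetry: swapping the systems negates bias and mirrors the limits
  set.seed(51)
  a <- rnorm(20); b <- rnorm(20)
  f <- bland_altman(a, b); g <- bland_altman(b, a)
  expect_equal(g$bias, -f$bias)
  expect_equal(g$loa_lower, -f$loa_upper)
  expect_equal(g$loa_upper, -f$loa_lower)
  expect_equal((f$loa_lower + f$loa_upper) / 2, f$bias)
})

test_that("Pearson correlation matches its moment definition", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(52)
  a <- rnorm(50); b <- rnorm(50)
  oracle <- mean((a - mean(a)) * (b - mean(b))) /
    (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  expect_equal(pearson_r(a, b), oracle, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("ICC(2,1) matches the ANOVA mean-squares route", {
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc_2_1(m), 1)
  set.seed(53)
  for (i in 1:10) {
    m62 <- matrix(rnorm(12, mean = 5), 6, 2)
    expect_equal(icc_2_1(m62), aov_icc21(m62), tolerance = 1e-10)
    m115 <- matrix(rnorm(55, mean = 2, sd = 3), 11, 5)
    expect_equal(icc_2_1(m115), aov_icc21(m115), tolerance = 1e-10)
  }
  expect_error(icc_2_1(matrix(3, 4, 2)), "degenerate")
  expect_error(icc_2_1(matrix(1, 1, 2)), "at least 2")
})

test_that("independent raters drive ICC(2,1) to zero on average", {
  set.seed(54)
  vals <- replicate(300, icc_2_1(matrix(rnorm(22), 11, 2)))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("absolute-agreement ICC penalizes a pure mean shift", {
  set.seed(55)
  a <- rnorm(12)
  shifted <- cbind(a, a + 2)
  expect_equal(pearson_r(shifted[, 1], shifted[, 2]), 1)
  expect_lt(icc_2_1(shifted), 1)
})

test_that("CV averages per-subject relative SDs and is scale invariant", {
  expect_equal(as.numeric(cv_percent(matrix(5, 4, 5))), 0)
  m <- rbind(c(9, 11), c(18, 22))
  expect_equal(as.numeric(cv_percent(m)), 100 * sqrt(2) / 10)
  expect_equal(as.numeric(cv_percent(3 * m)), as.numeric(cv_percent(m)))
  expect_warning(cv_percent(rbind(c(-1, 1), c(9, 11))), "zero mean")
})

test_that("intra-device ICC is ICC(2,1) with repetitions as raters", {
  set.seed(56)
  m <- matrix(rnorm(30, mean = 4), 6, 5)
  expect_equal(intra_device_icc(m), icc_2_1(m))
  perfect <- matrix(rep(c(1, 2, 3, 4, 5, 6), 5), 6, 5)
  expect_equal(intra_device_icc(perfect), 1)
  expect_lt(abs(mean(replicate(200,
    intra_device_icc(matrix(rnorm(20), 4, 5))))), 0.1)
})

make_measures <- function(n = 8, targets = c("PM", "AD"), noise = 0) {
  rows <- list()
  set.seed(57)
  for (tg in targets) for (side in c("left", "right")) {
    base <- runif(n, 0.3, 0.7)
    reps_d <- sapply(1:5, function(k) base + rnorm(n, 0, noise + 1e-3))
    reps_r <- sapply(1:5, function(k) base + rnorm(n, 0, noise + 1e-3))
    for (sys in c("device", "reference")) {
      reps <- if (sys == "device") reps_d else reps_r
      head_val <- if (noise == 0) base else rowMeans(reps)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = rep(1:n, 6),
        side = side, target = tg, system = sys,
        repetition = rep(0:5, each = n),
        value = c(head_val, as.vector(reps)))
    }
  }
  do.call(rbind, rows)
}

test_that("the agreement table mirrors the validation-report schema", {
  meas <- make_measures()
  tab <- build_agreement_table(meas)
  expect_equal(nrow(tab), 4)   # 2 targets x 2 limbs
  expect_named(tab, c("target", "side", "n", "bias", "sd_diff", "loa_lower",
                      "loa_upper", "pearson_r", "icc_between",
                      "icc_intra_device", "icc_intra_reference",
                      "cv_device_pct", "cv_reference_pct"))
  # identical headline pairs: perfect agreement in every cell
  expect_equal(tab$bias, rep(0, 4))
  expect_equal(tab$pearson_r, rep(1, 4))
  expect_equal(tab$icc_between, rep(1, 4))
  # LOA midpoint equals bias for every emitted row
  expect_equal((tab$loa_lower + tab$loa_upper) / 2, tab$bias)
  expect_true(all(tab$loa_lower <= tab$bias & tab$bias <= tab$loa_upper))
  # under-populated targets are skipped with a warning each
  thin <- meas[meas$participant <= 2, ]
  w <- capture_warnings(out <- build_agreement_table(thin))
  expect_null(out)
  expect_length(w, 4)
  expect_true(all(grepl("skipped", w)))
})

test_that("Bland-Altman plot data carries points and reference lines", {
  x <- c(0.2, 0.5, 0.9)
  pd <- bland_altman_plot_data(x, x)
  expect_equal(pd$points$difference, rep(0, 3))
  expect_equal(nrow(pd$points), 3)
  set.seed(58)
  a <- rnorm(15); b <- rnorm(15)
  pd2 <- bland_altman_plot_data(a, b)
  expect_equal(nrow(pd2$points), 15)
  expect_true(pd2$loa_lower <= pd2$bias && pd2$bias <= pd2$loa_upper)
  expect_equal(pd2$points$mean, (a + b) / 2)
})
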