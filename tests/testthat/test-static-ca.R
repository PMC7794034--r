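test_that("CPP binning uses half-open 1 mmHg intervals", {
  b <- make_binned(rep(70.5, 6), rep(0.2, 6))
  c1 <- lassen_curve_subject(b, value = "dcbf")
  expect_equal(nrow(c1), 1)
  expect_equal(c1$bin_left, 70)
  expect_equal(c1$value, 0.2)
  expect_equal(c1$n, 6L)

  b2 <- make_binned(c(60.2, 60.9, 61.1), c(0.1, 0.3, 0.5))
  c2 <- lassen_curve_subject(b2, value = "dcbf")
  expect_equal(c2$bin_left, c(60, 61))
  expect_equal(c2$value, c(0.2, 0.5))

  # a value exactly on the edge belongs to the upper bin
  b3 <- make_binned(c(61.0, 61.0), c(1, 3))
  c3 <- lassen_curve_subject(b3, value = "dcbf")
  expect_equal(c3$bin_left, 61)

  # outlier-masked and invalid bins never reach the curve
  b4 <- make_binned(c(70.5, 70.5, 80.5), c(0.2, 9, 0.3))
  b4$cbf_outlier[2] <- TRUE
  b4$n_valid[3] <- 0L
  c4 <- lassen_curve_subject(b4, value = "dcbf")
  expect_equal(c4$bin_left, 70)
  expect_equal(c4$value, 0.2)
})

test_that("per-subject normalization is mean-subtract mean-divide", {
  b <- make_binned(c(60.5, 70.5), c(2, 2))
  cur <- lassen_curve_subject(b, value = "dcbf")
  expect_equal(normalize_subject_curve(cur)$value, c(0, 0))

  b2 <- make_binned(c(60.5, 70.5), c(1, 3))
  n2 <- normalize_subject_curve(lassen_curve_subject(b2, value = "dcbf"))
  expect_equal(n2$value, c(-0.5, 0.5))

  set.seed(8)
  b3 <- make_binned(runif(40, 40, 120), runif(40, 0.5, 2))
  n3 <- normalize_subject_curve(lassen_curve_subject(b3, value = "dcbf"))
  expect_lt(abs(mean(n3$value)), 1e-12)

  b4 <- make_binned(c(60.5, 70.5), c(-1, 1))
  expect_error(normalize_subject_curve(
    lassen_curve_subject(b4, value = "dcbf")), "zero")
})

test_that("group averaging pools normalized curves bin-wise", {
  mk <- function(cpp, v, id) {
    cur <- lassen_curve_subject(make_binned(cpp, v, subject_id = id),
                                value = "dcbf")
    normalize_subject_curve(cur)
  }
  c1 <- mk(c(60.5, 70.5), c(1, 3), "a")
  g1 <- group_lassen(list(c1), "fentanyl", plateau = FALSE)
  expect_equal(g1$mean_dcbf, c1$value)
  expect_true(all(is.na(g1$sd)))

  g2 <- group_lassen(list(c1, c1), "fentanyl", plateau = FALSE)
  expect_equal(g2$mean_dcbf, c1$value)
  expect_equal(g2$sd, c(0, 0))

  c2 <- mk(c(60.5, 70.5), c(1.2, 2.8), "b")
  g3 <- group_lassen(list(c1, c2), "fentanyl", plateau = FALSE)
  # bin [60,61): subject values -0.5 and -0.4 -> mean -0.45, sd 0.0707
  expect_equal(g3$mean_dcbf[1], mean(c(c1$value[1], c2$value[1])))
  expect_equal(g3$sd[1], sd(c(c1$value[1], c2$value[1])))
  expect_error(group_lassen(list(), "fentanyl"), "empty")
  expect_error(group_lassen(list(lassen_curve_subject(
    make_binned(c(60.5, 70.5), c(1, 3)), value = "dcbf")), "fentanyl"),
    "normalized")
})

test_that("two-subject SD follows the two-point formula", {
  mk <- function(v, id) {
    cur <- lassen_curve_subject(make_binned(c(60.5), v, subject_id = id),
                                value = "dcbf")
    cur$value <- v  # bypass normalization for the arithmetic check
    attr(cur, "normalized") <- TRUE
    cur
  }
  g <- group_lassen(list(mk(0.1, "a"), mk(0.3, "b")), "fentanyl",
                    plateau = FALSE)
  expect_equal(g$mean_dcbf, 0.2)
  expect_equal(g$sd, 0.1414214, tolerance = 1e-6)
})

test_that("plateau fit recovers known breakpoints and flags degeneracy", {
  x <- seq(30.5, 130.5, by = 1)
  truth <- function(cpp) 0.02 * pmin(cpp - 60, 0) + 0.01 * pmax(cpp - 100, 0)
  set.seed(9)
  l <- data.frame(bin_center = x, mean_dcbf = truth(x) + rnorm(length(x), 0, 0.005))
  fit <- estimate_plateau(l)
  expect_lt(abs(fit$lla - 60), 3)
  expect_lt(abs(fit$ula - 100), 3)
  expect_false(fit$degenerate)

  # globally linear: plateau collapses and is flagged
  l2 <- data.frame(bin_center = x, mean_dcbf = 0.01 * x)
  fit2 <- estimate_plateau(l2)
  expect_true(fit2$degenerate)

  # flat everywhere: the whole range is plateau
  l3 <- data.frame(bin_center = x, mean_dcbf = rep(0.3, length(x)))
  fit3 <- estimate_plateau(l3)
  expect_false(fit3$degenerate)
  expect_lt(fit3$lla, quantile(x, 0.1))
  expect_gt(fit3$ula, quantile(x, 0.9))

  expect_error(estimate_plateau(l[1:10, ]), "too few")
})

test_that("rank-sum test is exact for small groups", {
  # identical multisets: perfect symmetry
  expect_equal(distribution_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # the fully separated worked case
  res <- distribution_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.1)
  # label swap leaves p unchanged
  res2 <- distribution_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(res2$p.value, res$p.value)
  # all tied
  expect_equal(distribution_test(rep(2, 4), rep(2, 5))$p.value, 1)
})

test_that("exact branch matches independent enumeration for n <= 10", {
  set.seed(10)
  for (na_ in 2:5) {
    for (nb_ in na_:min(5, 10 - na_)) {
      a <- round(rnorm(na_), 1)
      b <- round(rnorm(nb_, 0.5), 1)
      expect_equal(distribution_test(a, b)$p.value, ranksum_bitmask_p(a, b),
                   tolerance = 1e-12,
                   info = sprintf("na=%d nb=%d", na_, nb_))
    }
  }
  # with deliberate ties
  a <- c(1, 1, 2); b <- c(1, 2, 2, 3)
  expect_equal(distribution_test(a, b)$p.value, ranksum_bitmask_p(a, b))
})

test_that("pooled pressure histograms count every unmasked sample once", {
  s1 <- make_aligned(rep(80.2, 30), icp = rep(10, 30), group = "fentanyl")
  s2 <- make_aligned(rep(60.7, 20), icp = rep(10, 20), group = "isoflurane")
  h <- pressure_histograms(list(s1, s2), "cpp")
  expect_equal(h$bin_left[h$group == "fentanyl"], 70)
  expect_equal(h$count[h$group == "fentanyl"], 30L)
  expect_equal(sum(h$count), 50L)

  set.seed(11)
  s3 <- make_aligned(100 + rnorm(5000, 0, 8))
  h3 <- pressure_histograms(list(s3), "map")
  expect_equal(sum(h3$count), 5000L)

  # approximately uniform counts for uniform samples
  s4 <- make_aligned(runif(1e5, 0, 10))
  h4 <- pressure_histograms(list(s4), "map")
  expect_equal(nrow(h4), 10)
  chi <- sum((h4$count - 1e4)^2 / 1e4)
  expect_lt(chi, qchisq(0.999, df = 9))
})
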