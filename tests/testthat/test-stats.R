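test_that("descriptive statistics match closed forms and brute-force formulas", {
  d <- descriptive_stats(c(1, 2, 3, 4, 5))
  expect_equal(d$mean, 3)
  expect_equal(d$median, 3)
  expect_equal(d$sd, sqrt(2.5))
  expect_equal(d$iqr, 2)
  expect_equal(d$min, 1)
  expect_equal(d$max, 5)

  set.seed(1)
  x <- rlnorm(200, 4, 0.5)
  d <- descriptive_stats(x)
  n <- length(x)
  expect_equal(d$n, n)
  expect_equal(d$mean, sum(x) / n, tolerance = 1e-12)
  expect_equal(d$sd, sqrt(sum((x - mean(x))^2) / (n - 1)), tolerance = 1e-12)
  expect_equal(d$cv, 100 * d$sd / d$mean, tolerance = 1e-12)
  expect_equal(d$ci95_low, mean(x) - qt(0.975, n - 1) * sd(x) / sqrt(n),
               tolerance = 1e-12)
  expect_equal(d$ci95_high, mean(x) + qt(0.975, n - 1) * sd(x) / sqrt(n),
               tolerance = 1e-12)
  expect_equal(d$iqr, unname(quantile(x, 0.75) - quantile(x, 0.25)),
               tolerance = 1e-12)
  expect_true(d$min <= d$median && d$median <= d$max)
  expect_true(d$ci95_low < d$mean && d$mean < d$ci95_high)
  expect_error(descriptive_stats(1), "at least 2")
})

test_that("mode uses 2-decimal rounding and cv flags a zero mean", {
  x <- c(1.011, 1.012, 1.013, 2.5) # all round to 1.01 but one
  expect_equal(descriptive_stats(x)$mode, 1.01)
  expect_warning(d0 <- descriptive_stats(c(-1, 1)), "cv undefined")
  expect_true(is.na(d0$cv))
})

test_that("normality test statistics behave under null and alternative", {
  set.seed(2)
  r <- dagostino_pearson_k2(rnorm(5000))
  expect_gte(r$k2, 0)
  ln <- dagostino_pearson_k2(rlnorm(5000, 0, 1))
  expect_lt(ln$p_value, 0.001)
  expect_error(dagostino_pearson_k2(rnorm(10)), "n >= 20")
  expect_error(dagostino_pearson_k2(rep(1, 30)), "zero variance")
})

test_that("normality test holds its type-I error at alpha = 0.05", {
  set.seed(3)
  reps <- 1000
  n <- 2000
  p <- vapply(seq_len(reps),
              function(i) dagostino_pearson_k2(rnorm(n))$p_value, 0)
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("Kruskal-Wallis is exact on trivial and separated fixtures", {
  d <- tibble::tibble(v = rep(c(1, 2, 3), 3),
                      g = rep(c("a", "b", "c"), each = 3))
  kw <- kruskal_wallis_dunn(d, "v", "g", p_method = "chisq")
  expect_equal(kw$h, 0)
  expect_equal(kw$p_value, 1)

  set.seed(4)
  d2 <- tibble::tibble(
    v = c(rnorm(50), rnorm(50, 20), rnorm(50, 40)),
    g = rep(c("a", "b", "c"), each = 50)
  )
  kw2 <- kruskal_wallis_dunn(d2, "v", "g")
  expect_lt(kw2$p_value, 0.001)
  expect_true(all(tidy(kw2)$p_adjusted < 0.01))
  expect_gte(kw2$h, 0)
  # invariance under monotone transforms
  d3 <- d2
  d3$v <- exp(d3$v / 10)
  expect_equal(kruskal_wallis_dunn(d3, "v", "g")$h, kw2$h, tolerance = 1e-12)

  expect_error(kruskal_wallis_dunn(tibble::tibble(v = rep(1, 9),
                                                  g = rep(c("a", "b", "c"), 3)),
                                   "v", "g"), "identical")
})

test_that("exact permutation p matches an independent enumeration oracle", {
  set.seed(5)
  for (rep in 1:3) {
    x <- sample(1:20, 8)
    g <- rep(c("a", "b", "c"), c(3, 3, 2))
    d <- tibble::tibble(v = x, g = g)
    kw <- kruskal_wallis_dunn(d, "v", "g") # auto -> exact at n = 8
    expect_equal(kw$p_method, "exact")
    # oracle: enumerate every assignment of the 8 values to groups via
    # kruskal.test's H on relabeled data
    combs <- utils::combn(8, 3, simplify = FALSE)
    h_obs <- unname(stats::kruskal.test(x, factor(g))$statistic)
    count <- 0L; total <- 0L
    for (i1 in combs) {
      rest <- setdiff(1:8, i1)
      for (i2 in utils::combn(rest, 3, simplify = FALSE)) {
        gg <- integer(8); gg[i1] <- 1L; gg[i2] <- 2L
        gg[setdiff(rest, i2)] <- 3L
        h <- unname(stats::kruskal.test(x, factor(gg))$statistic)
        total <- total + 1L
        if (h >= h_obs - 1e-12) count <- count + 1L
      }
    }
    expect_equal(kw$p_value, count / total, tolerance = 0.01)
  }
})

test_that("Dunn z statistics follow the midrank formula", {
  set.seed(6)
  d <- tibble::tibble(v = round(rnorm(60), 1),
                      g = rep(c("a", "b", "c"), each = 20))
  kw <- kruskal_wallis_dunn(d, "v", "g", p_adjust_method = "holm")
  r <- rank(d$v)
  n <- 60
  ties <- table(d$v)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  rb <- tapply(r, d$g, mean)
  z_ab <- (rb[["a"]] - rb[["b"]]) /
    sqrt((n * (n + 1) / 12 - tie_term) * (1 / 20 + 1 / 20))
  expect_equal(tidy(kw)$z[1], unname(z_ab), tolerance = 1e-12)
  expect_equal(tidy(kw)$p_adjusted,
               pmin(stats::p.adjust(tidy(kw)$p_value, "holm"), 1))
})

test_that("chi-square on compositions matches the hand-calculated 2x2 oracle", {
  comp <- tibble::tibble(
    region = rep(c("BA9", "BA24"), each = 2),
    cell_type = rep(c("granule", "small_pyramidal"), 2),
    n = c(10, 20, 20, 10)
  )
  res <- chi_square_composition(comp)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(res$df, 1)

  same <- tibble::tibble(
    region = rep(c("BA9", "BA24"), each = 2),
    cell_type = rep(c("granule", "small_pyramidal"), 2),
    n = c(30, 70, 30, 70)
  )
  res2 <- chi_square_composition(same)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1)

  tiny <- tibble::tibble(
    region = rep(c("BA9", "BA24"), each = 2),
    cell_type = rep(c("granule", "small_pyramidal"), 2),
    n = c(1, 50, 0, 60)
  )
  expect_error(chi_square_composition(tiny), "below 1")
})
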