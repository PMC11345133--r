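feat_row <- function(aspect_ratio, area = 150, form_factor = 0.85,
                     solidity = 0.97) {
  tibble::tibble(aspect_ratio = aspect_ratio, area_um2 = area,
                 form_factor = form_factor, solidity = solidity)
}

test_that("the default rule set reproduces the worked decision examples", {
  expect_equal(as.character(classify_cells(feat_row(1.20, 100, 0.88, 0.98))$predicted_rule),
               "granule")
  expect_equal(as.character(classify_cells(feat_row(1.50, 250, 0.85, 0.97))$predicted_rule),
               "medium_pyramidal")
  expect_equal(as.character(classify_cells(feat_row(2.40, 300, 0.85, 0.97))$predicted_rule),
               "large_fusiform")
  expect_equal(as.character(classify_cells(feat_row(1.50, 150, 0.70, 0.90))$predicted_rule),
               "polymorphic")
})

test_that("interval endpoints are lower-inclusive, upper-exclusive", {
  expect_equal(as.character(classify_cells(feat_row(1.38, 100))$predicted_rule),
               "small_pyramidal")
  expect_equal(as.character(classify_cells(feat_row(1.50, 202.2))$predicted_rule),
               "medium_pyramidal")
  expect_equal(as.character(classify_cells(feat_row(1.50, 394.5))$predicted_rule),
               "large_pyramidal")
  expect_equal(as.character(classify_cells(feat_row(1.86, 161.2))$predicted_rule),
               "large_fusiform")
})

test_that("rule regions partition feature space", {
  set.seed(15)
  n <- 20000
  f <- tibble::tibble(
    aspect_ratio = 1 + rexp(n, 1 / 0.6),
    area_um2 = runif(n, 5, 1200),
    form_factor = runif(n, 0.05, 1),
    solidity = runif(n, 0.4, 1)
  )
  cls <- classify_cells(f)$predicted_rule
  expect_false(anyNA(cls))
  # determinism: identical input gives identical output
  expect_identical(cls, classify_cells(f)$predicted_rule)
  # polymorphic-last variant also assigns every cell exactly one class
  cls2 <- classify_cells(f, polymorphic_first = FALSE)$predicted_rule
  expect_false(anyNA(cls2))
})

test_that("ruleset construction validates threshold ordering", {
  expect_error(ruleset(ar_granule_max = 2.0), "below ar_fusiform_min")
  expect_error(ruleset(area_small_medium = 400), "below area_medium_large")
  expect_error(ruleset(ff_polymorphic_max = -1), "positive")
  expect_error(classify_cells(feat_row(0.5)), "out of range")
  expect_error(classify_cells(tibble::tibble(aspect_ratio = 1.2)), "missing feature")
})

test_that("roc_curve matches the exhaustive confusion-matrix oracle", {
  set.seed(2)
  for (rep in 1:5) {
    scores <- round(c(rnorm(40, 0), rnorm(30, 1)), 2) # ties on purpose
    labels <- rep(c(FALSE, TRUE), c(40, 30))
    roc <- roc_curve(scores, labels)
    for (i in seq_len(nrow(roc))) {
      t <- roc$threshold[i]
      expect_equal(roc$sensitivity[i], mean(scores[labels] >= t))
      expect_equal(roc$specificity[i], mean(scores[!labels] < t))
    }
    # reversed direction
    rocr <- roc_curve(scores, labels, direction = "<=")
    for (i in seq_len(nrow(rocr))) {
      t <- rocr$threshold[i]
      expect_equal(rocr$sensitivity[i], mean(scores[labels] <= t))
      expect_equal(rocr$specificity[i], mean(scores[!labels] > t))
    }
  }
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("perfectly separated scores give a perfect operating point at 2.5", {
  roc <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  perfect <- roc[roc$sensitivity == 1 & roc$specificity == 1, ]
  expect_equal(nrow(perfect), 1)
  expect_equal(perfect$threshold, 2.5)
  sel <- select_threshold(roc)
  expect_equal(sel$threshold, 2.5)
  expect_equal(sel$sensitivity, 1)
  expect_equal(sel$specificity, 1)
})

test_that("AUC of random labels is about one half, and agrees with pROC", {
  set.seed(4)
  scores <- rnorm(1000)
  labels <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
  auc <- glance(roc_curve(scores, labels))$auc
  expect_lt(abs(auc - 0.5), 0.05)
  skip_if_not_installed("pROC")
  scores2 <- c(rnorm(300), rnorm(300, 1))
  labels2 <- rep(c(FALSE, TRUE), each = 300)
  auc2 <- glance(roc_curve(scores2, labels2))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels2, scores2, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc2, ref, tolerance = 1e-9)
})

test_that("threshold selection approximates the analytic Gaussian solution", {
  set.seed(6)
  n <- 5000
  scores <- c(rnorm(n, 0), rnorm(n, 2))
  labels <- rep(c(FALSE, TRUE), each = n)
  sel <- select_threshold(roc_curve(scores, labels))
  expect_gte(sel$specificity, 0.90)
  # analytic: at the 90%-specificity threshold t = qnorm(0.9),
  # sensitivity is pnorm(2 - t)
  t_exact <- qnorm(0.9)
  expect_lt(abs(sel$sensitivity - pnorm(2 - t_exact)), 0.02)
  expect_lt(abs(sel$threshold - t_exact), 0.15)
})

test_that("Youden fallback equals the brute-force J maximizer", {
  # discrete scores whose maximum is shared by both classes: no finite
  # threshold reaches the specificity aim
  scores <- c(1, 2, 3, 3, 3, 2, 3, 3)
  labels <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  roc <- roc_curve(scores, labels)
  sel <- select_threshold(roc, min_specificity = 0.9)
  expect_false(sel$met_specificity_aim)
  j <- roc$sensitivity + roc$specificity - 1
  expect_equal(sel$youden_j, max(j[is.finite(roc$threshold)]))
})

test_that("derive_ruleset recovers the generating boundaries", {
  f <- simulate_feature_table(7 * 1000, seed = 21)
  rs <- derive_ruleset(f)
  ref <- default_ruleset()
  for (nm in names(unclass(ref))) {
    expect_lt(abs(rs[[nm]] - ref[[nm]]) / ref[[nm]], 0.05)
  }
  sel <- attr(rs, "selection")
  expect_true(all(sel$specificity >= 0.90))

  # fixed point: relabeling by the derived rules and re-deriving moves
  # thresholds by at most the data spacing near the boundaries
  f2 <- classify_cells(f, rs)
  f2$label <- f2$predicted_rule
  f2 <- f2[as.character(f2$label) != "gigantic_pyramidal", ]
  rs2 <- derive_ruleset(f2)
  for (nm in names(unclass(ref))) {
    expect_lt(abs(rs2[[nm]] - rs[[nm]]) / rs[[nm]], 0.05)
  }
})

test_that("derive_ruleset errors when a class is missing", {
  f <- simulate_feature_table(600, seed = 3)
  f <- f[f$label != "polymorphic", ]
  expect_error(derive_ruleset(f), "polymorphic")
})

test_that("tidy methods expose thresholds and contrasts", {
  td <- tidy(default_ruleset())
  expect_equal(nrow(td), 7)
  expect_setequal(unique(td$parameter),
                  c("aspect_ratio", "area_um2", "form_factor", "solidity"))
})
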