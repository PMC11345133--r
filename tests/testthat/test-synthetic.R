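test_that("generation is deterministic for a fixed seed", {
  a <- generate_cell("granule", seed = 7)
  b <- generate_cell("granule", seed = 7)
  expect_identical(a$vertices[[1]], b$vertices[[1]])
  c1 <- generate_column(composition_profile("BA9"), 30, seed = 3)
  c2 <- generate_column(composition_profile("BA9"), 30, seed = 3)
  expect_identical(c1$vertices, c2$vertices)
  expect_identical(as.character(c1$label), as.character(c2$label))
  s1 <- simulate_feature_table(50, seed = 5)
  s2 <- simulate_feature_table(50, seed = 5)
  expect_identical(s1, s2)
})

test_that("every generated contour passes the contour invariants", {
  set.seed(20)
  classes <- setdiff(somamorph:::CELL_TYPES, "gigantic_pyramidal")
  for (ct in classes) {
    for (i in 1:5) {
      cell <- generate_cell(ct, seed = i)
      v <- cell$vertices[[1]]
      expect_gte(nrow(v), 3)
      # re-validates simplicity and orientation
      expect_silent(contour_table(list(v), label = ct))
    }
  }
})

test_that("granule aspect-ratio targets round-trip through morphometrics", {
  hits <- 0
  for (i in 1:100) {
    f <- compute_features(generate_cell("granule", seed = i))
    if (f$aspect_ratio >= 1 && f$aspect_ratio < 1.38) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("generated cells fall in their class's rule region", {
  set.seed(500)
  classes <- setdiff(somamorph:::CELL_TYPES, "gigantic_pyramidal")
  cells <- dplyr::bind_rows(lapply(classes, function(ct) {
    dplyr::bind_rows(lapply(1:25, function(i) generate_cell(ct)))
  }))
  f <- classify_cells(compute_features(cells))
  agree <- mean(as.character(f$predicted_rule) == as.character(f$label))
  expect_gte(agree, 0.95)
})

test_that("classical height/width geometry yields a spindle of the right size", {
  # large fusiform at the classical average height 30 x width 15 um
  p <- class_shape_params("large_fusiform")
  p$target_area_range <- NULL
  p$height_range <- c(30, 30)
  p$width_range <- c(15, 15)
  f <- classify_cells(compute_features(generate_cell("large_fusiform",
                                                     params = p, seed = 2)))
  expect_lt(abs(f$area_um2 - pi * 15 * 7.5) / (pi * 15 * 7.5), 0.10)
  expect_gt(f$aspect_ratio, 1.86)
  expect_equal(as.character(f$predicted_rule), "large_fusiform")
})

test_that("single-class layer profile yields only that class", {
  prof <- composition_profile("BA9")
  prob <- matrix(0, 6, length(somamorph:::CELL_TYPES))
  colnames(prob) <- somamorph:::CELL_TYPES
  prob[, "granule"] <- 1
  prof[, somamorph:::CELL_TYPES] <- prob
  col <- generate_column(prof, 50, seed = 1)
  expect_true(all(as.character(col$label) == "granule"))
})

test_that("column composition converges to the profile probabilities", {
  prof <- composition_profile("BA14r")
  n <- 3000
  col <- generate_column(prof, n, seed = 99)
  # layer frequencies within 3 binomial SE of thickness shares
  lt <- table(col$layer)[as.character(prof$layer)]
  for (i in seq_len(nrow(prof))) {
    p <- prof$rel_thickness[i]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(lt[[i]] / n - p), 3.5 * se + 1e-9)
  }
  # per-layer class frequencies within binomial error of the profile
  pm <- as.matrix(prof[, somamorph:::CELL_TYPES])
  for (i in seq_len(nrow(prof))) {
    lay <- as.character(prof$layer[i])
    sub <- col[as.character(col$layer) == lay, ]
    nl <- nrow(sub)
    if (nl < 30) next
    freq <- table(factor(as.character(sub$label),
                         levels = somamorph:::CELL_TYPES)) / nl
    for (j in seq_along(somamorph:::CELL_TYPES)) {
      p <- pm[i, j]
      se <- sqrt(p * (1 - p) / nl)
      expect_lt(abs(freq[[j]] - p), 3.5 * se + 2 / nl)
    }
  }
})

test_that("different seeds give different geometry but compatible composition", {
  prof <- composition_profile("BA9")
  a <- generate_column(prof, 400, seed = 1)
  b <- generate_column(prof, 400, seed = 2)
  expect_false(identical(a$vertices[[1]], b$vertices[[1]]))
  tab <- rbind(table(factor(as.character(a$label), levels = somamorph:::CELL_TYPES)),
               table(factor(as.character(b$label), levels = somamorph:::CELL_TYPES)))
  tab <- tab[, colSums(tab) > 0]
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.001)
})

test_that("simulated feature tables satisfy the descriptor invariants", {
  f <- simulate_feature_table(700, seed = 31)
  expect_true(all(f$aspect_ratio >= 1))
  expect_true(all(f$form_factor > 0 & f$form_factor <= 1))
  expect_true(all(f$solidity > 0 & f$solidity <= 1))
  expect_true(all(f$convexity > 0 & f$convexity <= 1))
  expect_true(all(f$feret_max_um >= f$feret_min_um))
  expect_equal(f$roundness, f$compactness^2, tolerance = 1e-12)
  expect_equal(f$form_factor, 4 * pi * f$area_um2 / f$perimeter_um^2,
               tolerance = 1e-9)
  expect_error(simulate_feature_table(0), "positive")
})

test_that("simulated features are recovered by the rule classifier and match class medians", {
  f <- simulate_feature_table(3500, seed = 8)
  cls <- classify_cells(f)
  expect_gte(mean(as.character(cls$predicted_rule) == as.character(cls$label)), 0.95)
  gran <- f[f$label == "granule", ]
  expect_lt(median(gran$area_um2), 202.2)
  expect_lt(median(gran$aspect_ratio), 1.38)
})

test_that("infeasible generator parameters error", {
  p <- class_shape_params("granule")
  p$target_aspect_ratio_range <- c(0.5, 0.9)
  expect_error(generate_cell("granule", params = p, seed = 1), "aspect ratio")
  expect_error(generate_cell("astrocyte"), "arg")
})
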