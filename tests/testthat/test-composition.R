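pred_table <- function(types, region = "BA9", layer = "III",
                       excluded = FALSE) {
  tibble::tibble(
    region = factor(region, levels = somamorph:::REGIONS),
    layer = factor(layer, levels = somamorph:::LAYERS),
    predicted_nn = factor(types, levels = somamorph:::CELL_TYPES),
    excluded = excluded
  )
}

test_that("a single-class stratum gives ternary corner (1, 0, 0)", {
  comp <- build_composition(pred_table(rep("granule", 10)))
  tc <- ternary_coords(comp)
  expect_equal(tc$granule, 1)
  expect_equal(tc$pyramidal, 0)
  expect_equal(tc$fusiform, 0)
  expect_equal(tc$tx, 0)
  expect_equal(tc$ty, 0)
})

test_that("proportions sum to one per stratum and counts are conserved", {
  set.seed(1)
  types <- sample(setdiff(somamorph:::CELL_TYPES, "gigantic_pyramidal"),
                  300, replace = TRUE)
  excl <- runif(300) < 0.1
  rec <- pred_table(types, region = sample(c("BA9", "BA24"), 300, TRUE),
                    layer = sample(c("II", "V"), 300, TRUE),
                    excluded = excl)
  rec$predicted_nn[rec$excluded] <- NA
  comp <- build_composition(rec)
  sums <- comp |>
    dplyr::group_by(region, layer) |>
    dplyr::summarise(p = sum(proportion), n = sum(n),
                     n_total = dplyr::first(n_total),
                     n_excluded = dplyr::first(n_excluded),
                     .groups = "drop")
  expect_true(all(abs(sums$p - 1) < 1e-9))
  expect_equal(sum(sums$n) + sum(sums$n_excluded), 300)
})

test_that("super-class ternary proportions renormalize when polymorphic cells drop out", {
  types <- c(rep("granule", 4), rep("medium_pyramidal", 3),
             rep("small_fusiform", 2), rep("polymorphic", 6))
  tc <- ternary_coords(build_composition(pred_table(types)))
  expect_equal(tc$granule + tc$pyramidal + tc$fusiform, 1)
  expect_equal(tc$granule, 4 / 9)
  expect_equal(tc$fusiform, 2 / 9)
})

test_that("radar coordinates cover the seven observed classes", {
  types <- rep(setdiff(somamorph:::CELL_TYPES, "gigantic_pyramidal"), 2)
  rc <- radar_coords(build_composition(pred_table(types)))
  expect_equal(nrow(rc), 7)
  expect_equal(sort(unique(rc$angle)), 2 * pi * (0:6) / 7)
})

test_that("column composition is recovered within binomial error", {
  prof <- composition_profile("BA24")
  col <- generate_column(prof, 4000, seed = 12)
  feats <- classify_cells(compute_features(col))
  comp <- build_composition(feats, by = c("region", "layer"),
                            prediction = "predicted_rule")
  pm <- as.matrix(prof[, somamorph:::CELL_TYPES])
  rownames(pm) <- as.character(prof$layer)
  for (i in seq_len(nrow(comp))) {
    lay <- as.character(comp$layer[i])
    p <- pm[lay, as.character(comp$cell_type[i])]
    nl <- comp$n_total[i] - comp$n_excluded[i]
    if (nl < 50) next
    se <- sqrt(p * (1 - p) / nl)
    expect_lt(abs(comp$proportion[i] - p), 3.5 * se + 2 / nl)
  }
})

test_that("compositions from distinct profiles are distinguished, identical ones are not", {
  a <- generate_column(composition_profile("BA9"), 1500, seed = 5)
  b <- generate_column(composition_profile("BA24"), 1500, seed = 6)
  feats <- classify_cells(compute_features(dplyr::bind_rows(a, b)))
  comp <- build_composition(feats, by = "region", prediction = "predicted_rule")
  res <- chi_square_composition(comp, "region")
  expect_lt(res$p_value, 0.001)

  # identical counts: X2 exactly 0
  dup <- dplyr::bind_rows(
    pred_table(rep(c("granule", "medium_pyramidal"), c(30, 20)), region = "BA9"),
    pred_table(rep(c("granule", "medium_pyramidal"), c(30, 20)), region = "BA24")
  )
  res0 <- chi_square_composition(build_composition(dup, by = "region"))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
})

test_that("strata with all cells excluded are flagged empty", {
  rec <- pred_table(rep("granule", 5), excluded = TRUE)
  rec$predicted_nn <- factor(NA, levels = somamorph:::CELL_TYPES)
  comp <- build_composition(rec)
  expect_true(all(comp$empty))
  expect_true(all(is.na(comp$proportion)))
})

test_that("t-SNE is deterministic, guards perplexity, and separates clusters", {
  set.seed(30)
  n_per <- 100
  mk <- function(cx, cy) tibble::tibble(
    cluster = paste0(cx, cy),
    area_um2 = rnorm(n_per, cx, 0.05), aspect_ratio = rnorm(n_per, cy, 0.05),
    form_factor = rnorm(n_per, cx - cy, 0.05), solidity = rnorm(n_per, cx + cy, 0.05)
  )
  df <- dplyr::bind_rows(mk(0, 0), mk(10, 0), mk(0, 10))
  emb1 <- tsne_embed(df, perplexity = 20, n_iter = 300, seed = 3)
  emb2 <- tsne_embed(df, perplexity = 20, n_iter = 300, seed = 3)
  expect_identical(emb1$tsne1, emb2$tsne1)

  y <- cbind(emb1$tsne1, emb1$tsne2)
  d <- as.matrix(dist(y))
  diag(d) <- Inf
  purity <- mean(vapply(seq_len(nrow(y)), function(i) {
    nb <- order(d[i, ])[1:10]
    mean(df$cluster[nb] == df$cluster[i]) > 0.5
  }, TRUE))
  expect_gte(purity, 0.90)

  expect_error(tsne_embed(df[1:10, ], perplexity = 30), "perplexity too large")
})
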