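#' Descriptive statistics of one descriptor
#'
#' The summary set used for per-region descriptor tables: n, mean,
#' sample SD, 95% confidence interval for the mean (t quantiles),
#' coefficient of variation (100 * SD / mean, %), median, IQR
#' (type-7 quantiles), mode (most frequent value after rounding to
#' 2 decimals; smallest such value on ties), minimum and maximum.
#'
#' @param values Numeric vector, n >= 2, finite.
#' @return One-row tibble with columns `n`, `mean`, `sd`, `ci95_low`,
#'   `ci95_high`, `cv`, `median`, `iqr`, `mode`, `min`, `max`. `cv` is
#'   `NA` (with a warning) when the mean is 0.
#' @export
#' @examples
#' descriptive_stats(c(1, 2, 3, 4, 5))
descriptive_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) abort("need at least 2 values")
  if (any(!is.finite(values))) abort("values must be finite")
  n <- length(values)
  m <- mean(values)
  s <- sd(values)
  se <- s / sqrt(n)
  tq <- qt(0.975, n - 1)
  cv <- if (m == 0) {
    warn("cv undefined: mean is zero")
    NA_real_
  } else {
    100 * s / m
  }
  r2 <- round(values, 2)
  tab <- table(r2)
  mode_val <- as.numeric(names(tab)[which.max(tab)])
  tibble(
    n = n, mean = m, sd = s,
    ci95_low = m - tq * se, ci95_high = m + tq * se,
    cv = cv,
    median = median(values),
    iqr = unname(diff(quantile(values, c(0.25, 0.75), type = 7))),
    mode = mode_val,
    min = min(values), max = max(values)
  )
}

#' Descriptor summary table by stratum
#'
#' [descriptive_stats()] applied to each descriptor within each group,
#' producing a long summary table in the style of a per-region
#' descriptive statistics table.
#'
#' @param features Feature table.
#' @param ... Grouping columns (tidy-select style), e.g. `region` or
#'   `region, layer`.
#' @param columns Descriptor columns to summarise.
#' @return Tibble with grouping columns, `parameter`, and the summary
#'   columns.
#' @export
describe_features <- function(features, ...,
                              columns = intersect(FEATURE_COLS, names(features))) {
  stopifnot(is.data.frame(features))
  features |>
    dplyr::select(dplyr::all_of(columns), ...) |>
    tidyr::pivot_longer(dplyr::all_of(columns),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(..., .data$parameter) |>
    dplyr::reframe(descriptive_stats(.data$value)) |>
    as_tibble()
}

#' D'Agostino-Pearson omnibus normality test
#'
#' K2 = Z1(skewness)^2 + Z2(kurtosis)^2 with the standard normalizing
#' transformations (D'Agostino's skewness transformation and the
#' Anscombe-Glynn kurtosis transformation); under normality K2 is
#' approximately chi-square with 2 degrees of freedom.
#'
#' @param values Numeric vector, n >= 20.
#' @return One-row tibble: `k2`, `p_value`, `z_skewness`, `z_kurtosis`,
#'   `skewness`, `kurtosis` (non-excess), `n`.
#' @export
dagostino_pearson_k2 <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 20) abort("D'Agostino-Pearson test needs n >= 20")
  if (any(!is.finite(values))) abort("values must be finite")
  if (diff(range(values)) == 0) abort("zero variance: test undefined")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # skewness: D'Agostino (1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)

  # kurtosis: Anscombe & Glynn (1983)
  eg2 <- 3 * (n - 1) / (n + 1)
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eg2) / sqrt(vg2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  tibble(
    k2 = k2,
    p_value = pchisq(k2, df = 2, lower.tail = FALSE),
    z_skewness = z1, z_kurtosis = z2,
    skewness = g1, kurtosis = g2, n = n
  )
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across groups, then Dunn's pairwise z
#' statistics on the pooled midranks with multiplicity adjustment
#' (Bonferroni by default). For very small samples the global p-value
#' can be computed from the exhaustive permutation distribution of H
#' instead of the chi-square approximation (`p_method = "exact"`, the
#' default `"auto"` switches to it when total n <= 10).
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping variable.
#' @param p_adjust_method Method for Dunn's pairwise p-values (any
#'   [stats::p.adjust()] method; default `"bonferroni"`).
#' @param p_method `"auto"`, `"chisq"` or `"exact"`.
#' @return A `soma_kw` object; `glance()` gives H, df and the global
#'   p-value, `tidy()` the pairwise Dunn comparisons.
#' @export
kruskal_wallis_dunn <- function(data, value, group,
                                p_adjust_method = "bonferroni",
                                p_method = c("auto", "chisq", "exact")) {
  p_method <- match.arg(p_method)
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  x <- as.numeric(data[[value]])
  g <- factor(data[[group]])
  g <- droplevels(g)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  n <- length(x)
  if (n < 5) abort("need total n >= 5")
  if (diff(range(x)) == 0) abort("H undefined: all values identical")

  kw <- kruskal.test(x, g)
  h <- unname(kw$statistic)
  df <- unname(kw$parameter)
  p_global <- unname(kw$p.value)
  used <- "chisq"
  if (p_method == "exact" || (p_method == "auto" && n <= 10)) {
    p_global <- kw_exact_p(x, g)
    used <- "exact"
  }

  # Dunn's z on pooled midranks with tie correction
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    (rbar[[i]] - rbar[[j]]) /
      sqrt((n * (n + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
  })
  p_raw <- 2 * pnorm(-abs(z))
  dunn <- tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = as.numeric(z),
    p_value = p_raw,
    p_adjusted = pmin(p.adjust(p_raw, method = p_adjust_method), 1)
  )
  structure(
    list(h = h, df = df, p_value = p_global, p_method = used,
         dunn = dunn, n = n, groups = lev,
         p_adjust_method = p_adjust_method),
    class = "soma_kw"
  )
}

# Exact permutation p-value of the (tie-corrected) H statistic by
# enumeration of all distinct assignments of observations to groups.
kw_exact_p <- function(x, g) {
  n <- length(x)
  ns <- as.integer(table(g))
  h_of <- function(idx_list) {
    r <- rank(x)
    ties <- table(x)
    c_tie <- 1 - sum(ties^3 - ties) / (n^3 - n)
    hh <- 12 / (n * (n + 1)) *
      sum(vapply(idx_list, function(ii) sum(r[ii])^2 / length(ii), 0)) -
      3 * (n + 1)
    hh / c_tie
  }
  obs_idx <- split(seq_len(n), g)
  h_obs <- h_of(obs_idx)
  # enumerate multiset partitions of 1..n into groups of sizes ns
  count_ge <- 0L
  total <- 0L
  rec <- function(remaining, k, acc) {
    if (k == length(ns)) {
      hh <- h_of(c(acc, list(remaining)))
      total <<- total + 1L
      if (hh >= h_obs - 1e-12) count_ge <<- count_ge + 1L
      return(invisible())
    }
    cmb <- utils::combn(remaining, ns[k], simplify = FALSE)
    for (sel in cmb) rec(setdiff(remaining, sel), k + 1L, c(acc, list(sel)))
  }
  rec(seq_len(n), 1L, list())
  count_ge / total
}

#' @export
print.soma_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (%s)\n",
              x$h, x$df, x$p_value, x$p_method))
  cat("Dunn post hoc (", x$p_adjust_method, "-adjusted):\n", sep = "")
  print(x$dunn)
  invisible(x)
}

#' @export
tidy.soma_kw <- function(x, ...) x$dunn

#' @export
glance.soma_kw <- function(x, ...) {
  tibble(h = x$h, df = x$df, p_value = x$p_value,
         p_method = x$p_method, n = x$n)
}

#' Chi-square test on a composition table
#'
#' Pearson chi-square (no continuity correction) on the
#' stratum x cell-type count table of a composition, testing whether the
#' morphological composition differs between strata (regions by
#' default). Warns when any expected count is below 5 and errors below 1.
#'
#' @param composition A `soma_composition` (see [build_composition()]) or
#'   a data frame with `cell_type`, `n` and the grouping column.
#' @param grouping Column defining the strata (default `"region"`).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_composition <- function(composition, grouping = "region") {
  stopifnot(is.data.frame(composition),
            all(c(grouping, "cell_type", "n") %in% names(composition)))
  wide <- composition |>
    dplyr::group_by(.data[[grouping]], .data$cell_type) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "n",
                       values_fill = 0)
  m <- as.matrix(wide[, -1])
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) abort("need at least 2 groups and 2 cell types with counts")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 1)) abort("expected count below 1; chi-square invalid")
  if (any(expected < 5)) warn("expected count below 5; chi-square approximate")
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(statistic = unname(res$statistic),
         df = unname(res$parameter),
         p_value = unname(res$p.value))
}
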