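#' Spearman rank-correlation matrix of morphometric descriptors
#'
#' Pairwise Spearman correlations (Pearson on midranks, the standard
#' tie handling) over the descriptor columns of a feature table.
#'
#' @param features Data frame; by default all ten descriptor columns
#'   present are used.
#' @param columns Character vector of columns to correlate.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(features, columns = intersect(FEATURE_COLS, names(features))) {
  stopifnot(is.data.frame(features), length(columns) >= 2)
  x <- as.matrix(features[, columns])
  if (nrow(x) < 3) abort("need at least 3 rows")
  const <- apply(x, 2, function(col) diff(range(col)) == 0)
  if (any(const)) {
    abort(paste0("correlation undefined for constant column(s): ",
                 paste(columns[const], collapse = ", ")))
  }
  cor(x, method = "spearman")
}

#' Factor analysis of the descriptor correlation matrix
#'
#' Principal-component extraction from the Spearman or Pearson
#' correlation matrix; the number of factors is chosen by the
#' eigenvalue > 1 criterion and the retained loadings are varimax
#' rotated. Loadings are reproducible up to sign and column permutation.
#'
#' @param features Data frame of descriptor columns.
#' @param columns Columns to analyse (default: the descriptor columns).
#' @param cor_method `"pearson"` (default, the classical rotated
#'   component matrix) or `"spearman"`.
#' @return A `soma_factor` object: list with `eigenvalues` (descending),
#'   `n_factors`, `rotated_loadings` (features x factors),
#'   `communality`, `correlation`.
#' @export
factor_analysis <- function(features, columns = intersect(FEATURE_COLS, names(features)),
                            cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  stopifnot(is.data.frame(features), length(columns) >= 2)
  if (nrow(features) <= length(columns)) {
    abort("need more rows than features")
  }
  x <- as.matrix(features[, columns])
  cm <- cor(x, method = cor_method)
  if (anyNA(cm)) abort("correlation matrix has undefined entries (constant column?)")
  ev <- eigen(cm, symmetric = TRUE)
  lambda <- ev$values
  if (min(lambda) < -1e-8) warn("correlation matrix not positive semi-definite")
  lambda <- pmax(lambda, 0)
  n_factors <- sum(lambda > 1)
  k <- max(n_factors, 1)
  loadings <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(k)]), k)
  rotated <- if (k > 1) {
    rot <- varimax(loadings, normalize = FALSE)
    unclass(rot$loadings)
  } else {
    loadings
  }
  # orient each factor so its largest-magnitude loading is positive
  for (j in seq_len(ncol(rotated))) {
    if (rotated[which.max(abs(rotated[, j])), j] < 0) rotated[, j] <- -rotated[, j]
  }
  dimnames(rotated) <- list(columns, paste0("factor", seq_len(k)))
  structure(
    list(
      eigenvalues = lambda,
      n_factors = n_factors,
      rotated_loadings = rotated,
      communality = rowSums(rotated^2),
      correlation = cm,
      cor_method = cor_method
    ),
    class = "soma_factor"
  )
}

#' @export
print.soma_factor <- function(x, ...) {
  cat("<soma_factor> ", length(x$eigenvalues), " features, ",
      x$n_factors, " factor(s) with eigenvalue > 1\n", sep = "")
  cat("eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.soma_factor <- function(x, ...) {
  as_tibble(x$rotated_loadings, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "factor", values_to = "loading")
}

#' @export
glance.soma_factor <- function(x, ...) {
  tibble(
    n_features = length(x$eigenvalues),
    n_factors = x$n_factors,
    prop_variance = sum(x$eigenvalues[seq_len(max(x$n_factors, 1))]) /
      length(x$eigenvalues)
  )
}

#' Scree plot of a factor analysis
#' @param object A `soma_factor`.
#' @param ... Unused.
#' @return A ggplot object (eigenvalues against factor index, with the
#'   eigenvalue = 1 retention line).
#' @export
autoplot.soma_factor <- function(object, ...) {
  df <- tibble(factor = seq_along(object$eigenvalues),
               eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(.data$factor, .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_continuous(breaks = df$factor) +
    ggplot2::labs(x = "component", y = "eigenvalue") +
    ggplot2::theme_minimal()
}
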