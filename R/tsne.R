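#' t-SNE embedding of morphometric feature vectors
#'
#' Exact (dense) t-distributed stochastic neighbor embedding into two
#' dimensions: Gaussian input affinities calibrated per point to the
#' target perplexity by bisection, symmetrized and exaggerated early,
#' Student-t output kernel, gradient descent with momentum and adaptive
#' per-coordinate gains. Complexity is O(n^2) per iteration, intended
#' for the data sizes at which the map is readable (up to a few
#' thousand cells). Deterministic for a fixed `seed`.
#'
#' @param features Data frame; the descriptor columns are standardized
#'   before computing distances.
#' @param columns Columns to embed (default the descriptor columns).
#' @param perplexity Target perplexity; requires `n > 3 * perplexity`.
#' @param n_iter Gradient-descent iterations.
#' @param seed Integer seed for the random initialization.
#' @return A `soma_tsne` tibble: the non-descriptor columns of
#'   `features` plus embedding coordinates `tsne1`, `tsne2`.
#' @export
tsne_embed <- function(features, columns = intersect(FEATURE_COLS, names(features)),
                       perplexity = 30, n_iter = 500, seed = 1) {
  stopifnot(is.data.frame(features), length(columns) >= 2)
  n <- nrow(features)
  if (n <= 3 * perplexity) {
    abort("perplexity too large: need n > 3 * perplexity")
  }
  x <- as.matrix(features[, columns])
  if (any(!is.finite(x))) abort("non-finite feature value")
  keep <- apply(x, 2, function(col) diff(range(col)) > 0)
  x <- scale(x[, keep, drop = FALSE])

  d2 <- as.matrix(dist(x))^2
  p <- cond_probs(d2, perplexity)
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  y <- withr::with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), ncol = 2))
  gains <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  eta <- 200
  exaggeration <- 12
  stop_lying <- 100L
  pe <- p * exaggeration
  for (it in seq_len(n_iter)) {
    if (it == stop_lying + 1L) pe <- p
    if (it == 250L) momentum <- 0.8
    num <- 1 / (1 + as.matrix(dist(y))^2)
    diag(num) <- 0
    q <- num / sum(num)
    q <- pmax(q, 1e-12)
    w <- (pe - q) * num
    grad <- 4 * (diag(rowSums(w)) - w) %*% y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  out <- dplyr::select(as_tibble(features), -dplyr::all_of(columns))
  out$tsne1 <- y[, 1]
  out$tsne2 <- y[, 2]
  class(out) <- c("soma_tsne", class(out))
  out
}

# Row-wise conditional probabilities at a fixed perplexity, bisection
# on the Gaussian precision beta.
cond_probs <- function(d2, perplexity, tol = 1e-5, max_iter = 50) {
  n <- nrow(d2)
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (k in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) {
        entropy <- 0
      } else {
        entropy <- log(sw) + beta * sum(di * w) / sw
      }
      diff <- entropy - target
      if (abs(diff) < tol) break
      if (diff > 0) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    pi_ <- if (sum(w) == 0) rep(1 / (n - 1), n - 1) else w / sum(w)
    p[i, -i] <- pi_
  }
  p
}

#' @export
autoplot.soma_tsne <- function(object, colour = NULL, ...) {
  aes <- ggplot2::aes(.data$tsne1, .data$tsne2)
  p <- ggplot2::ggplot(object, aes) + ggplot2::theme_minimal() +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2")
  cols <- intersect(c(colour, "predicted_nn", "predicted_rule", "label"),
                    names(object))
  if (length(cols) > 0) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[cols[1]]]),
                            size = 0.8, alpha = 0.8)
  } else {
    p + ggplot2::geom_point(size = 0.8, alpha = 0.8)
  }
}
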