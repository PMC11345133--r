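#' Train a multi-layer-perceptron cell-type classifier
#'
#' Fits a single-hidden-layer perceptron with softmax output
#' ([nnet::nnet()]) on z-score-standardized descriptors. The
#' standardization statistics (per-feature training mean/SD), class
#' list, configuration and seed are stored with the weights, so
#' prediction is deterministic and reproducible.
#'
#' @param features Data frame with a `label` column and descriptor
#'   columns; every class needs at least 10 rows, all descriptors finite.
#' @param columns Descriptor columns used as inputs (default: the ten
#'   canonical descriptors present).
#' @param hidden Hidden-layer size.
#' @param decay L2 weight decay.
#' @param maxit Maximum optimizer iterations.
#' @param seed Integer seed for the random weight initialization.
#' @return A `soma_mlp` object.
#' @export
train_mlp <- function(features, columns = intersect(FEATURE_COLS, names(features)),
                      hidden = 16, decay = 1e-3, maxit = 500, seed = 1) {
  stopifnot(is.data.frame(features), "label" %in% names(features),
            length(columns) >= 1)
  lab <- droplevels(factor(as.character(features$label), levels = CELL_TYPES))
  if (anyNA(lab)) abort("missing or unknown label(s) in training data")
  if (nlevels(lab) < 2) abort("need at least 2 classes")
  small <- table(lab) < 10
  if (any(small)) {
    abort(paste0("class(es) with fewer than 10 rows: ",
                 paste(names(which(small)), collapse = ", ")))
  }
  x <- as.matrix(features[, columns])
  if (any(!is.finite(x))) abort("non-finite feature value in training data")
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  if (any(scale_ == 0)) abort("constant feature column in training data")
  xs <- scale(x, center, scale_)
  y <- nnet::class.ind(lab)
  fit <- withr::with_seed(seed, {
    nnet::nnet(xs, y, size = hidden, softmax = TRUE, decay = decay,
               maxit = maxit, MaxNWts = 100000, trace = FALSE)
  })
  structure(
    list(
      fit = fit,
      columns = columns,
      center = center,
      scale = scale_,
      classes = levels(lab),
      config = list(hidden = hidden, decay = decay, maxit = maxit),
      seed = seed
    ),
    class = "soma_mlp"
  )
}

#' @export
print.soma_mlp <- function(x, ...) {
  cat("<soma_mlp> ", length(x$columns), " inputs -> ", x$config$hidden,
      " hidden -> ", length(x$classes), " classes (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' @export
glance.soma_mlp <- function(x, ...) {
  tibble(
    n_inputs = length(x$columns),
    hidden = x$config$hidden,
    n_classes = length(x$classes),
    n_weights = length(x$fit$wts),
    converged = x$fit$convergence == 0,
    value = x$fit$value
  )
}

#' Class-membership probabilities from a trained classifier
#'
#' Softmax outputs of the network; each row is a probability vector over
#' the training classes (non-negative, summing to 1). The incoming
#' feature table must contain exactly the descriptor columns the model
#' was trained on.
#'
#' @param model A `soma_mlp` from [train_mlp()].
#' @param features Data frame with the model's descriptor columns.
#' @return Numeric matrix, rows = cells, columns = classes.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "soma_mlp"), is.data.frame(features))
  miss <- setdiff(model$columns, names(features))
  if (length(miss) > 0) {
    abort(paste0("feature column(s) missing or misnamed: ",
                 paste(miss, collapse = ", ")))
  }
  x <- as.matrix(features[, model$columns])
  if (any(!is.finite(x))) abort("non-finite feature value")
  xs <- scale(x, model$center, model$scale)
  p <- predict(model$fit, xs, type = "raw")
  p <- matrix(p, ncol = length(model$classes),
              dimnames = list(NULL, model$classes))
  p / rowSums(p)
}

#' Certainty-filtered classification
#'
#' Assigns each cell the maximum-probability class when that probability
#' reaches `certainty_min`, and excludes it otherwise (the
#' reject option: predictions with less than 50% certainty are dropped
#' from downstream composition counts by default).
#'
#' @inheritParams predict_proba
#' @param certainty_min Minimum winning-class probability (default 0.5).
#' @return `features` with `predicted_nn` (factor, `NA` when excluded),
#'   `certainty` and `excluded` columns appended; the exclusion rate
#'   (excluded / total) is stored in the `exclusion_rate` attribute.
#' @export
predict_filtered <- function(model, features, certainty_min = 0.5) {
  p <- predict_proba(model, features)
  win <- max.col(p, ties.method = "first")
  certainty <- p[cbind(seq_len(nrow(p)), win)]
  excluded <- certainty < certainty_min
  lab <- model$classes[win]
  lab[excluded] <- NA_character_
  out <- as_tibble(features)
  out$predicted_nn <- factor(lab, levels = CELL_TYPES)
  out$certainty <- certainty
  out$excluded <- excluded
  attr(out, "exclusion_rate") <- mean(excluded)
  class(out) <- unique(c(class(features), class(out)))
  out
}

#' Persist and restore a trained classifier
#'
#' The bundle stores a format version besides weights, standardization
#' statistics, class list, configuration and seed, so stored models are
#' rejected with a clear error if the format ever changes.
#'
#' @param model A `soma_mlp`.
#' @param path File path for the model bundle.
#' @return `save_mlp()` returns `path` invisibly; `load_mlp()` the model.
#' @export
save_mlp <- function(model, path) {
  stopifnot(inherits(model, "soma_mlp"))
  saveRDS(list(format = "soma_mlp/1", model = model), path)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "soma_mlp/1") ||
      !inherits(obj$model, "soma_mlp")) {
    abort("not a soma_mlp model bundle (or unsupported format version)")
  }
  obj$model
}

#' Exclusion rate of a filtered prediction table
#' @param predictions Output of [predict_filtered()].
#' @return Fraction of cells excluded.
#' @export
exclusion_rate <- function(predictions) {
  stopifnot("excluded" %in% names(predictions))
  mean(predictions$excluded)
}
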