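#' Threshold rule set for morphological classification
#'
#' Container for the seven decision thresholds that separate the
#' morphological classes: the Aspect Ratio cut between granule and
#' pyramidal cells, the Aspect Ratio cut between pyramidal and fusiform
#' cells, the two Area cuts among pyramidal sizes, the Area cut between
#' small and large fusiform cells, and the Form Factor / Solidity pair
#' that defines the polymorphic region. Defaults are the published
#' ROC-derived values.
#'
#' @param ar_granule_max Aspect Ratio below which a cell is granule (1.38).
#' @param ar_fusiform_min Aspect Ratio at/above which a cell is fusiform (1.86).
#' @param area_small_medium Area (µm²) cut between small and medium
#'   pyramidal (202.2).
#' @param area_medium_large Area (µm²) cut between medium and large
#'   pyramidal (394.5).
#' @param area_fusiform_split Area (µm²) cut between small and large
#'   fusiform (161.2).
#' @param ff_polymorphic_max Form Factor below which (together with the
#'   Solidity criterion) a cell is polymorphic (0.79).
#' @param solidity_polymorphic_max Solidity below which (together with
#'   the Form Factor criterion) a cell is polymorphic (0.95).
#' @return A `soma_ruleset` object.
#' @export
ruleset <- function(ar_granule_max = 1.38,
                    ar_fusiform_min = 1.86,
                    area_small_medium = 202.2,
                    area_medium_large = 394.5,
                    area_fusiform_split = 161.2,
                    ff_polymorphic_max = 0.79,
                    solidity_polymorphic_max = 0.95) {
  vals <- c(
    ar_granule_max = ar_granule_max,
    ar_fusiform_min = ar_fusiform_min,
    area_small_medium = area_small_medium,
    area_medium_large = area_medium_large,
    area_fusiform_split = area_fusiform_split,
    ff_polymorphic_max = ff_polymorphic_max,
    solidity_polymorphic_max = solidity_polymorphic_max
  )
  if (any(vals <= 0)) abort("all thresholds must be positive")
  if (ar_granule_max >= ar_fusiform_min) {
    abort("ar_granule_max must be below ar_fusiform_min")
  }
  if (area_small_medium >= area_medium_large) {
    abort("area_small_medium must be below area_medium_large")
  }
  structure(as.list(vals), class = "soma_ruleset")
}

#' @rdname ruleset
#' @export
default_ruleset <- function() ruleset()

#' @export
print.soma_ruleset <- function(x, ...) {
  cat("<soma_ruleset>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
tidy.soma_ruleset <- function(x, ...) {
  tibble(
    threshold = names(unclass(x)),
    value = unlist(unclass(x), use.names = FALSE),
    parameter = c("aspect_ratio", "aspect_ratio", "area_um2", "area_um2",
                  "area_um2", "form_factor", "solidity")
  )
}

# Vectorized decision procedure on descriptor columns. Decision order:
# (1) polymorphic when form_factor < ff_max AND solidity < sol_max;
# (2) granule when aspect_ratio < ar_granule_max;
# (3) pyramidal when aspect_ratio < ar_fusiform_min, size split by area
#     (lower bounds inclusive, upper bounds exclusive);
# (4) otherwise fusiform, split by area.
# With polymorphic_first = FALSE the polymorphic test runs last.
apply_ruleset <- function(features, rules = default_ruleset(),
                          polymorphic_first = TRUE) {
  ar <- features$aspect_ratio
  area <- features$area_um2
  ff <- features$form_factor
  sol <- features$solidity
  n <- length(ar)
  poly <- ff < rules$ff_polymorphic_max & sol < rules$solidity_polymorphic_max
  out <- character(n)
  gran <- ar < rules$ar_granule_max
  pyr <- !gran & ar < rules$ar_fusiform_min
  fus <- !gran & !pyr
  out[gran] <- "granule"
  out[pyr & area < rules$area_small_medium] <- "small_pyramidal"
  out[pyr & area >= rules$area_small_medium &
        area < rules$area_medium_large] <- "medium_pyramidal"
  out[pyr & area >= rules$area_medium_large] <- "large_pyramidal"
  out[fus & area < rules$area_fusiform_split] <- "small_fusiform"
  out[fus & area >= rules$area_fusiform_split] <- "large_fusiform"
  if (polymorphic_first) {
    out[poly] <- "polymorphic"
  } else {
    out[poly & out == ""] <- "polymorphic"
  }
  factor(out, levels = CELL_TYPES)
}

#' Classify cells by threshold rules
#'
#' Applies the rule set's deterministic decision procedure to a feature
#' table. The polymorphic criterion (Form Factor and Solidity jointly
#' low) is tested first by default because it is defined against all
#' other classes; the remaining classes partition the
#' Aspect Ratio x Area plane. Every feature vector maps to exactly one
#' class.
#'
#' @param features A `soma_features` tibble (or any data frame with
#'   `aspect_ratio`, `area_um2`, `form_factor`, `solidity` columns).
#' @param rules A [ruleset()].
#' @param polymorphic_first Test the polymorphic criterion before (TRUE,
#'   default) or after the aspect-ratio/area grid.
#' @return `features` with a `predicted_rule` factor column appended.
#' @export
#' @examples
#' f <- tibble::tibble(aspect_ratio = 1.2, area_um2 = 100,
#'                     form_factor = 0.88, solidity = 0.98)
#' classify_cells(f)$predicted_rule # granule
classify_cells <- function(features, rules = default_ruleset(),
                           polymorphic_first = TRUE) {
  stopifnot(is.data.frame(features))
  need <- c("aspect_ratio", "area_um2", "form_factor", "solidity")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0) {
    abort(paste0("missing feature column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- !is.finite(features$aspect_ratio) | features$aspect_ratio < 1 |
    !is.finite(features$area_um2) | features$area_um2 <= 0 |
    !is.finite(features$form_factor) | features$form_factor <= 0 |
    !is.finite(features$solidity) | features$solidity <= 0
  if (any(bad)) abort("invalid feature vector(s): descriptors out of range")
  out <- as_tibble(features)
  out$predicted_rule <- apply_ruleset(features, rules, polymorphic_first)
  class(out) <- unique(c(class(features), class(out)))
  out
}

#' Empirical ROC curve over exact candidate thresholds
#'
#' One point per candidate threshold; candidates are the midpoints
#' between adjacent distinct sorted scores plus -Inf and +Inf, so
#' sensitivity and specificity are exact counts over the input. With
#' `direction = ">="` (default) a case is called positive when its score
#' is at or above the threshold; `"<="` reverses the call (used for
#' descriptors where the positive class has low values, e.g. Form Factor
#' for polymorphic cells).
#'
#' @param scores Numeric scores.
#' @param labels Logical/0-1 vector, `TRUE`/1 = positive class.
#' @param direction `">="` or `"<="`.
#' @return A `soma_roc` tibble with columns `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
roc_curve <- function(scores, labels, direction = c(">=", "<=")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (!any(labels) || all(labels)) {
    abort("roc_curve needs both classes present")
  }
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  pos <- sort(scores[labels])
  neg <- sort(scores[!labels])
  # thresholds are strictly between data values (or infinite), so
  # counts <= thr equal counts < thr
  n_pos_le <- findInterval(thr, pos)
  n_neg_le <- findInterval(thr, neg)
  if (direction == ">=") {
    sens <- (length(pos) - n_pos_le) / length(pos)
    spec <- n_neg_le / length(neg)
  } else {
    sens <- n_pos_le / length(pos)
    spec <- (length(neg) - n_neg_le) / length(neg)
  }
  out <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
  attr(out, "direction") <- direction
  class(out) <- c("soma_roc", class(out))
  out
}

#' @export
glance.soma_roc <- function(x, ...) {
  # trapezoidal AUC over (1 - specificity, sensitivity)
  fpr <- 1 - x$specificity
  o <- order(fpr, x$sensitivity)
  fpr <- fpr[o]; tpr <- x$sensitivity[o]
  tibble(
    auc = sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2),
    n_thresholds = nrow(x)
  )
}

#' @export
autoplot.soma_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Select a classification threshold from a ROC curve
#'
#' Among ROC points meeting the specificity aim (default >= 0.90),
#' returns the one with maximal sensitivity, breaking sensitivity ties
#' toward the highest specificity and remaining ties toward the smallest
#' threshold (so that for separable classes the selected threshold sits
#' at the midpoint of the class gap). If no point meets the aim, falls back to
#' maximizing Youden's J (sensitivity + specificity - 1) and flags the
#' result as not meeting the specificity aim.
#'
#' @param roc A `soma_roc` tibble from [roc_curve()].
#' @param min_specificity,min_sensitivity The selection aims.
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`, `met_specificity_aim`, `met_sensitivity_aim`.
#' @export
select_threshold <- function(roc, min_specificity = 0.90,
                             min_sensitivity = 0.70) {
  stopifnot(is.data.frame(roc), nrow(roc) > 0)
  ok <- roc$specificity >= min_specificity & is.finite(roc$threshold)
  cand <- if (any(ok)) roc[ok, ] else roc[is.finite(roc$threshold), ]
  if (nrow(cand) == 0) cand <- roc
  if (any(ok)) {
    best <- cand[cand$sensitivity == max(cand$sensitivity), ]
    best <- best[best$specificity == max(best$specificity), ]
    best <- best[which.min(best$threshold), ]
  } else {
    j <- cand$sensitivity + cand$specificity - 1
    best <- cand[j == max(j), ]
    best <- best[which.min(best$threshold), ]
  }
  tibble(
    threshold = best$threshold,
    sensitivity = best$sensitivity,
    specificity = best$specificity,
    youden_j = best$sensitivity + best$specificity - 1,
    met_specificity_aim = best$specificity >= min_specificity,
    met_sensitivity_aim = best$sensitivity >= min_sensitivity
  )
}

# One binary contrast: ROC + threshold selection.
contrast_threshold <- function(scores, is_positive, direction,
                               min_specificity, min_sensitivity, name) {
  if (!any(is_positive) || all(is_positive)) {
    abort(paste0("cannot derive threshold for contrast '", name,
                 "': a class is missing"))
  }
  roc <- roc_curve(scores, is_positive, direction)
  sel <- select_threshold(roc, min_specificity, min_sensitivity)
  sel$contrast <- name
  sel
}

#' Derive a threshold rule set from labeled features by ROC analysis
#'
#' Runs ROC threshold selection (specificity aim 0.90, sensitivity aim
#' 0.70) on the seven binary contrasts that define the rule set:
#' granule vs pyramidal and pyramidal vs fusiform on Aspect Ratio, the
#' pyramidal size splits and the fusiform size split on Area,
#' polymorphic vs all other classes on Form Factor, and polymorphic vs
#' fusiform on Solidity.
#'
#' @param features Data frame with a `label` column holding all seven
#'   non-gigantic classes plus the descriptor columns.
#' @param min_specificity,min_sensitivity Selection aims per contrast.
#' @return A `soma_ruleset` whose `selection` attribute is a tibble of
#'   per-contrast sensitivity/specificity (see `tidy()` on it).
#' @export
derive_ruleset <- function(features, min_specificity = 0.90,
                           min_sensitivity = 0.70) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  lab <- as.character(features$label)
  required <- setdiff(CELL_TYPES, "gigantic_pyramidal")
  miss <- setdiff(required, unique(lab))
  if (length(miss) > 0) {
    abort(paste0("missing class(es) in training data: ",
                 paste(miss, collapse = ", ")))
  }
  pyram <- c("small_pyramidal", "medium_pyramidal", "large_pyramidal",
             "gigantic_pyramidal")
  fusi <- c("small_fusiform", "large_fusiform")

  sub <- function(keep) features[lab %in% keep, , drop = FALSE]
  lab_of <- function(df) as.character(df$label)

  gp <- sub(c("granule", pyram))
  c1 <- contrast_threshold(gp$aspect_ratio, lab_of(gp) %in% pyram, ">=",
                           min_specificity, min_sensitivity,
                           "granule_vs_pyramidal (aspect_ratio)")
  pf <- sub(c(pyram, fusi))
  c2 <- contrast_threshold(pf$aspect_ratio, lab_of(pf) %in% fusi, ">=",
                           min_specificity, min_sensitivity,
                           "pyramidal_vs_fusiform (aspect_ratio)")
  sm <- sub(c("small_pyramidal", "medium_pyramidal"))
  c3 <- contrast_threshold(sm$area_um2, lab_of(sm) == "medium_pyramidal", ">=",
                           min_specificity, min_sensitivity,
                           "small_vs_medium_pyramidal (area)")
  ml <- sub(c("medium_pyramidal", "large_pyramidal"))
  c4 <- contrast_threshold(ml$area_um2, lab_of(ml) == "large_pyramidal", ">=",
                           min_specificity, min_sensitivity,
                           "medium_vs_large_pyramidal (area)")
  ff <- sub(fusi)
  c5 <- contrast_threshold(ff$area_um2, lab_of(ff) == "large_fusiform", ">=",
                           min_specificity, min_sensitivity,
                           "small_vs_large_fusiform (area)")
  c6 <- contrast_threshold(features$form_factor,
                           lab == "polymorphic", "<=",
                           min_specificity, min_sensitivity,
                           "polymorphic_vs_all (form_factor)")
  pfu <- sub(c("polymorphic", fusi))
  c7 <- contrast_threshold(pfu$solidity, lab_of(pfu) == "polymorphic", "<=",
                           min_specificity, min_sensitivity,
                           "polymorphic_vs_fusiform (solidity)")

  sel <- dplyr::bind_rows(c1, c2, c3, c4, c5, c6, c7)
  rs <- ruleset(
    ar_granule_max = c1$threshold,
    ar_fusiform_min = c2$threshold,
    area_small_medium = c3$threshold,
    area_medium_large = c4$threshold,
    area_fusiform_split = c5$threshold,
    ff_polymorphic_max = c6$threshold,
    solidity_polymorphic_max = c7$threshold
  )
  attr(rs, "selection") <- sel
  rs
}
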