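# Contour JSONL: one JSON object per line with fields id, subject,
# region, layer, vertices_um (list of [x, y] pairs) and optional label.
# Feature CSV: fixed column order, full-precision floats.

FEATURE_CSV_COLS <- c(
  "id", "subject", "region", "layer",
  FEATURE_COLS,
  "label", "predicted_rule", "predicted_nn", "certainty", "excluded"
)

#' Read and write soma contours as line-delimited JSON
#'
#' `write_contours()` writes one JSON object per contour;
#' `read_contours()` parses them back, normalizing orientation to
#' counterclockwise and validating each polygon. In strict mode (the
#' default) a malformed line is a fatal error citing its line number;
#' with `strict = FALSE` malformed lines are reported as warnings and
#' skipped.
#'
#' @param contours A `soma_contours` tibble.
#' @param path File path.
#' @param strict Fatal (`TRUE`) or skip-with-warning (`FALSE`) handling
#'   of malformed lines.
#' @return `read_contours()` returns a `soma_contours` tibble;
#'   `write_contours()` returns `path` invisibly.
#' @export
write_contours <- function(contours, path) {
  stopifnot(is.data.frame(contours), "vertices" %in% names(contours))
  lines <- purrr::map_chr(seq_len(nrow(contours)), function(i) {
    v <- contours$vertices[[i]]
    obj <- list(
      id = contours$id[i],
      subject = contours$subject[i],
      region = as.character(contours$region[i]),
      layer = as.character(contours$layer[i]),
      vertices_um = unname(lapply(seq_len(nrow(v)), function(k) v[k, ]))
    )
    if ("label" %in% names(contours) && !is.na(contours$label[i])) {
      obj$label <- as.character(contours$label[i])
    }
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parse_line <- function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    problem <- function(msg) {
      full <- sprintf("line %d: %s", i, msg)
      if (strict) abort(full) else {
        warn(paste0("skipping ", full))
        NULL
      }
    }
    if (is.null(obj)) return(problem("invalid JSON"))
    need <- c("id", "subject", "region", "layer", "vertices_um")
    miss <- setdiff(need, names(obj))
    if (length(miss) > 0) {
      return(problem(paste0("missing required field(s): ",
                            paste(miss, collapse = ", "))))
    }
    v <- obj$vertices_um
    if (is.list(v)) v <- do.call(rbind, v)
    if (!is.numeric(v)) return(problem("non-numeric vertex"))
    v <- matrix(as.numeric(v), ncol = 2)
    if (nrow(v) < 3) return(problem("fewer than 3 vertices"))
    v <- tryCatch(normalize_polygon(v),
                  error = function(e) problem(conditionMessage(e)))
    if (is.null(v)) return(NULL)
    tibble(
      id = as.character(obj$id),
      subject = as.character(obj$subject),
      region = as_region(obj$region),
      layer = as_layer(obj$layer),
      label = as_cell_type(obj$label %||% NA_character_),
      vertices = list(v)
    )
  }
  rows <- purrr::compact(purrr::map(seq_along(lines), parse_line))
  if (length(rows) == 0) abort("no valid contours in file")
  out <- dplyr::bind_rows(rows)
  class(out) <- c("soma_contours", class(out))
  out
}

#' Read and write the morphometric feature table as CSV
#'
#' Fixed canonical column order (`id`, `subject`, `region`, `layer`, the
#' ten descriptors, `label`, `predicted_rule`, `predicted_nn`,
#' `certainty`, `excluded`); columns absent from `features` are written
#' empty. Floats round-trip at full precision. `read_feature_table()`
#' errors when a required column is missing from the header.
#'
#' @param features A `soma_features` tibble.
#' @param path File path.
#' @return `read_feature_table()` returns a `soma_features` tibble;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features))
  out <- as_tibble(features)
  if ("vertices" %in% names(out)) out$vertices <- NULL
  for (col in FEATURE_CSV_COLS) {
    if (!col %in% names(out)) {
      out[[col]] <- if (col == "excluded") NA else NA_character_
    }
  }
  out <- out[, FEATURE_CSV_COLS]
  # 17 significant digits: exact double round trip
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA_character_
      out[[col]] <- v
    }
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  miss <- setdiff(FEATURE_CSV_COLS, hdr)
  if (length(miss) > 0) {
    abort(paste0("feature CSV missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  out <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  # parse doubles through strtod for an exact round trip
  for (col in c(FEATURE_COLS, "certainty")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  out$excluded <- as.logical(out$excluded)
  out$region <- as_region(out$region)
  out$layer <- as_layer(out$layer)
  for (col in c("label", "predicted_rule", "predicted_nn")) {
    out[[col]] <- as_cell_type(out[[col]])
  }
  out <- as_tibble(out)
  class(out) <- c("soma_features", class(out))
  out
}

# Recognized pipeline configuration keys and their defaults.
default_config <- function() {
  list(
    seed = 1,
    regions = c("BA9", "BA14r", "BA24"),
    n_cells_per_region = 2000,
    n_train = 2850,
    certainty_min = 0.5,
    ruleset = as.list(unclass(default_ruleset())),
    nn = list(hidden = 16, decay = 1e-3, maxit = 500),
    p_adjust_method = "bonferroni",
    output_dir = NULL
  )
}

#' Read a pipeline configuration file
#'
#' YAML configuration with the keys of `default_config()`; unknown keys
#' are rejected with an error naming the key. Missing keys take their
#' defaults.
#'
#' @param path YAML file path (or `NULL` for all defaults).
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (!is.null(user$ruleset)) {
    bad <- setdiff(names(user$ruleset), names(unclass(default_ruleset())))
    if (length(bad) > 0) {
      abort(paste0("unknown configuration key(s): ",
                   paste0("ruleset.", bad, collapse = ", ")))
    }
  }
  utils::modifyList(cfg, user)
}

#' Write a pipeline configuration file
#' @param config Named list as returned by [read_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
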