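# Region and layer vocabularies used throughout the package. Contours carry
# both as factors with these levels; "other"/"unknown" absorb anything else.
REGIONS <- c("BA9", "BA14r", "BA24", "other")
LAYERS <- c("I", "II", "III", "IV", "V", "VI", "unknown")

# The eight morphological classes (soma shape and size), after
# von Economo & Koskinas, plus the polymorphic category for irregular somata.
CELL_TYPES <- c(
  "granule",
  "small_pyramidal", "medium_pyramidal", "large_pyramidal",
  "gigantic_pyramidal",
  "small_fusiform", "large_fusiform",
  "polymorphic"
)

# The ten morphometric descriptors, in canonical column order.
FEATURE_COLS <- c(
  "perimeter_um", "area_um2", "feret_max_um", "feret_min_um",
  "aspect_ratio", "compactness", "convexity", "form_factor",
  "roundness", "solidity"
)

as_region <- function(x) {
  x <- as.character(x)
  x[!x %in% REGIONS] <- "other"
  factor(x, levels = REGIONS)
}

as_layer <- function(x) {
  x <- as.character(x)
  x[!x %in% LAYERS] <- "unknown"
  factor(x, levels = LAYERS)
}

as_cell_type <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), CELL_TYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown cell type(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = CELL_TYPES)
}
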