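#' Run the full synthetic-column analysis pipeline
#'
#' End-to-end composition analysis driven by a configuration list:
#' generate one synthetic cortical column per region, measure the ten
#' descriptors, classify by threshold rules, train the MLP on a
#' manually-labeled-sized subsample, predict the remaining cells with
#' the certainty filter, and assemble composition tables and the main
#' statistics. Everything is reproducible from `config$seed`.
#'
#' @param config Configuration list (see [read_config()]); any entries
#'   given override the defaults.
#' @return A list with elements `contours`, `features` (with
#'   `predicted_rule`), `train`, `test` (with `predicted_nn`,
#'   `certainty`, `excluded`), `model`, `derived_rules`, `composition`,
#'   `composition_by_region`, `chi_square`, `kruskal_area`,
#'   `exclusion_rate`, `agreement` (rule vs MLP on non-excluded test
#'   rows) and `config`. If `config$output_dir` is set, contour JSONL,
#'   feature CSV and composition CSV files are written there.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  withr::with_seed(cfg$seed, {
    contours <- dplyr::bind_rows(lapply(cfg$regions, function(rg) {
      generate_column(composition_profile(rg), cfg$n_cells_per_region,
                      subject = paste0("synthetic_", rg))
    }))
    class(contours) <- c("soma_contours", class(contours))
    features <- compute_features(contours)
    rules <- do.call(ruleset, cfg$ruleset)
    features <- classify_cells(features, rules)

    n <- nrow(features)
    n_train <- min(cfg$n_train, floor(n / 2))
    idx <- sample.int(n, n_train)
    train <- features[idx, ]
    test <- features[-idx, ]
    model <- train_mlp(train, hidden = cfg$nn$hidden, decay = cfg$nn$decay,
                       maxit = cfg$nn$maxit, seed = cfg$seed)
    test <- predict_filtered(model, test, cfg$certainty_min)

    derived_rules <- derive_ruleset(simulate_feature_table(7000, seed = cfg$seed))

    composition <- build_composition(test, by = c("region", "layer"))
    composition_by_region <- build_composition(test, by = "region")
    chi <- chi_square_composition(composition_by_region, "region")
    kw <- kruskal_wallis_dunn(features, "area_um2", "region",
                              p_adjust_method = cfg$p_adjust_method)
    keep <- !test$excluded
    agreement <- mean(as.character(test$predicted_nn[keep]) ==
                        as.character(test$predicted_rule[keep]))

    if (!is.null(cfg$output_dir)) {
      dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
      write_contours(contours, file.path(cfg$output_dir, "contours.jsonl"))
      write_feature_table(test, file.path(cfg$output_dir, "features.csv"))
      readr::write_csv(composition, file.path(cfg$output_dir, "composition.csv"))
    }

    list(
      contours = contours,
      features = features,
      train = train,
      test = test,
      model = model,
      derived_rules = derived_rules,
      composition = composition,
      composition_by_region = composition_by_region,
      chi_square = chi,
      kruskal_area = kw,
      exclusion_rate = exclusion_rate(test),
      agreement = agreement,
      config = cfg
    )
  })
}
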