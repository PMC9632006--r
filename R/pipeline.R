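#' Resolve a full run configuration
#'
#' Merges (in increasing precedence) the built-in defaults, a flat
#' `key = value` / `key: value` text config file, and explicit overrides.
#' Every key has a documented default in [feature_config()],
#' [booster_params()] and [synthetic_config()]; unknown keys raise an
#' error so typos do not silently fall back to defaults.
#'
#' @param config_file optional path to a flat key-value text file; lines
#'   starting with `#` are comments.
#' @param overrides named list of settings overriding file and defaults.
#' @return named list of class `"run_config"` with `seed`, `folds`,
#'   `mask_test_in_similarity`, `score_threshold`, `top_n`, the
#'   feature-config keys, the booster keys (prefixed `booster_`), and the
#'   synthetic-config keys (prefixed `sim_`).
#' @export
resolve_config <- function(config_file = NULL, overrides = list()) {
  defaults <- c(list(seed = 42L, folds = 5L, mask_test_in_similarity = TRUE,
                     score_threshold = 0.9, top_n = 20L),
                unclass(feature_config()),
                stats::setNames(unclass(booster_params()),
                                paste0("booster_", names(booster_params()))),
                stats::setNames(unclass(synthetic_config()),
                                paste0("sim_", names(synthetic_config()))))
  cfg <- defaults
  apply_entries <- function(cfg, entries, origin) {
    for (key in names(entries)) {
      if (!key %in% names(cfg)) {
        stop(sprintf("unknown configuration key '%s' (%s)", key, origin))
      }
      val <- entries[[key]]
      if (is.character(val)) {
        parsed <- suppressWarnings(as.numeric(val))
        if (!is.na(parsed)) val <- parsed
        else if (toupper(val) %in% c("TRUE", "FALSE")) val <- as.logical(val)
      }
      cfg[[key]] <- if (is.numeric(cfg[[key]]) && is.numeric(val)) {
        if (is.integer(defaults[[key]])) as.integer(val) else val
      } else val
    }
    cfg
  }
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      stop(sprintf("config file not found: %s", config_file))
    }
    lines <- readLines(config_file, encoding = "UTF-8")
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$", lines))
    bad <- which(lengths(kv) != 3L)
    if (length(bad)) stop(sprintf("malformed config line: '%s'", lines[bad[1L]]))
    entries <- stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, "", 2L))
    cfg <- apply_entries(cfg, entries, config_file)
  }
  cfg <- apply_entries(cfg, overrides, "override")
  structure(cfg, class = "run_config")
}

# internal: split a resolved run_config back into module configs
split_config <- function(cfg) {
  list(feature = do.call(feature_config,
                         unclass(cfg)[names(feature_config())]),
       booster = do.call(booster_params,
                         stats::setNames(unclass(cfg)[paste0("booster_", names(booster_params()))],
                                         names(booster_params()))),
       synthetic = do.call(synthetic_config,
                           stats::setNames(unclass(cfg)[paste0("sim_", names(synthetic_config()))],
                                           names(synthetic_config()))))
}

# internal: read the three inputs for a pipeline stage and harmonize them
load_inputs <- function(assoc_path, expr_path = NULL, dsim_path = NULL) {
  assoc <- read_association(assoc_path,
                            format = if (grepl("edge", assoc_path)) "edge_list" else "matrix")
  expr <- if (!is.null(expr_path)) read_expression(expr_path)
  dsim <- if (!is.null(dsim_path)) read_similarity(dsim_path)
  h <- harmonize_ids(assoc, expr, dsim)
  h
}

#' Run one pipeline stage end to end
#'
#' Orchestrates the five stages over files on disk. `simulate` writes the
#' three synthetic input TSVs plus a ground-truth group sidecar;
#' `features` writes the labelled pair feature table; `cv` writes per-fold
#' and mean metrics as TSV and JSON; `train`/`predict` write the scored
#' candidate table. A plain-text run log captures the resolved
#' configuration and seed, making every run reproducible from its log.
#'
#' @param command one of `"simulate"`, `"features"`, `"cv"`, `"train"`,
#'   `"predict"` (`train` and `predict` are synonyms over files: fit on all
#'   labelled pairs, then score candidates).
#' @param out_dir output directory, created if missing.
#' @param assoc,expr,dsim input file paths (not needed for `simulate`).
#' @param config_file,overrides forwarded to [resolve_config()].
#' @return invisibly, a list of written file paths plus the stage result.
#' @export
run_pipeline <- function(command = c("simulate", "features", "cv", "train", "predict"),
                         out_dir, assoc = NULL, expr = NULL, dsim = NULL,
                         config_file = NULL, overrides = list()) {
  command <- match.arg(command)
  cfg <- resolve_config(config_file, overrides)
  parts <- split_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, paste0(command, "_run_log.txt"))
  flat <- unclass(cfg)
  writeLines(c(sprintf("command: %s", command),
               sprintf("package: cdaboost %s",
                       as.character(utils::packageVersion("cdaboost"))),
               sprintf("%s: %s", names(flat), vapply(flat, format, ""))),
             log_path)
  written <- list(log = log_path)

  if (command == "simulate") {
    sim_cfg <- parts$synthetic
    sim_cfg$seed <- as.integer(cfg$seed)
    ds <- generate_dataset(sim_cfg)
    written$assoc <- write_matrix_tsv(ds$assoc, file.path(out_dir, "association.tsv"))
    written$expr <- write_matrix_tsv(ds$expr, file.path(out_dir, "expression.tsv"))
    written$dsim <- write_matrix_tsv(ds$dsim, file.path(out_dir, "disease_similarity.tsv"))
    truth <- data.frame(id = c(names(ds$groups$circ), names(ds$groups$disease)),
                        type = rep(c("circRNA", "disease"),
                                   c(length(ds$groups$circ), length(ds$groups$disease))),
                        group = c(ds$groups$circ, ds$groups$disease))
    utils::write.table(truth, file.path(out_dir, "ground_truth_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written$truth <- file.path(out_dir, "ground_truth_groups.tsv")
    return(invisible(c(written, list(result = ds))))
  }

  if (is.null(assoc)) stop("this command requires --assoc")
  inputs <- load_inputs(assoc, expr, dsim)

  if (command == "features") {
    pair_set <- build_pair_dataset(inputs$assoc, seed = cfg$seed)
    feats <- pair_features_from_inputs(inputs$assoc, inputs$expr, inputs$dsim,
                                       pair_set[, c("circRNA", "disease")],
                                       pair_set$label, parts$feature)
    path <- file.path(out_dir, "pair_features.tsv")
    utils::write.table(feats, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written$features <- path
    return(invisible(c(written, list(result = feats))))
  }

  if (command == "cv") {
    report <- cross_validate(inputs$assoc, inputs$expr, inputs$dsim,
                             k = cfg$folds, params = parts$booster,
                             cfg = parts$feature, seed = cfg$seed,
                             mask_test_in_similarity = cfg$mask_test_in_similarity)
    tsv <- file.path(out_dir, "cv_metrics.tsv")
    utils::write.table(report$folds, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    json <- file.path(out_dir, "cv_metrics.json")
    jsonlite::write_json(list(folds = report$folds, mean = as.list(report$mean)),
                         json, auto_unbox = TRUE, digits = NA)
    written$metrics_tsv <- tsv
    written$metrics_json <- json
    return(invisible(c(written, list(result = report))))
  }

  # train / predict
  scored <- train_final_and_score(inputs$assoc, inputs$expr, inputs$dsim,
                                  params = parts$booster, cfg = parts$feature,
                                  seed = cfg$seed)
  path <- file.path(out_dir, "predictions.tsv")
  utils::write.table(scored, path, sep = "\t", quote = FALSE, row.names = FALSE)
  written$predictions <- path
  top <- utils::head(scored[scored$score > cfg$score_threshold, , drop = FALSE],
                     cfg$top_n)
  top_path <- file.path(out_dir, "predictions_high_confidence.tsv")
  utils::write.table(top, top_path, sep = "\t", quote = FALSE, row.names = FALSE)
  written$high_confidence <- top_path
  invisible(c(written, list(result = scored)))
}
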