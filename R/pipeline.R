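#' Build a pipeline configuration
#'
#' Configuration for a full reproducible run: either simulate a cohort or
#' read panel/subject CSVs, then screen, random-forest halving, green
#' windows, decision-tree reduction, scoring and evaluation. Serializes to
#' YAML with a stable round trip.
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory for all stage artifacts.
#' @param simulate If `TRUE`, generate the cohort from
#'   [build_default_spec()]; otherwise `panel_path` and `subjects_path`
#'   must point at existing CSVs.
#' @param group_sizes Named sizes for the simulated cohort.
#' @param plant_featured Passed to [build_default_spec()]; default `TRUE`
#'   so the downstream feature-reduction stages see the full planted
#'   signal structure.
#' @param panel_path,subjects_path Input CSVs when `simulate = FALSE`.
#' @param pair Two-class comparison driving feature selection (default
#'   NAFL vs NASH, the score's target contrast).
#' @param cv `"kfold10"` or `"loocv"`.
#' @param ks Feature-halving sequence.
#' @param ntree Trees per forest.
#' @param cutoff_mode `"youden"` (select from the data) or `"fixed"`.
#' @param cutoff_value Threshold used when `cutoff_mode = "fixed"`.
#' @param exclusions Optional data.frame of per-value exclusions with
#'   columns `id`, `metabolite`; excluded values are set to `NA` and the
#'   affected subjects are dropped from stages that need those values.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 2022L, out_dir = "metanash-run",
                            simulate = TRUE,
                            group_sizes = c(healthy = 25L, NAFL = 42L,
                                            NASH = 19L),
                            plant_featured = TRUE,
                            panel_path = NULL, subjects_path = NULL,
                            pair = c("NAFL", "NASH"),
                            cv = "kfold10",
                            ks = c(79L, 64L, 32L, 16L, 8L, 4L),
                            ntree = 500L,
                            cutoff_mode = c("youden", "fixed"),
                            cutoff_value = published_cutoffs()[["metanash"]],
                            exclusions = NULL) {
  cutoff_mode <- match.arg(cutoff_mode)
  if (!simulate && (is.null(panel_path) || is.null(subjects_path)))
    stop("configuration error: no panel and no simulation requested")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, group_sizes = group_sizes,
                 plant_featured = plant_featured,
                 panel_path = panel_path, subjects_path = subjects_path,
                 pair = pair, cv = cv, ks = as.integer(ks),
                 ntree = as.integer(ntree), cutoff_mode = cutoff_mode,
                 cutoff_value = cutoff_value, exclusions = exclusions),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$group_sizes <- as.list(obj$group_sizes)
  if (!is.null(obj$exclusions))
    obj$exclusions <- lapply(seq_len(nrow(obj$exclusions)), function(i)
      as.list(obj$exclusions[i, ]))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  excl <- NULL
  if (!is.null(obj$exclusions))
    excl <- do.call(rbind, lapply(obj$exclusions, function(r)
      data.frame(id = r$id, metabolite = r$metabolite,
                 stringsAsFactors = FALSE)))
  pipeline_config(seed = obj$seed, out_dir = obj$out_dir,
                  simulate = obj$simulate,
                  group_sizes = unlist(obj$group_sizes),
                  plant_featured = obj$plant_featured,
                  panel_path = obj$panel_path,
                  subjects_path = obj$subjects_path,
                  pair = unlist(obj$pair), cv = obj$cv,
                  ks = unlist(obj$ks), ntree = obj$ntree,
                  cutoff_mode = obj$cutoff_mode,
                  cutoff_value = obj$cutoff_value, exclusions = excl)
}

#' Write / read a metabolite panel as CSV
#'
#' First column `id`, remaining columns the catalog metabolites.
#'
#' @param panel Numeric matrix with subject rownames.
#' @param path CSV path.
#' @return `path` (write) or a numeric matrix (read).
#' @export
write_panel_csv <- function(panel, path) {
  df <- data.frame(id = rownames(panel), panel, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Executes simulate -> screen -> rf-select -> green-window -> tree ->
#' score -> evaluate in order, writing every intermediate artifact under
#' `config$out_dir` (panel.csv, subjects.csv, screen.csv, halving.json,
#' windows.csv, tree.json, scores.csv, report.json). Identical config and
#' seed give a byte-identical report; stage progress is logged to stderr.
#'
#' @param config A [pipeline_config()].
#' @return The run report (also written as `report.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(package_version = as.character(utils::packageVersion("metanash")),
                 seed = config$seed)

  # -- simulate / load ------------------------------------------------
  if (config$simulate) {
    stage_log("simulate", "generating cohort, seed ", config$seed)
    spec <- build_default_spec(seed = config$seed,
                               plant_featured = config$plant_featured)
    spec$group_sizes <- stats::setNames(
      as.integer(config$group_sizes[names(spec$group_sizes)]),
      names(spec$group_sizes))
    cohort <- generate_cohort(spec)
    panel <- cohort$panel
    subjects <- cohort$subjects
    write_cohort_spec(spec, out("spec.yaml"))
  } else {
    stage_log("simulate", "reading panel from ", config$panel_path)
    panel <- read_panel_csv(config$panel_path)
    subjects <- utils::read.csv(config$subjects_path,
                                stringsAsFactors = FALSE)
  }
  if (!is.null(config$exclusions)) {
    for (i in seq_len(nrow(config$exclusions)))
      panel[config$exclusions$id[i], config$exclusions$metabolite[i]] <- NA
  }
  write_panel_csv(panel, out("panel.csv"))
  utils::write.csv(subjects, out("subjects.csv"), row.names = FALSE)

  # -- screen ---------------------------------------------------------
  stage_log("screen", "univariate screen of ", ncol(panel), " metabolites")
  screen <- screen_metabolites(panel, subjects$group)
  utils::write.csv(screen, out("screen.csv"), row.names = FALSE)
  report$n_significant <- sum(screen$significant)

  # -- rf-select ------------------------------------------------------
  stage_log("rf-select", "halving over ", paste(config$ks, collapse = "/"),
            " for ", paste(config$pair, collapse = " vs "))
  cpanel <- panel[!apply(is.na(panel), 1, any), , drop = FALSE]
  csub <- subjects[match(rownames(cpanel), subjects$id), ]
  split <- split_cohort(csub, config$pair, seed = config$seed)
  halving <- halving_evaluate(cpanel, stats::setNames(csub$group, csub$id),
                              split, cv = config$cv, seed = config$seed,
                              ks = config$ks, ntree = config$ntree)
  halving_json <- lapply(halving$by_k, function(e)
    list(k = e$k, features = e$features,
         metrics = e$metrics[c("accuracy", "kappa", "f1", "auroc")]))
  jsonlite::write_json(halving_json, out("halving.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  rep_set <- select_representative_set(halving)
  report$representative_k <- rep_set$k
  report$ranking_top8 <- halving$ranking[seq_len(min(8, length(halving$ranking)))]

  # -- green-window ---------------------------------------------------
  top8 <- report$ranking_top8
  stage_log("green-window", "multinomial fits for ", length(top8),
            " features")
  windows <- green_window_table(cpanel, csub$group, top8)
  utils::write.csv(windows, out("windows.csv"), row.names = FALSE)
  report$green_windows <- windows$feature[windows$exists & windows$acceptable]

  # -- tree -----------------------------------------------------------
  stage_log("tree", "classification tree on the top-8 features")
  pair_rows <- csub$group %in% config$pair
  tree <- fit_classification_tree(cpanel[pair_rows, top8, drop = FALSE],
                                  csub$group[pair_rows])
  jsonlite::write_json(
    list(selected_features = tree$selected_features,
         importance = as.list(tree$importance),
         splits = tree$splits),
    out("tree.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- score ----------------------------------------------------------
  # the score formula is defined on three metabolites: take the tree's
  # importance order, padding from the RF ranking if the tree used fewer
  score_feats <- tree$selected_features
  if (length(score_feats) < 3)
    score_feats <- c(score_feats, setdiff(top8, score_feats))
  score_feats <- score_feats[1:3]
  weights <- assign_weights(score_feats, mode = "balance")
  stage_log("score", "weighted log-product score on ",
            paste(score_feats, collapse = ", "))
  scores <- weighted_log_score(cpanel, weights)
  names(scores) <- rownames(cpanel)
  utils::write.csv(data.frame(id = names(scores), score = scores,
                              group = csub$group, stringsAsFactors = FALSE),
                   out("scores.csv"), row.names = FALSE)
  report$score_features <- score_feats
  report$weights <- as.list(weights)
  report$score_by_group <- lapply(split(scores, csub$group), function(s)
    list(mean = mean(s), sd = stats::sd(s)))

  # -- evaluate -------------------------------------------------------
  is_nash <- csub$group == "NASH"
  cut <- if (config$cutoff_mode == "youden") {
    sc <- select_cutoff(scores, is_nash)
    sc$cutoff
  } else config$cutoff_value
  met <- evaluate_score(scores, is_nash, cut)
  stage_log("evaluate", sprintf("cutoff %.4f accuracy %.3f AUROC %.3f",
                                cut, met$accuracy, met$auroc))
  report$cutoff <- cut
  report$cutoff_metrics <- met[c("accuracy", "kappa", "f1", "auroc",
                                 "sensitivity", "specificity",
                                 "false_negatives")]
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
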