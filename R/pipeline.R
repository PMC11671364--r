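#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations; a single global seed deterministically
#' derives every stage's seed via [derive_seed()].
#'
#' @param cohort a [cohort_config()] (the synthetic cohort to generate), or
#'   `NULL` if matrices/metadata are supplied to [run_pipeline()] directly.
#' @param prep a [preprocess_config()].
#' @param selection a [selection_config()].
#' @param training a [train_config()].
#' @param specificities operating points to calibrate (default 0.95 and 0.99).
#' @param pathway_map_path optional TSV path for enrichment (defaults to the
#'   bundled synthetic map).
#' @param origin_mode `"hierarchical"` or `"ovr-stacked"`.
#' @param seed global seed overriding all stage seeds.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       prep = preprocess_config(),
                       selection = selection_config(),
                       training = train_config(),
                       specificities = c(0.95, 0.99),
                       pathway_map_path = NULL,
                       origin_mode = c("hierarchical", "ovr-stacked"),
                       seed = 1L) {
  origin_mode <- match.arg(origin_mode)
  seed <- as.integer(seed)
  if (!is.null(cohort)) cohort$seed <- derive_seed(seed, "cohort")
  prep$seed <- derive_seed(seed, "preprocess")
  selection$seed <- derive_seed(seed, "select")
  training$seed <- derive_seed(seed, "train")
  structure(list(cohort = cohort, prep = prep, selection = selection,
                 training = training, specificities = specificities,
                 pathway_map_path = pathway_map_path,
                 origin_mode = origin_mode, seed = seed),
            class = "run_config")
}

#' Run the full analysis chain
#'
#' Simulate (or accept) a cohort, preprocess all platforms, select the
#' pan-cancer panel on the discovery cohort, train and calibrate the
#' screening SVM, evaluate on the validation cohort (AUC with bootstrap CI
#' against healthy controls and against all non-cancer, stage-stratified
#' detection rates at each calibrated specificity, age-confounding check),
#' train and evaluate the two-stage origin model, and run pathway
#' over-representation on the pan-cancer panel. All model fitting and
#' calibration uses discovery samples only. Identical config + seed yields an
#' identical metrics object (and byte-identical JSON when written).
#'
#' @param config a [run_config()].
#' @param cohort optional pre-generated cohort (as from [generate_cohort()]);
#'   generated from `config$cohort` when `NULL`.
#' @param out_dir optional directory; when given, writes `metrics.json`,
#'   panels, the detection-rate table and the enrichment table there.
#' @return list with `metrics` (nested list of all headline numbers),
#'   `panels`, `screening` (model + thresholds), `origin` (model), `cohort`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL, out_dir = NULL) {
  if (is.null(cohort)) {
    if (is.null(config$cohort)) stop("run_pipeline: no cohort config and no cohort given")
    cohort <- generate_cohort(config$cohort)
  }
  meta <- cohort$metadata
  if (!"cohort" %in% names(meta) || !any(meta$cohort == "validation")) {
    stop("a validation cohort is required (cohort column with both splits)")
  }

  prep <- preprocess_cohort(cohort$matrices, meta, config$prep)
  X <- prep$X
  disc <- meta$cohort == "discovery"
  valid <- meta$cohort == "validation"
  is_cancer <- meta$group %in% c("LC", "GC", "CRC")

  # --- screening: pan-cancer vs non-cancer, discovery only -----------------
  # factor levels ordered so "cancer" is the modeled (second) level and panel
  # coefficient signs read as cancer-directed
  y_screen <- factor(ifelse(is_cancer, "cancer", "control"),
                     levels = c("control", "cancer"))
  panel <- select_per_platform_and_merge(
    X[disc, , drop = FALSE], prep$platform_of, y_screen[disc],
    config$selection, label = "pan-cancer")
  pf <- panel_features(panel)
  if (!length(pf)) stop("screening panel is empty")
  model <- train_screening_model(X[disc, pf, drop = FALSE], y_screen[disc],
                                 config$training, positive = "cancer")

  disc_scores <- score_samples(model, X[disc, pf, drop = FALSE])
  disc_controls <- disc_scores[y_screen[disc] == "control"]
  calibrated <- lapply(config$specificities, function(sp) {
    calibrated_classifier(model, disc_controls, sp)
  })
  names(calibrated) <- sprintf("spec_%s", sub("0\\.", "", format(config$specificities)))

  val_scores <- score_samples(model, X[valid, pf, drop = FALSE])
  y_val <- y_screen[valid]
  hc_or_cancer <- meta$group[valid] %in% c("LC", "GC", "CRC", "HC")
  auc_hc <- auc_bootstrap_ci(val_scores[hc_or_cancer],
                             y_val[hc_or_cancer] == "cancer",
                             seed = derive_seed(config$seed, "ci_hc"))
  auc_nc <- auc_bootstrap_ci(val_scores, y_val == "cancer",
                             seed = derive_seed(config$seed, "ci_nc"))

  stage_tables <- lapply(calibrated, function(cal) {
    detection_rate_by_stage(cal, X[valid, pf, drop = FALSE],
                            meta[valid, , drop = FALSE])
  })
  age_check <- age_confound_check(val_scores, meta$age[valid])

  # --- origin: two-stage model on discovery cancers ------------------------
  disc_cancer <- disc & is_cancer
  val_cancer <- valid & is_cancer
  origin <- train_origin_model(X[disc_cancer, , drop = FALSE],
                               meta$group[disc_cancer], prep$platform_of,
                               config$selection, config$training,
                               mode = config$origin_mode)
  origin_pred <- predict_origin(origin, X[val_cancer, , drop = FALSE])
  cm <- confusion_matrix(origin_pred$labels, meta$group[val_cancer],
                         classes = origin$classes)
  ovr_auc <- per_class_auc(origin_pred$probabilities, meta$group[val_cancer])

  # --- enrichment of the pan-cancer panel ----------------------------------
  map_path <- config$pathway_map_path %||%
    system.file("extdata", "pathway_map_synthetic.tsv", package = "metaboscreen")
  enrichment <- NULL
  if (nzchar(map_path) && file.exists(map_path)) {
    map <- read_pathway_map(map_path)
    enrichment <- tryCatch(enrich(panel, map, universe = colnames(X)),
                           error = function(e) NULL)
  }

  metrics <- list(
    seed = config$seed,
    n = list(discovery = sum(disc), validation = sum(valid),
             features = ncol(X)),
    screening = list(
      panel_size = length(pf),
      cv_auc = model$cv_auc,
      validation_auc_vs_hc = auc_hc,
      validation_auc_vs_noncancer = auc_nc,
      thresholds = lapply(calibrated, function(cal) {
        list(target = cal$target_specificity,
             threshold = cal$threshold,
             achieved_on_discovery = cal$achieved_specificity)
      }),
      detection_by_stage = lapply(stage_tables, function(tb) {
        stats::setNames(as.list(tb$detection_rate), tb$stage)
      }),
      age_confounding = age_check),
    origin = list(
      panel_a_size = nrow(origin$panel_a$entries),
      panel_b_size = nrow(origin$panel_b$entries),
      accuracy = cm$accuracy,
      recall = as.list(cm$recall),
      per_class_auc = as.list(ovr_auc),
      confusion = as.data.frame.matrix(cm$counts)),
    enrichment = if (!is.null(enrichment)) {
      lapply(seq_len(nrow(enrichment)), function(i) {
        as.list(enrichment[i, c("pathway_id", "k", "K", "p_value", "q_value",
                                "significant")])
      })
    })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_panel(panel, file.path(out_dir, "panel_pan_cancer.tsv"))
    write_panel(origin$panel_a, file.path(out_dir, "panel_lc_vs_nonlc.tsv"))
    write_panel(origin$panel_b, file.path(out_dir, "panel_gc_vs_crc.tsv"))
    utils::write.table(stage_tables[[1]],
                       file.path(out_dir, "detection_by_stage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enrichment)) {
      utils::write.table(as.data.frame(enrichment),
                         file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  list(metrics = metrics, panel = panel, screening = list(
         model = model, calibrated = calibrated),
       origin = origin, cohort = cohort, preprocessing = prep$reports)
}

#' A small demonstration configuration
#'
#' A compact cohort (270 subjects, 78 features over three platforms, strong
#' planted effects) that exercises the full chain in well under five minutes
#' on one CPU; used by the worked example and the determinism checks.
#'
#' @param seed global seed.
#' @return a [run_config()].
#' @export
demo_run_config <- function(seed = 1L) {
  sizes <- c(polar = 30, lipid = 8, GC = 40)
  ids <- platform_feature_ids(sizes)
  planted <- c(
    lapply(ids$polar[1:6], function(f)
      effect_spec(f, c("LC", "GC", "CRC"), 2.5,
                  stage_multipliers = c(I = 1, II = 1, III = 1, IV = 1, unknown = 1))),
    lapply(ids$GC[1:4], function(f) effect_spec(f, "LC", 3.0,
                  stage_multipliers = c(I = 1, II = 1, III = 1, IV = 1, unknown = 1))),
    lapply(ids$GC[5:8], function(f) effect_spec(f, "GC", 3.0,
                  stage_multipliers = c(I = 1, II = 1, III = 1, IV = 1, unknown = 1)))
  )
  run_config(
    cohort = cohort_config(
      n_per_group = c(LC = 70, GC = 45, CRC = 45, NCD = 60, HC = 50),
      platform_sizes = sizes, planted = planted,
      n_batches = 2, qc_per_batch = 3, split_ratio = 0.7),
    selection = selection_config(n_rounds = 25L),
    training = train_config(cv_repeats = 2L, cost = c(0.1, 1, 10)),
    seed = seed)
}
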