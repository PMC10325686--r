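#' Process one case: segmentation, sectorization, labeling, patches
#'
#' Runs the per-patient imaging stages: myocardium segmentation on every
#' early-phase slice (automatic, or taking the ground-truth mask when
#' `segmentation = "oracle"`), basal/mid/apical section assignment with the
#' basal ring-completeness rule and apical-cap exclusion, AHA
#' sectorization, three-way labeling from the late-phase scar mask, and
#' patch extraction for the retained (scar / no-scar) sectors.
#'
#' @param case A `phantom_case` (or any object with the same fields).
#' @param labeling_cfg A [labeling_config()].
#' @param reference_angle Sector-1 start angle, radians.
#' @param segmentation `"auto"` (region-growing segmentation) or `"oracle"`
#'   (use `case$myo_mask`).
#' @param mapping Early-to-late slice mapping; defaults to the identity
#'   (phantom early/late stacks share the grid).
#' @return List: `labels` (data frame with patient_id, slice_index, section,
#'   aha_segment, scar_fraction, label), `patches` (list, one 85 x 85
#'   matrix per retained sector, aligned with `meta`), `meta` (data frame
#'   for retained sectors with binary label), `counts`.
#' @export
process_case <- function(case, labeling_cfg = labeling_config(),
                         reference_angle = 0,
                         segmentation = c("auto", "oracle"),
                         mapping = NULL) {
  segmentation <- match.arg(segmentation)
  n <- dim(case$early$data)[1]
  slice_ids <- (case$base_index:case$apex_index) - 1L  # 0-based
  if (is.null(mapping)) mapping <- identity_mapping(n)

  masks <- list()
  for (s0 in slice_ids) {
    img <- case$early$data[s0 + 1L, , ]
    masks[[as.character(s0)]] <- if (segmentation == "oracle")
      accept_external_mask(case$myo_mask[s0 + 1L, , ], slice_index = s0)
    else segment_myocardium(img, slice_index = s0)
  }

  assignments <- assign_sections(slice_ids)
  # basal inclusion rule: the myocardium must fully surround the LV
  for (i in which(assignments$section == "basal")) {
    if (!basal_ring_complete(masks[[as.character(assignments$slice_index[i])]]))
      assignments$section[i] <- "excluded"
  }
  assignments <- exclude_apical_cap(assignments, masks)

  labels <- list()
  patches <- list()
  meta <- list()
  for (i in which(assignments$section != "excluded")) {
    s0 <- assignments$slice_index[i]
    sec <- assignments$section[i]
    m <- masks[[as.character(s0)]]
    sectors <- sectorize_slice(m, sec, reference_angle, slice_index = s0)
    lab <- label_volume(sectors, case$scar_mask, mapping, labeling_cfg)
    lab$patient_id <- case$patient_id
    labels[[length(labels) + 1L]] <- lab
    masked <- apply_mask(case$early$data[s0 + 1L, , ], m)
    for (j in seq_along(sectors)) {
      if (lab$label[j] == "excluded") next
      patches[[length(patches) + 1L]] <-
        preprocess_sector(masked, sectors[[j]]$mask)
      meta[[length(meta) + 1L]] <- data.frame(
        patient_id = case$patient_id, slice_index = s0,
        aha_segment = lab$aha_segment[j],
        label = as.integer(lab$label[j] == "scar"),
        stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, labels)
  counts <- c(total = nrow(labels),
              scar = sum(labels$label == "scar"),
              no_scar = sum(labels$label == "no_scar"),
              excluded = sum(labels$label == "excluded"))
  list(labels = labels, patches = patches,
       meta = if (length(meta)) do.call(rbind, meta) else NULL,
       counts = counts)
}

run_config_defaults <- function() {
  list(
    n_patients = 20L,
    scar_prevalence = 0.5,
    phantom = list(),          # overrides for phantom_config()
    labeling = list(),         # overrides for labeling_config()
    reference_angle = 0,
    segmentation = "auto",
    k_folds = 5L,
    arch = list(),             # overrides for arch_config()
    train = list(),            # overrides for train_config()
    augment = FALSE,           # FALSE, TRUE (defaults) or override list
    seed = 1L,
    out_dir = NULL
  )
}

apply_overrides <- function(ctor, overrides, what) {
  known <- names(formals(ctor))
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown ", what, " config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(ctor, overrides)
}

#' Validate and resolve a run configuration
#'
#' Accepts a YAML/JSON file path or a plain list; unknown keys anywhere are
#' rejected by name, defaults are filled in, and nested configs are
#' validated by their constructors.
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @return A fully resolved `run_config` list with elements `phantom_cfg`,
#'   `labeling_cfg`, `arch`, `train`, `augment_cfg` alongside the scalar
#'   settings.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- run_config_defaults()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$segmentation %in% c("auto", "oracle"))
    stop("segmentation must be 'auto' or 'oracle'", call. = FALSE)
  if (cfg$n_patients < cfg$k_folds)
    stop("need at least k_folds patients", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$phantom_cfg <- apply_overrides(phantom_config,
                                     as.list(cfg$phantom), "phantom")
  cfg$labeling_cfg <- apply_overrides(labeling_config,
                                      as.list(cfg$labeling), "labeling")
  cfg$arch_cfg <- apply_overrides(arch_config, as.list(cfg$arch), "arch")
  cfg$train_cfg <- apply_overrides(train_config, as.list(cfg$train), "train")
  cfg$augment_cfg <- if (isTRUE(cfg$augment)) augment_config()
    else if (is.list(cfg$augment))
      apply_overrides(augment_config, cfg$augment, "augment")
    else NULL
  class(cfg) <- "run_config"
  cfg
}

# Stage seeds fan out from the global seed via a fixed counter scheme.
stage_seed <- function(seed, stage) {
  (as.integer(seed) + 104729L * stage) %% 2147483647L
}

#' Run the full experiment
#'
#' Phantom cohort generation, per-case segmentation / sectorization /
#' labeling / patch extraction, patient-wise k-fold cross-validated
#' training, and evaluation, all driven by one resolved configuration.
#' Rerunning with the same config reproduces the manifest counts exactly.
#'
#' @param config A `run_config` from [validate_config()] (or a list/path,
#'   validated on the fly).
#' @param verbose Print stage progress.
#' @return List with `report` (a `metrics_report`), `manifest`, and
#'   `labels` (the pooled sector label table).
#' @export
run_experiment <- function(config = list(), verbose = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  log_stage <- function(stage, msg) {
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }

  log_stage("phantom", sprintf("generating %d cases (scar prevalence %.2f)",
                               config$n_patients, config$scar_prevalence))
  cohort <- tryCatch(
    generate_cohort(config$n_patients, config$phantom_cfg,
                    config$scar_prevalence,
                    seed = stage_seed(config$seed, 1L)),
    error = function(e) stop("stage phantom: ", conditionMessage(e),
                             call. = FALSE))

  all_labels <- list()
  all_patches <- list()
  all_meta <- list()
  for (case in cohort) {
    log_stage("segment+label", case$patient_id)
    pc <- tryCatch(
      process_case(case, config$labeling_cfg, config$reference_angle,
                   config$segmentation),
      error = function(e) stop("stage segment/label (patient ",
                               case$patient_id, "): ", conditionMessage(e),
                               call. = FALSE))
    all_labels[[case$patient_id]] <- pc$labels
    all_patches <- c(all_patches, pc$patches)
    all_meta[[case$patient_id]] <- pc$meta
  }
  labels <- do.call(rbind, all_labels)
  meta <- do.call(rbind, all_meta)
  rownames(labels) <- rownames(meta) <- NULL
  counts <- c(total = nrow(labels),
              scar = sum(labels$label == "scar"),
              no_scar = sum(labels$label == "no_scar"),
              excluded = sum(labels$label == "excluded"))

  log_stage("folds", sprintf("%d-fold patient-wise split", config$k_folds))
  folds <- make_folds(vapply(cohort, `[[`, "", "patient_id"),
                      k = config$k_folds,
                      seed = stage_seed(config$seed, 2L))

  tc <- config$train_cfg
  tc$seed <- stage_seed(config$seed, 3L)
  log_stage("train", sprintf("%d retained samples, %d scar",
                             nrow(meta), sum(meta$label == 1L)))
  report <- tryCatch(
    run_cross_validation(list(patches = all_patches, meta = meta), folds,
                         config$arch_cfg, tc,
                         augment_cfg = config$augment_cfg,
                         verbose = verbose),
    error = function(e) stop("stage train/evaluate: ", conditionMessage(e),
                             call. = FALSE))

  manifest <- list(
    package_version = as.character(utils::packageVersion("scarCCT")),
    seed = config$seed,
    stage_seeds = list(phantom = stage_seed(config$seed, 1L),
                       folds = stage_seed(config$seed, 2L),
                       train = stage_seed(config$seed, 3L)),
    n_patients = config$n_patients,
    scar_prevalence = config$scar_prevalence,
    scar_fraction_threshold = config$labeling_cfg$scar_fraction_threshold,
    segmentation = config$segmentation,
    k_folds = config$k_folds,
    counts = as.list(counts),
    fold_of_patient = as.list(folds$fold_of_patient),
    excluded_dropped_from = "training and testing"
  )
  stopifnot(counts["total"] ==
              counts["scar"] + counts["no_scar"] + counts["excluded"])

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(labels, file.path(config$out_dir, "labels.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(
      list(per_fold = report$per_fold,
           summary = lapply(report$summary, function(s)
             s[c("mean", "ci_low", "ci_high")]),
           overall_agreement = report$agreement$overall_agreement),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    utils::write.csv(report$agreement$per_segment,
                     file.path(config$out_dir, "segment_agreement.csv"),
                     row.names = FALSE)
  }

  list(report = report, manifest = manifest, labels = labels)
}
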