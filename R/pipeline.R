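pipeline_defaults <- function() {
  list(
    out_dir = NULL,
    manifest = NULL,        # path to an existing cohort manifest, or NULL
    n_per_class = 9L,       # synthetic cohort size per class
    base_seed = 1L,
    image_size = 512L,
    n_bands = 16L,
    kernel = 3L,            # mean-filter size
    work_size = 64L,        # active-contour working resolution
    max_iter = 200L,
    segment = TRUE,         # FALSE: use truth masks for feature extraction
    Ng = 32L,
    group = "G5",
    alpha = 0.01,
    variance_target = 0.97,
    max_components = NULL,
    refit = TRUE,
    classifiers = c("DT", "NB", "NN")
  )
}

read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  unknown <- setdiff(names(config), names(pipeline_defaults()))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(pipeline_defaults(), config)
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full texture-classification pipeline
#'
#' Orchestrates synthesize (or load) -> segment -> equalize -> 3D GLCM ->
#' Haralick features -> ANOVA/PCA selection -> LOOCV classification, writing
#' every intermediate artifact into `out_dir`: the cohort and its manifest,
#' predicted masks with overlap scores, the feature CSV, the per-class
#' feature summary, a selection report and one JSON report per classifier.
#' Runs are exactly repeatable: all randomness derives from `base_seed`, and
#' the resolved config is echoed to `config.json`.
#'
#' @param config A named list overriding the defaults (see
#'   `celltex3d:::pipeline_defaults()`), or a path to a YAML/JSON file with
#'   the same fields. `out_dir` is required.
#' @return Invisibly, a list with the manifest, segmentation scores, feature
#'   matrix, selection summary and one `classifier_report` per classifier.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_config(config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(cfg$out_dir, "log.txt"), open = "a")
  on.exit(close(logf))
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  if (is.null(cfg$manifest)) {
    log_line(logf, "generating ", 3 * cfg$n_per_class,
             "-sample synthetic cohort (seed ", cfg$base_seed, ")")
    cohort <- generate_cohort(cfg$n_per_class, cfg$base_seed,
                              image_size = cfg$image_size,
                              n_bands = cfg$n_bands)
    manifest <- write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
    manifest <- read_manifest(file.path(cfg$out_dir, "cohort",
                                        "manifest.csv"))
  } else {
    log_line(logf, "loading cohort from ", cfg$manifest)
    manifest <- read_manifest(cfg$manifest)
    cohort <- lapply(seq_len(nrow(manifest)), function(k) {
      structure(list(volume = load_volume(manifest$path_volume[k]),
                     truth_mask = load_mask(manifest$path_mask[k]),
                     label = manifest$label[k]),
                class = "labeled_sample")
    })
    names(cohort) <- manifest$sample_id
  }
  labels <- manifest$label

  if (isTRUE(cfg$segment)) {
    log_line(logf, "segmenting ", length(cohort), " volumes (work size ",
             cfg$work_size, ", max ", cfg$max_iter, " iterations)")
    seg <- segment_cohort(cohort, work_size = cfg$work_size,
                          max_iter = cfg$max_iter, kernel = cfg$kernel)
    write.csv(seg$scores, file.path(cfg$out_dir, "seg_scores.csv"),
              row.names = FALSE)
    mask_dir <- file.path(cfg$out_dir, "masks_pred")
    dir.create(mask_dir, showWarnings = FALSE)
    for (k in seq_along(seg$masks)) {
      save_mask(seg$masks[[k]],
                file.path(mask_dir, paste0(names(cohort)[k], ".png")))
    }
    masks <- seg$masks
    log_line(logf, sprintf("mean JSC %.3f DSC %.3f", seg$summary["jsc"],
                           seg$summary["dsc"]))
  } else {
    seg <- NULL
    masks <- lapply(cohort, `[[`, "truth_mask")
  }

  log_line(logf, "equalizing to ", cfg$Ng, " levels and extracting ",
           cfg$group, " features")
  samples <- lapply(seq_along(cohort), function(k) {
    list(quant = equalize_to_levels(cohort[[k]]$volume, masks[[k]],
                                    Ng = cfg$Ng),
         mask = masks[[k]])
  })
  names(samples) <- names(cohort)
  features <- assemble_group(samples, group = cfg$group, Ng = cfg$Ng)
  write.csv(data.frame(sample_id = rownames(features), label = labels,
                       features, check.names = FALSE),
            file.path(cfg$out_dir, "features.csv"), row.names = FALSE)
  write.csv(mean_feature_table(features, labels),
            file.path(cfg$out_dir, "feature_summary.csv"),
            row.names = FALSE)

  log_line(logf, "selection snapshot on the full cohort (alpha ",
           cfg$alpha, ", variance target ", cfg$variance_target, ")")
  z <- suppressWarnings(zscore(features))
  sel <- anova_select(z, labels, alpha = cfg$alpha)
  pca <- pca_reduce(z[, sel$selected, drop = FALSE],
                    variance_target = cfg$variance_target,
                    max_components = cfg$max_components)
  jsonlite::write_json(
    list(n_features = ncol(features), n_selected = length(sel$selected),
         n_components = pca$k,
         cumvar = unname(pca$cumvar[seq_len(pca$k)]),
         pvalues = as.list(sel$pvalues[sel$selected])),
    file.path(cfg$out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)

  reports <- list()
  for (clf in cfg$classifiers) {
    log_line(logf, "LOOCV with ", clf,
             if (cfg$refit) " (selection refit per fold)" else "")
    rep <- loocv_run(features, labels, classifier = clf, alpha = cfg$alpha,
                     variance_target = cfg$variance_target,
                     max_components = cfg$max_components, refit = cfg$refit)
    reports[[clf]] <- rep
    jsonlite::write_json(
      list(classifier = clf, accuracy = rep$accuracy,
           accuracy_pct = rep$accuracy_pct,
           confusion = as.data.frame(rep$confusion),
           per_class = rep$per_class, auc = as.list(rep$auc)),
      file.path(cfg$out_dir, paste0("report_", clf, ".json")),
      auto_unbox = TRUE, digits = NA)
    log_line(logf, sprintf("%s accuracy %.2f%%", clf, rep$accuracy_pct))
  }

  invisible(list(manifest = manifest, segmentation = seg,
                 features = features, labels = labels,
                 selection = list(anova = sel, pca = pca),
                 reports = reports, config = cfg))
}
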