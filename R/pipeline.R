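# End-to-end orchestration: rescaling -> brainstem extraction -> first-pass
# clustering -> group priors -> probabilistic refinement -> quality report,
# plus the channel-combination experiment and Dice utilities.

.COMBO_CHANNELS <- list(
  all3 = c("uni", "t1map", "ratio"),
  uni = "uni", ratio = "ratio", t1map = "t1map",
  "uni+t1map" = c("uni", "t1map"),
  "ratio+t1map" = c("ratio", "t1map")
)

#' Run the segmentation pipeline on a cohort
#'
#' Rescales every subject's UNI/T1 map, builds the RATIO image, extracts the
#' brainstem channels on a common bounding box, clusters the z-scored stack
#' (k = 6), harmonizes labels to the reference subject, builds the
#' probabilistic group priors by iterative diffeomorphic template
#' construction, projects them back, refines each subject's labels, and
#' scores segmentation quality.
#'
#' @param cohort List of `phantom_subject`-like objects (fields `uni`,
#'   `t1map`, `tissue_probs`, `brainstem_mask`, `spacing`, `id`).
#' @param channels Channel combination for clustering (subset of
#'   `c("uni", "t1map", "ratio")`).
#' @param k Number of clusters.
#' @param replicates,max_iter k-means restarts and iteration cap.
#' @param reference Index of the reference subject for label harmonization.
#' @param rescale_pars [rescale_params()].
#' @param prior_pars [priors_params()].
#' @param p_high,p_margin Refinement thresholds.
#' @param mask_threshold Brainstem tissue-mask intensity threshold.
#' @param seed Global seed; per-subject k-means seeds are derived from it.
#' @param compute_quality Compute per-subject quality reports (silhouettes
#'   are the slow part).
#' @param compute_silhouettes Include the silhouette pass in the quality
#'   reports.
#' @param max_sil_n Silhouette subsample cap.
#' @return Object of class `pipeline_result` with per-subject `stacks`,
#'   `models` (matched), `segmentations`, `quality`, plus `prior_set`,
#'   `box`, `channels`, `seed`.
#' @export
segment_cohort <- function(cohort,
                           channels = c("uni", "t1map", "ratio"),
                           k = 6L, replicates = 10L, max_iter = 1000L,
                           reference = 1L,
                           rescale_pars = rescale_params(),
                           prior_pars = priors_params(),
                           p_high = 0.75, p_margin = 0.20,
                           mask_threshold = 10,
                           seed = 1L, compute_quality = TRUE,
                           compute_silhouettes = TRUE,
                           max_sil_n = 20000L) {
  stopifnot(length(cohort) >= 2, all(channels %in% c("uni", "t1map", "ratio")))
  cal <- lapply(cohort, function(sub) {
    rescale_subject(sub$uni, sub$t1map, sub$tissue_probs, rescale_pars)
  })
  # common bounding box across subjects
  boxes <- lapply(cohort, function(sub) bounding_box(sub$brainstem_mask,
                                                     pad = 2L))
  box <- list(lo = do.call(pmin, lapply(boxes, `[[`, "lo")),
              hi = do.call(pmax, lapply(boxes, `[[`, "hi")))

  stacks <- vector("list", length(cohort))
  models <- vector("list", length(cohort))
  for (s in seq_along(cohort)) {
    bs <- extract_brainstem(cal[[s]]$uni_cal, cal[[s]]$t1map_cal,
                            cal[[s]]$ratio, cohort[[s]]$brainstem_mask,
                            box = box)
    mask <- make_tissue_mask(bs$uni, bs$label, threshold = mask_threshold,
                             min_voxels = 50L * k)
    chans <- list(uni = bs$uni, t1map = bs$t1map, ratio = bs$ratio)[channels]
    stacks[[s]] <- channel_stack(chans, mask)
    models[[s]] <- kmeans_firstpass(stacks[[s]], k = k, max_iter = max_iter,
                                    replicates = replicates,
                                    seed = seed + 1000L * s)
  }
  models <- lapply(models, match_centroids, reference = models[[reference]])
  maps <- lapply(models, labels_to_binary_maps)
  prior_set <- build_group_template(maps, prior_pars,
                                    spacing = cohort[[1]]$spacing)
  segmentations <- vector("list", length(cohort))
  quality <- vector("list", length(cohort))
  combo_name <- paste(channels, collapse = "+")
  if (identical(sort(channels), sort(c("uni", "t1map", "ratio"))))
    combo_name <- "all3"
  for (s in seq_along(cohort)) {
    pri <- warp_priors_to_subject(prior_set, s)
    segmentations[[s]] <- refine_segmentation(models[[s]], stacks[[s]], pri,
                                              p_high, p_margin)
    if (compute_quality)
      quality[[s]] <- quality_report(models[[s]], stacks[[s]], pri,
                                     input_combo = combo_name,
                                     max_sil_n = max_sil_n,
                                     compute_silhouettes = compute_silhouettes)
  }
  structure(list(stacks = stacks, models = models,
                 segmentations = segmentations, quality = quality,
                 prior_set = prior_set, calibrated = cal, box = box,
                 channels = channels, combo = combo_name, seed = seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$models), "subjects, channels",
      x$combo, "\n")
  if (!is.null(x$quality[[1]])) {
    mci <- vapply(x$quality, `[[`, 0, "missclassification_index")
    cat(sprintf("  mean miss-classification index: %.2f%%\n", mean(mci)))
  }
  invisible(x)
}

#' Per-class Dice between a segmentation and ground truth
#'
#' Cluster numbering is arbitrary, so by default the label permutation
#' maximizing the total Dice is found exhaustively (k <= 8) and applied
#' before scoring.
#'
#' @param labels Integer label volume (may be cropped; see `box`).
#' @param truth Ground-truth label volume on the full grid.
#' @param k Number of classes.
#' @param box Optional bounding box to crop `truth` to the grid of `labels`.
#' @param match Find the best label permutation first?
#' @return List with `dice` (per truth class), `permutation`.
#' @export
dice_scores <- function(labels, truth, k = 6L, box = NULL, match = TRUE) {
  if (!is.null(box)) truth <- crop_to_box(truth, box)
  stopifnot(identical(dim(labels), dim(truth)))
  counts <- function(perm) {
    vapply(seq_len(k), function(c) {
      a <- labels == perm[c]; b <- truth == c
      s <- sum(a) + sum(b)
      if (s == 0) return(NA_real_)
      2 * sum(a & b) / s
    }, 0)
  }
  perm <- seq_len(k)
  if (match && k <= 8L) {
    # overlap matrix: rows = predicted label, cols = truth class
    ov <- matrix(0, k, k)
    na <- tabulate(labels[labels > 0], k)
    nb <- tabulate(truth[truth > 0], k)
    both <- labels > 0 & truth > 0
    tab <- table(factor(labels[both], levels = 1:k),
                 factor(truth[both], levels = 1:k))
    for (i in 1:k) for (j in 1:k)
      ov[i, j] <- 2 * tab[i, j] / max(na[i] + nb[j], 1)
    perms <- all_permutations(k)
    tot <- apply(perms, 1, function(p) sum(ov[cbind(p, seq_len(k))]))
    perm <- perms[which.max(tot), ]
  }
  list(dice = counts(perm), permutation = perm)
}

#' Channel-combination experiment
#'
#' Reruns clustering, prior generation and evaluation for each channel
#' combination and tabulates the quality indices, with paired comparisons of
#' each combination against the all-three-channel run.
#'
#' @param cohort Subject list as for [segment_cohort()].
#' @param combos Combination names among `names(bstemseg:::.COMBO_CHANNELS)`.
#' @param ... Passed to [segment_cohort()].
#' @return Object of class `combo_experiment`: `table` (one row per combo:
#'   mean/sd of the three indices), `per_subject` (long data frame),
#'   `tests` (paired comparisons vs all3), `results` (named list of
#'   [segment_cohort()] outputs).
#' @export
run_input_combo_experiment <- function(cohort,
                                       combos = c("all3", "uni", "ratio",
                                                  "t1map", "uni+t1map",
                                                  "ratio+t1map"),
                                       ...) {
  stopifnot(all(combos %in% names(.COMBO_CHANNELS)))
  results <- lapply(combos, function(cb) {
    segment_cohort(cohort, channels = .COMBO_CHANNELS[[cb]], ...)
  })
  names(results) <- combos
  per_subject <- do.call(rbind, lapply(combos, function(cb) {
    q <- results[[cb]]$quality
    data.frame(combo = cb, subject = seq_along(q),
               low_silhouette = vapply(q, `[[`, 0, "low_silhouette_index"),
               missclassification = vapply(q, `[[`, 0,
                                           "missclassification_index"),
               std_distance = vapply(q, `[[`, 0, "missclass_std_distance"))
  }))
  tab <- do.call(rbind, lapply(combos, function(cb) {
    d <- per_subject[per_subject$combo == cb, ]
    data.frame(combo = cb,
               low_silhouette = mean(d$low_silhouette),
               low_silhouette_sd = stats::sd(d$low_silhouette),
               missclassification = mean(d$missclassification),
               missclassification_sd = stats::sd(d$missclassification),
               std_distance = mean(d$std_distance, na.rm = TRUE))
  }))
  tests <- NULL
  if ("all3" %in% combos && length(combos) > 1 &&
      length(results[[1]]$models) >= 3) {
    ref <- per_subject[per_subject$combo == "all3", "missclassification"]
    tests <- do.call(rbind, lapply(setdiff(combos, "all3"), function(cb) {
      other <- per_subject[per_subject$combo == cb, "missclassification"]
      gc <- tryCatch(group_compare(ref, other, paired = TRUE),
                     error = function(e) list(statistic = NA, p = NA,
                                              test = conditionMessage(e)))
      data.frame(combo = cb, mean_diff = mean(ref - other),
                 statistic = gc$statistic, p = gc$p, test = gc$test)
    }))
  }
  structure(list(table = tab, per_subject = per_subject, tests = tests,
                 results = results),
            class = "combo_experiment")
}

#' @export
print.combo_experiment <- function(x, ...) {
  cat("combo_experiment over", length(unique(x$per_subject$subject)),
      "subjects:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# ---- configured runs --------------------------------------------------

#' Default pipeline configuration
#' @return Nested list mirroring the config file sections.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    phantom = list(n_subjects = 4L, grid_shape = c(48L, 56L, 40L),
                   voxel_size_mm = 1, noise_sd = c(uni = 60, t1map = 80),
                   bias_amplitude = 0.05, subject_jitter = 1.5),
    rescale = list(ref1 = 100, ref2 = 20, tissue_prob_threshold = 0.9,
                   vessel_low_pct = 1, vessel_high_pct = 95,
                   ratio_cap_pct = 99),
    extract = list(mask_threshold = 10),
    cluster = list(k = 6L, replicates = 10L, max_iter = 1000L,
                   reference = 1L),
    priors = list(n_reg_iter = 12L, sigma_update = 1.0,
                  sigma_velocity = 1.2, force_k = 1.0, n_outer = 3L),
    refine = list(p_high = 0.75, p_margin = 0.20),
    evaluate = list(max_sil_n = 20000L),
    output_dir = NULL
  )
}

#' @keywords internal
.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with any subset of the [default_config()] sections.
#' @return Full configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  .merge_config(default_config(), yaml::read_yaml(path))
}

#' Run the configured pipeline end to end
#'
#' Generates (or accepts) a cohort, runs [segment_cohort()] with the
#' configured parameters, and writes a deterministic JSON quality report
#' plus a manifest when `output_dir` is set. Rerunning with an unchanged
#' configuration reuses the existing report (the manifest stores the full
#' configuration; a byte-identical manifest short-circuits the run).
#'
#' @param config Configuration list ([default_config()] shape) or a YAML
#'   path.
#' @param cohort Optional pre-generated cohort; default: a phantom cohort
#'   from the `phantom` section.
#' @return List with `result` (a [segment_cohort()] output or `NULL` when
#'   resumed), `report` (the report list), `resumed`.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL) {
  if (is.character(config)) config <- load_config(config)
  config <- .merge_config(default_config(), config)
  cfg_json <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                            digits = NA, pretty = TRUE))
  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    manifest <- file.path(out_dir, "manifest.json")
    report_path <- file.path(out_dir, "report.json")
    if (file.exists(manifest) && file.exists(report_path) &&
        identical(paste(readLines(manifest, warn = FALSE), collapse = "\n"),
                  as.character(cfg_json))) {
      return(list(result = NULL,
                  report = jsonlite::read_json(report_path,
                                               simplifyVector = TRUE),
                  resumed = TRUE))
    }
  }
  if (is.null(cohort)) {
    ph <- config$phantom
    spec <- phantom_spec(grid_shape = ph$grid_shape,
                         voxel_size_mm = ph$voxel_size_mm,
                         noise_sd = unlist(ph$noise_sd),
                         bias_amplitude = ph$bias_amplitude,
                         subject_jitter = ph$subject_jitter,
                         seed = config$seed)
    cohort <- generate_cohort(spec, ph$n_subjects)
  }
  rp <- do.call(rescale_params, config$rescale)
  pp <- do.call(priors_params, config$priors)
  res <- segment_cohort(cohort,
                        k = config$cluster$k,
                        replicates = config$cluster$replicates,
                        max_iter = config$cluster$max_iter,
                        reference = config$cluster$reference,
                        rescale_pars = rp, prior_pars = pp,
                        p_high = config$refine$p_high,
                        p_margin = config$refine$p_margin,
                        mask_threshold = config$extract$mask_threshold,
                        seed = config$seed,
                        max_sil_n = config$evaluate$max_sil_n)
  report <- pipeline_report(res, cohort)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(cfg_json, file.path(out_dir, "manifest.json"))
    for (s in seq_along(cohort)) {
      base <- file.path(out_dir, cohort[[s]]$id)
      lab <- array(0L, dim(cohort[[s]]$uni))
      lab_cropped <- res$segmentations[[s]]$final_labels
      lab[res$box$lo[1]:res$box$hi[1], res$box$lo[2]:res$box$hi[2],
          res$box$lo[3]:res$box$hi[3]] <- lab_cropped
      RNifti::writeNifti(RNifti::asNifti(
        lab, pixdim = rep(cohort[[s]]$spacing, 3)),
        paste0(base, "_final-labels.nii.gz"))
    }
  }
  list(result = res, report = report, resumed = FALSE)
}

#' @keywords internal
pipeline_report <- function(res, cohort) {
  list(
    seed = res$seed,
    channels = res$combo,
    n_subjects = length(res$models),
    scale_factors = lapply(res$calibrated, function(cc) list(
      uni = list(fact = cc$factors$uni$fact, shift = cc$factors$uni$shift,
                 wm_mode = cc$factors$uni$wm_mode,
                 csf_mode = cc$factors$uni$csf_mode),
      t1map = list(fact = cc$factors$t1map$fact,
                   shift = cc$factors$t1map$shift,
                   wm_mode = cc$factors$t1map$wm_mode,
                   csf_mode = cc$factors$t1map$csf_mode))),
    quality = lapply(res$quality, function(q) if (is.null(q)) NULL else list(
      low_silhouette_index = q$low_silhouette_index,
      missclassification_index = q$missclassification_index,
      missclass_std_distance = q$missclass_std_distance)),
    n_reassigned = vapply(res$segmentations, `[[`, 0L, "n_reassigned"),
    template_metrics = res$prior_set$metrics
  )
}
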