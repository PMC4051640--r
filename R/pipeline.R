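# End-to-end orchestration on the phantom: simulate -> preprocess -> map
# (GLM / seed-based / ICA) -> AMPLE threshold -> overlap, CoM and ECS
# concordance -> report files. One run is one synthetic "case"; stage
# failures mark the affected method unavailable ('-' semantics) and the run
# continues.

#' Pipeline configuration
#'
#' @param spec a [phantom_spec()]; its seed drives every simulation stage.
#' @param task motor task to analyse ("hand", "foot" or "mouth"). The
#'   phantom lesion sits in the right hemisphere, so the diseased hemisoma
#'   is the left one: the task side of interest is left (right-hemisphere
#'   motor cortex) and seed ROIs are defined on the healthy left hemisphere
#'   from the right-sided blocks.
#' @param methods resting-state methods to run, subset of
#'   `c("aROI", "fROI", "ICA")`.
#' @param threshold_policy "ample" or a fixed numeric threshold.
#' @param eval_dilation_gyri,eval_dilation_paracentral dilation iterations
#'   for the evaluation masks (defaults 2 and 6 voxels as in the study).
#' @param preprocess a [preprocess_config()].
#' @param ica_components,ica_z_thr spatial ICA settings.
#' @param ecs NULL, or `list(n =, offset_mm =)` to place synthetic
#'   stimulation sites near the task activation surface.
#' @param include_self_check also score the task map against itself (must
#'   give alpha = beta = 1 and zero CoM distance).
#' @param out_dir optional output directory for NIfTI/TSV/JSON reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spec = phantom_spec(), task = "hand",
                            methods = c("aROI", "fROI", "ICA"),
                            threshold_policy = "ample",
                            eval_dilation_gyri = 2L,
                            eval_dilation_paracentral = 6L,
                            preprocess = preprocess_config(),
                            ica_components = 20L, ica_z_thr = 2,
                            ecs = list(n = 8L, offset_mm = 5),
                            include_self_check = FALSE, out_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"),
            task %in% c("hand", "foot", "mouth"),
            all(methods %in% c("aROI", "fROI", "ICA")), length(methods) > 0)
  structure(list(spec = spec, task = task, methods = methods,
                 threshold_policy = threshold_policy,
                 eval_dilation_gyri = as.integer(eval_dilation_gyri),
                 eval_dilation_paracentral =
                   as.integer(eval_dilation_paracentral),
                 preprocess = preprocess,
                 ica_components = as.integer(ica_components),
                 ica_z_thr = ica_z_thr, ecs = ecs,
                 include_self_check = isTRUE(include_self_check),
                 out_dir = out_dir),
            class = "pipeline_config")
}

union_mask <- function(masks, label) {
  v <- Reduce(`|`, lapply(masks, `[[`, "values"))
  roi_mask(v, masks[[1]]$affine, label)
}

#' Run the full phantom pipeline for one case
#'
#' @param config a [pipeline_config()].
#' @return A `case_record`: list with the statistical maps, thresholded
#'   maps, `overlap` / `com` / `dice` / `ecs` data.frames, the white-matter
#'   tSNR, the planted ground truth, and a `notes` character log. If
#'   `config$out_dir` is set, TSV and JSON reports (and the maps as NIfTI)
#'   are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$spec
  task <- config$task
  notes <- character(0)
  note <- function(...) notes <<- c(notes, sprintf(...))

  truth <- make_phantom(spec)
  design <- block_design(task = task, tr = 3.0)
  task_bold <- simulate_task_bold(spec, design, truth)
  rest_bold <- simulate_rest_bold(spec, truth)
  tsnr <- temporal_snr(rest_bold, truth$white_matter)

  gyri_bilateral <- union_mask(list(truth$precentral_R, truth$precentral_L,
                                    truth$postcentral_R, truth$postcentral_L),
                               "motor_gyri_bilateral")
  gyri_R <- union_mask(list(truth$precentral_R, truth$postcentral_R),
                       "motor_gyri_R")
  gyri_L <- union_mask(list(truth$precentral_L, truth$postcentral_L),
                       "motor_gyri_L")
  para_bilateral <- union_mask(list(truth$paracentral_R, truth$paracentral_L),
                               "paracentral_bilateral")
  if (task == "foot") {
    anat_mask <- para_bilateral
    eval_mask <- dilate_mask(para_bilateral,
                             config$eval_dilation_paracentral)
    ample_mask <- truth$paracentral_R          # ipsilateral to the lesion
  } else {
    anat_mask <- gyri_bilateral
    eval_mask <- dilate_mask(gyri_bilateral, config$eval_dilation_gyri)
    ample_mask <- gyri_R
  }

  # task-based map: smooth, then GLM on the affected (left) side regressor
  task_sm <- gaussian_smooth(task_bold, config$preprocess$fwhm_mm)
  maps <- list()
  maps$tb <- glm_tmap(task_sm, build_task_regressor(design, "left"),
                      provenance = "tb")

  # resting-state chain
  rest_pre <- preprocess_rest(rest_bold, truth$brain, config$preprocess)

  run_method <- function(m) {
    switch(m,
      aROI = {
        seed_roi <- switch(task,
          hand = build_hand_aroi(truth$precentral_L, truth$knob_centre$L),
          foot = build_foot_aroi(truth$paracentral_L),
          mouth = build_mouth_aroi(truth$precentral_L,
                                   spec$regions$mouth_strip_z[1],
                                   truth$knob_centre$L[3] -
                                     spec$regions$hand_knob_L$radius))
        sba_tmap(rest_pre, seed_timecourse(rest_pre, seed_roi),
                 provenance = "aROI")
      },
      fROI = {
        healthy_map <- glm_tmap(task_sm, build_task_regressor(design, "right"),
                                provenance = "tb")
        search <- if (task == "foot") truth$paracentral_L else gyri_L
        froi <- build_froi(healthy_map, search, radius_mm = 6)
        sba_tmap(rest_pre, seed_timecourse(rest_pre, froi),
                 provenance = "fROI")
      },
      ICA = {
        dec <- spatial_ica(rest_pre, truth$brain, config$ica_components,
                           seed = spec$seed)
        select_sensorimotor_component(dec, gyri_bilateral, config$ica_z_thr)
      })
  }
  for (m in config$methods) {
    maps[[m]] <- tryCatch(run_method(m), error = function(e) {
      note("method %s unavailable: %s", m, conditionMessage(e))
      NULL
    })
  }

  threshold_map <- function(map) {
    if (identical(config$threshold_policy, "ample"))
      ample_threshold(map, ample_mask)
    else fixed_threshold(map, as.numeric(config$threshold_policy))
  }
  thr <- list()
  for (m in names(maps)) {
    if (is.null(maps[[m]])) next
    thr[[m]] <- tryCatch(threshold_map(maps[[m]]), error = function(e) {
      note("thresholding %s failed: %s", m, conditionMessage(e))
      NULL
    })
  }
  if (is.null(thr$tb)) stop("task-based map could not be thresholded")

  # overlap and CoM concordance
  rs_names <- c(intersect(config$methods, names(thr)),
                if (config$include_self_check) "self")
  thr$self <- if (config$include_self_check) thr$tb else NULL
  overlap <- data.frame()
  for (m in rs_names) {
    row <- if (is.null(thr[[m]])) {
      data.frame(method = m, v_tb = NA, v_rs = NA, v_overlap = NA,
                 alpha = NA, beta = NA, available = FALSE)
    } else tryCatch({
      ov <- overlap_alpha_beta(thr$tb, thr[[m]], eval_mask)
      data.frame(method = m, v_tb = ov$v_tb, v_rs = ov$v_rs,
                 v_overlap = ov$v_overlap, alpha = ov$alpha, beta = ov$beta,
                 available = TRUE)
    }, error = function(e) {
      note("overlap %s undefined: %s", m, conditionMessage(e))
      data.frame(method = m, v_tb = NA, v_rs = NA, v_overlap = NA,
                 alpha = NA, beta = NA, available = FALSE)
    })
    overlap <- rbind(overlap, row)
  }

  les_com <- lesion_com(truth$lesion)
  coms <- list()
  com_tab <- data.frame()
  for (m in c("tb", rs_names)) {
    row <- if (is.null(thr[[m]])) {
      data.frame(method = m, x_mm = NA, y_mm = NA, z_mm = NA,
                 dist_to_tb_mm = NA, dist_to_lesion_mm = NA,
                 available = FALSE)
    } else tryCatch({
      cm <- weighted_com(thr[[m]], anat_mask)
      coms[[m]] <- cm
      data.frame(method = m, x_mm = cm$xyz_mm[1], y_mm = cm$xyz_mm[2],
                 z_mm = cm$xyz_mm[3],
                 dist_to_tb_mm = if (m == "tb") NA else
                   com_distance(cm, coms$tb),
                 dist_to_lesion_mm = com_distance(cm, les_com),
                 available = TRUE)
    }, error = function(e) {
      note("CoM %s undefined: %s", m, conditionMessage(e))
      data.frame(method = m, x_mm = NA, y_mm = NA, z_mm = NA,
                 dist_to_tb_mm = NA, dist_to_lesion_mm = NA,
                 available = FALSE)
    })
    com_tab <- rbind(com_tab, row)
  }

  # recovery vs planted truth
  truth_ref <- list(tb = truth$activation[[paste0(task, "_R")]],
                    self = truth$activation[[paste0(task, "_R")]])
  for (m in config$methods) truth_ref[[m]] <- truth$network
  dice_tab <- data.frame()
  for (m in c("tb", rs_names)) {
    d <- if (is.null(thr[[m]])) NA_real_ else
      dice_coefficient(thr[[m]]$supra, truth_ref[[m]]$values)
    dice_tab <- rbind(dice_tab,
                      data.frame(method = m,
                                 reference = truth_ref[[m]]$label,
                                 dice = d))
  }

  # ECS concordance
  ecs_tab <- NULL
  if (!is.null(config$ecs)) {
    sites <- place_ecs_sites(truth, config$ecs$n, config$ecs$offset_mm,
                             seed = spec$seed + 3L,
                             activation = paste0(task, "_R"))
    cortex <- if (task == "foot") truth$paracentral_R else gyri_R
    sites <- project_site_to_cortex(sites, cortex)
    ecs_tab <- sites
    # distance of the raw (unprojected) sites to the planted activation:
    # checks that the placement offset is recovered
    ecs_tab$d_truth_mm <- vapply(seq_len(nrow(sites)), function(i)
      ecs_distance(c(sites$x_mm[i], sites$y_mm[i], sites$z_mm[i]),
                   truth$activation[[paste0(task, "_R")]]),
      numeric(1))
    for (m in c("tb", setdiff(rs_names, "self"))) {
      col <- rep(NA_real_, nrow(sites))
      if (!is.null(thr[[m]]))
        for (i in seq_len(nrow(sites)))
          col[i] <- ecs_distance(c(sites$proj_x_mm[i], sites$proj_y_mm[i],
                                   sites$proj_z_mm[i]), thr[[m]])
      ecs_tab[[paste0("d_", m, "_mm")]] <- col
    }
  }

  rec <- structure(list(config = config, truth = truth, maps = maps,
                        thresholded = thr, overlap = overlap, com = com_tab,
                        dice = dice_tab, ecs = ecs_tab, tsnr = tsnr,
                        lesion_com = les_com, seed = spec$seed,
                        notes = notes),
                   class = "case_record")
  if (!is.null(config$out_dir)) write_case_record(rec, config$out_dir)
  rec
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record> task %s, seed %d, tSNR %.1f\n",
              x$config$task, x$seed, x$tsnr))
  cat("overlap (alpha/beta):\n")
  print(x$overlap, row.names = FALSE)
  cat("centre-of-mass distances (mm):\n")
  print(x$com[, c("method", "dist_to_tb_mm", "dist_to_lesion_mm")],
        row.names = FALSE)
  if (length(x$notes)) cat("notes:\n ", paste(x$notes, collapse = "\n  "),
                           "\n")
  invisible(x)
}

# TSV (rounded to report precision) + JSON (full precision) + NIfTI maps
write_case_record <- function(rec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ov <- rec$overlap
  ov$alpha <- round(ov$alpha, 2); ov$beta <- round(ov$beta, 2)
  utils::write.table(ov, file.path(out_dir, "overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "-")
  cm <- rec$com
  for (cc in c("x_mm", "y_mm", "z_mm", "dist_to_tb_mm",
               "dist_to_lesion_mm"))
    cm[[cc]] <- round(cm[[cc]], 1)
  utils::write.table(cm, file.path(out_dir, "com.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "-")
  if (!is.null(rec$ecs))
    utils::write.table(rec$ecs, file.path(out_dir, "ecs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "-")
  for (m in names(rec$maps))
    if (!is.null(rec$maps[[m]]))
      write_volume(rec$maps[[m]],
                   file.path(out_dir, paste0("map_", m, ".nii.gz")))
  payload <- list(seed = rec$seed, task = rec$config$task,
                  tsnr = rec$tsnr, overlap = rec$overlap, com = rec$com,
                  dice = rec$dice, ecs = rec$ecs,
                  thresholds = lapply(rec$thresholded,
                                      function(t) if (is.null(t)) NULL
                                      else t$threshold),
                  notes = rec$notes)
  jsonlite::write_json(payload, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}
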