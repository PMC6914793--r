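#' Default pipeline configuration
#'
#' One nested list carrying every stage's settings; serialises round-trip
#' through YAML ([write_config()] / [read_config()]) and is written, resolved,
#' next to every run's outputs.
#'
#' @param ... overrides as `stage.key = value` pairs, e.g.
#'   `bias.enabled = FALSE`, `reg.mode = "rigid"`, `bpe.threshold = 0.2`.
#' @return a named nested list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    bias = list(enabled = TRUE, iterations = 8, order = 3),
    reg = list(enabled = TRUE, mode = "translation", deformable = FALSE,
               max_iter = 200, blur_match = TRUE),
    segment = list(fgt_polarity = "darker", cutoff = 0.5,
                   min_mask_voxels = 100, background_quantile = 0.1),
    bpe = list(threshold = 0.20, floor = NA_real_, denominator = "valid"),
    seed = 1L,
    verbosity = 1L)
  dots <- list(...)
  for (nm in names(dots)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) cfg[[parts[1]]][[parts[2]]] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' @rdname default_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(cfg)) base[[nm]] <- utils::modifyList(
    if (is.list(base[[nm]])) base[[nm]] else list(), as.list(cfg[[nm]]))
  # scalars get flattened back
  for (nm in c("seed", "verbosity")) base[[nm]] <- cfg[[nm]] %||% base[[nm]]
  class(base) <- c("run_config", "list")
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipe_log <- function(cfg, ...) {
  if ((cfg$verbosity %||% 1L) > 0) message("[bpequant] ", ...)
  invisible(NULL)
}

#' Quantify one patient study: from volumes to a BPE20% record
#'
#' Runs the full per-study chain on a pre/post-contrast volume pair: bias-field
#' correction of each volume, registration of the post volume onto the
#' pre-contrast grid, breast-mask construction from the chest-wall
#' delimitation, FGT segmentation by fuzzy C-means, the voxel-wise enhancement
#' ratio map, and the volume metrics. Deterministic for a fixed config.
#'
#' @param pre,post [volume_grid()]s, or paths to NIfTI files.
#' @param chest a [chest_wall_spec()] (or path to a CSV of control points with
#'   columns x, y, z in mm).
#' @param config a `run_config` from [default_config()].
#' @param tumor_mask optional logical array excluded from the breast mask.
#' @param keep_intermediates directory to write corrected/warped volumes and
#'   masks into, or `NULL`.
#' @return one-row tibble: the [compute_bpe()] record plus `reg_translation_mm`
#'   (list-column) and the registration similarity values.
#' @export
run_patient <- function(pre, post, chest, config = default_config(),
                        tumor_mask = NULL, keep_intermediates = NULL) {
  stage <- "io"
  res <- tryCatch({
    if (is.character(pre)) pre <- read_volume(pre)
    if (is.character(post)) post <- read_volume(post)
    if (is.character(chest)) {
      chest <- chest_wall_spec(control_points = utils::read.csv(chest))
    }
    stopifnot_same_grid(pre, post)

    stage <- "breast_mask"
    breast <- build_breast_mask(pre, chest,
                                background_quantile = config$segment$background_quantile,
                                tumor_mask = tumor_mask)

    stage <- "bias"
    if (isTRUE(config$bias$enabled)) {
      # each volume is corrected over its own body mask: before registration
      # the pre-frame breast mask is misaligned with the post volume, and
      # near-zero background voxels would corrupt the log-domain fit
      body <- function(v) {
        v$data > config$segment$background_quantile *
          stats::quantile(v$data, 0.99, names = FALSE)
      }
      pre_c <- correct_bias(pre, body(pre), iterations = config$bias$iterations,
                            order = config$bias$order)$corrected
      post_c <- correct_bias(post, body(post),
                             iterations = config$bias$iterations,
                             order = config$bias$order)$corrected
    } else {
      pre_c <- pre; post_c <- post
    }

    stage <- "registration"
    if (isTRUE(config$reg$enabled)) {
      reg <- register_post_to_pre(pre_c, post_c, mode = config$reg$mode,
                                  deformable = isTRUE(config$reg$deformable),
                                  max_iter = config$reg$max_iter)
      post_w <- reg$warped
    } else {
      reg <- NULL; post_w <- post_c
    }

    stage <- "segmentation"
    masks <- segment_fgt(pre_c, breast,
                         fgt_polarity = config$segment$fgt_polarity,
                         cutoff = config$segment$cutoff,
                         min_mask_voxels = config$segment$min_mask_voxels)

    stage <- "bpe"
    floor_cfg <- config$bpe$floor
    if (!is.null(floor_cfg) && is.na(floor_cfg)) floor_cfg <- NULL
    # the warped post volume carries the interpolation blur of resampling;
    # give the reference the matched kernel so the ratio is unbiased at
    # tissue boundaries
    pre_ref <- if (!is.null(reg) && isTRUE(config$reg$blur_match)) {
      match_resampling_blur(pre_c, reg$translation_mm)
    } else {
      pre_c
    }
    emap <- enhancement_ratio_map(pre_ref, post_w, floor = floor_cfg,
                                  mask = breast)
    rec <- compute_bpe(emap, masks, spacing = pre$spacing,
                       threshold = config$bpe$threshold,
                       denominator = config$bpe$denominator)
    rec$fgt_pct <- compute_fgt_pct(masks, pre$spacing)

    if (!is.null(keep_intermediates)) {
      dir.create(keep_intermediates, recursive = TRUE, showWarnings = FALSE)
      write_volume(pre_c, file.path(keep_intermediates, "pre_corrected.nii.gz"))
      write_volume(post_w, file.path(keep_intermediates, "post_warped.nii.gz"))
      write_volume(volume_grid(masks$breast_mask * 1, pre$spacing),
                   file.path(keep_intermediates, "breast_mask.nii.gz"))
      write_volume(volume_grid(masks$fgt_mask * 1, pre$spacing),
                   file.path(keep_intermediates, "fgt_mask.nii.gz"))
      write_volume(volume_grid(emap$ratio, pre$spacing),
                   file.path(keep_intermediates, "ratio_map.nii.gz"))
      write_config(config, file.path(keep_intermediates, "config.yaml"))
    }

    rec$reg_translation_mm <- if (is.null(reg)) list(c(0, 0, 0)) else
      list(reg$translation_mm)
    rec$similarity_before <- if (is.null(reg)) NA_real_ else reg$similarity_before
    rec$similarity_after <- if (is.null(reg)) NA_real_ else reg$similarity_after
    rec
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  res
}

#' Run the quantification over a cohort and compute its statistics
#'
#' Applies [run_patient()] to every row of a manifest (pre/post timepoints per
#' patient), pairs timepoints into a dBPE20% column, and runs the statistics
#' battery where the manifest carries the clinical columns. Per-patient
#' failures do not abort the cohort: the failed rows are collected and the
#' patient excluded from paired analyses.
#'
#' @param manifest data frame, one row per patient-timepoint: `patient_id`,
#'   `timepoint` (`"pre"`/`"post"`), `pre_path`, `post_path`, `chest_path`
#'   (paths to NIfTI / CSV) — or list-columns `pre_vol`, `post_vol`, `chest`
#'   holding in-memory objects. Clinical columns (`pcr`, `recurrence`,
#'   `rfs_months`, `lost_to_followup`, ...) are carried through.
#' @param config a `run_config`.
#' @return list of class `cohort_result`: `records` (per-study metric tibble),
#'   `paired` (one row per patient with both timepoints: pre/post BPE20% and
#'   `delta_pct`), `failures` (tibble of patient/timepoint/stage messages).
#' @export
run_cohort <- function(manifest, config = default_config()) {
  manifest <- tibble::as_tibble(manifest)
  records <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    rec <- tryCatch({
      pre <- if ("pre_vol" %in% names(row)) row$pre_vol[[1]] else row$pre_path
      post <- if ("post_vol" %in% names(row)) row$post_vol[[1]] else row$post_path
      chest <- if ("chest" %in% names(row)) row$chest[[1]] else row$chest_path
      out <- run_patient(pre, post, chest, config = config)
      out$patient_id <- row$patient_id
      out$timepoint <- row$timepoint
      out
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        patient_id = row$patient_id, timepoint = row$timepoint,
        message = conditionMessage(rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  records <- dplyr::bind_rows(records)
  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(patient_id = character(), timepoint = character(),
                   message = character())

  paired <- tibble::tibble()
  if (nrow(records)) {
    wide <- records |>
      dplyr::select(dplyr::all_of(c("patient_id", "timepoint", "bpe20_pct",
                                    "fgt_pct"))) |>
      tidyr::pivot_wider(names_from = "timepoint",
                         values_from = c("bpe20_pct", "fgt_pct"),
                         names_glue = "{.value}_{timepoint}")
    ok <- stats::complete.cases(wide[, c("bpe20_pct_pre", "bpe20_pct_post")])
    wide <- wide[ok & wide$bpe20_pct_pre > 0, , drop = FALSE]
    if (nrow(wide)) {
      wide$delta_pct <- (wide$bpe20_pct_post - wide$bpe20_pct_pre) /
        wide$bpe20_pct_pre * 100
    }
    paired <- wide
  }
  structure(list(records = records, paired = paired, failures = failures,
                 config = config), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", nrow(x$records), " study records, ",
      nrow(x$paired), " paired patients, ", nrow(x$failures), " failures\n",
      sep = "")
  invisible(x)
}

#' Plot the paired BPE20% change across a cohort
#'
#' @param object a `cohort_result` with paired rows.
#' @param ... unused.
#' @return a ggplot object: per-patient pre/post BPE20% slopes.
#' @export
autoplot.cohort_result <- function(object, ...) {
  if (!nrow(object$paired)) stop("no paired patients to plot", call. = FALSE)
  df <- object$paired
  long <- tibble::tibble(
    patient_id = rep(df$patient_id, 2),
    timepoint = factor(rep(c("pre", "post"), each = nrow(df)),
                       levels = c("pre", "post")),
    bpe20_pct = c(df$bpe20_pct_pre, df$bpe20_pct_post))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$bpe20_pct,
                                     group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(y = "BPE20% (percent of FGT voxels enhancing ≥ 20%)",
                  x = NULL, title = "Intrasubject BPE20% change") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
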