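# Subject-level orchestration (crop -> motion correct -> tensor fit ->
# interpolate -> ellipse -> landmarks -> ROIs -> means) and cohort-level
# aggregation with the group-comparison battery. Failures at any stage
# are recorded as QC flags; flagged subjects are excluded from the
# cohort statistics but kept in the bookkeeping.

default_config <- function(config = list()) {
  utils::modifyList(list(
    crop = list(bbox = "auto", margin_px = 4L),
    motion = list(max_shift_px = 10L, band_width_px = 5, method = "fourier"),
    interp = list(target_spacing_mm = 0.2),
    ellipse = list(shrink = 0.63, fa_threshold = NULL, smooth_w = 15L,
                   max_iter = 50L, tol = 1e-4,
                   bounds = list(center_mm = 0.15, axis_frac = 0.1,
                                 rotation_deg = 5)),
    roi = list(diameter_mm = 1.05, dc_frac = 0.15, pt_frac = 0.5),
    stats = list(alpha_levene = 0.05, bonferroni_family = 3L)
  ), config)
}

#' Process one subject end to end
#'
#' Runs the full single-subject chain on a DWI slice and returns the ROI
#' means with QC bookkeeping. Any stage failure is converted into a QC
#' flag; partial outputs up to the failing stage are kept.
#'
#' @param dwi a [dwi_slice()] (uncropped or already cropped).
#' @param id subject identifier.
#' @param config nested list overriding [default_config()] entries
#'   (keys: crop, motion, interp, ellipse, roi).
#' @param out_dir optional directory; when given, scalar maps (NIfTI),
#'   the shift table (CSV), the ROI set (JSON) and a QC profile figure
#'   (PNG) are written there.
#' @return An object of class `subject_result`: list with `id`, `shifts`,
#'   `ellipse`, `profile`, `roi_means` (named vector, 24 entries, or NULL
#'   on failure), and `qc` (list landmark_failure, shift_at_bound,
#'   clamped_fraction, stage_failed, message).
#' @export
run_subject <- function(dwi, id = "subject", config = list(), out_dir = NULL) {
  cfg <- default_config(config)
  qc <- list(landmark_failure = FALSE, shift_at_bound = FALSE,
             clamped_fraction = NA_real_, stage_failed = NA_character_,
             message = NA_character_)
  res <- list(id = id, shifts = NULL, ellipse = NULL, profile = NULL,
              roi_means = NULL, qc = qc)
  class(res) <- "subject_result"
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      res$qc$stage_failed <<- name
      res$qc$message <<- conditionMessage(e)
      NULL
    })
  }
  cropped <- stage("crop", crop_to_intraspinal(dwi, cfg$crop$bbox,
                                               cfg$crop$margin_px))
  if (is.null(cropped)) return(res)
  mc <- stage("motion", motion_correct(cropped, cfg$motion$max_shift_px,
                                       cfg$motion$band_width_px,
                                       cfg$motion$method))
  if (is.null(mc)) return(res)
  res$shifts <- mc$shifts
  res$qc$shift_at_bound <- any(mc$shifts$at_bound)
  tm <- stage("tensor", fit_tensor_map(mc$dwi))
  if (is.null(tm)) return(res)
  res$qc$clamped_fraction <- mean(tm$clamped[tm$mask])
  fine <- stage("interpolate", {
    maps <- lapply(tm$scalar_maps, function(m) {
      m[is.na(m)] <- 0
      interpolate_map(m, tm$spacing_mm, cfg$interp$target_spacing_mm)
    })
    list(maps = lapply(maps, `[[`, "map"),
         origin_mm = maps$FA$origin_mm)
  })
  if (is.null(fine)) return(res)
  seg <- stage("segment", {
    supp <- b0_support(b0_volume(mc$dwi))
    ell0 <- init_ellipse(tm$scalar_maps$FA, tm$spacing_mm,
                         cfg$ellipse$shrink, cfg$ellipse$fa_threshold, supp)
    fa0 <- tm$scalar_maps$FA; fa0[is.na(fa0)] <- 0
    ell <- refine_ellipse(fa0, tm$spacing_mm, ell0,
                          cfg$ellipse$max_iter, cfg$ellipse$tol,
                          cfg$ellipse$smooth_w, cfg$ellipse$bounds)
    prof <- sample_profile(fa0, tm$spacing_mm, ell)
    msk <- cord_mask(tm$scalar_maps$FA, cfg$ellipse$fa_threshold, supp)
    ell <- detect_landmarks(prof, ell, msk, tm$spacing_mm,
                            cfg$ellipse$smooth_w)
    list(ellipse = ell, profile = prof)
  })
  if (is.null(seg)) { res$qc$landmark_failure <- TRUE; return(res) }
  res$ellipse <- seg$ellipse
  res$profile <- seg$profile
  rois <- stage("roi", place_rois(seg$ellipse, dim(fine$maps$FA),
                                  cfg$interp$target_spacing_mm,
                                  cfg$roi$diameter_mm,
                                  dc_frac = cfg$roi$dc_frac,
                                  pt_frac = cfg$roi$pt_frac,
                                  origin_mm = fine$origin_mm))
  if (is.null(rois)) { res$qc$landmark_failure <- TRUE; return(res) }
  stats_df <- roi_stats(fine$maps, rois)
  per_side <- stats_df[stats_df$side %in% c("L", "R"), ]
  res$roi_means <- stats::setNames(per_side$mean,
                                   paste(per_side$region, per_side$metric,
                                         per_side$side, sep = "_"))
  res$rois <- rois
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in names(tm$scalar_maps)) {
      mm <- tm$scalar_maps[[m]]; mm[is.na(mm)] <- 0
      write_map(mm, file.path(out_dir, sprintf("%s_%s.nii.gz", id, m)),
                tm$spacing_mm, mc$dwi$slice_thickness_mm)
    }
    utils::write.csv(mc$shifts, file.path(out_dir, paste0(id, "_shifts.csv")),
                     row.names = FALSE)
    jsonlite::write_json(rois[setdiff(names(rois), "pixels")],
                         file.path(out_dir, paste0(id, "_rois.json")),
                         auto_unbox = TRUE, digits = NA)
    grDevices::png(file.path(out_dir, paste0(id, "_profile.png")),
                   width = 900, height = 450)
    plot_profile(seg$profile, seg$ellipse,
                 main = sprintf("%s: FA along the sampling ellipse", id))
    grDevices::dev.off()
  }
  res
}

#' @export
print.subject_result <- function(x, ...) {
  ok <- !is.null(x$roi_means)
  cat(sprintf("<subject_result %s: %s>\n", x$id,
              if (ok) "6 ROIs quantified"
              else paste0("FAILED at stage ", x$qc$stage_failed)))
  invisible(x)
}

#' Process a cohort manifest and run the group battery
#'
#' The manifest has one row per subject: `id`, `group`, `age`, `sex`,
#' optional `sprs`, `age_of_onset`, `disease_duration`, and file columns
#' `dwi`, `bvec`, `bval`. Each subject is processed with
#' [run_subject()]; QC-flagged subjects are excluded from the statistics
#' but reported. The battery compares FA, RD and MD (not AD, whose
#' single-slice axial estimates are too scattered to compare) between
#' the groups per region on bilateral means: variance-gated two-sample
#' test with Bonferroni correction across the three regions per metric,
#' plus the age/sex-adjusted GLM effect size.
#'
#' @param manifest data.frame as above (or a path to such a CSV).
#' @param config see [run_subject()].
#' @param out_dir optional output directory for per-subject artifacts,
#'   the cohort CSV and a Markdown report.
#' @return List with `table` (included subjects, a [cohort_table()]),
#'   `results` (one row per region x metric: test, p, adjusted p,
#'   Cohen's d), `excluded` (ids + reasons), `n_listed`, `n_included`,
#'   and `report` (character vector of Markdown lines).
#' @export
run_cohort <- function(manifest, config = list(), out_dir = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  cfg <- default_config(config)
  subjects <- lapply(seq_len(nrow(manifest)), function(k) {
    row <- manifest[k, ]
    dwi <- read_dwi(row$dwi, row$bvec, row$bval)
    run_subject(dwi, id = row$id, config = config,
                out_dir = if (is.null(out_dir)) NULL
                          else file.path(out_dir, "subjects"))
  })
  ok <- vapply(subjects, function(s) !is.null(s$roi_means), logical(1))
  excluded <- data.frame(
    id = manifest$id[!ok],
    reason = vapply(subjects[!ok], function(s)
      sprintf("%s: %s", s$qc$stage_failed, s$qc$message), character(1)))
  if (!any(ok)) stop("empty cohort: every subject failed quality control")
  tab <- cbind(manifest[ok, intersect(names(manifest),
                                      c("id", "group", "age", "sex", "sprs",
                                        "age_of_onset", "disease_duration"))],
               do.call(rbind, lapply(subjects[ok], `[[`, "roi_means")))
  tab <- cohort_table(tab)
  res <- cohort_battery(tab, alpha_levene = cfg$stats$alpha_levene,
                        family = cfg$stats$bonferroni_family)
  report <- cohort_report(tab, res, n_listed = nrow(manifest),
                          excluded = excluded)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(tab, file.path(out_dir, "cohort.csv"))
    utils::write.csv(res, file.path(out_dir, "stats.csv"), row.names = FALSE)
    writeLines(report, file.path(out_dir, "report.md"))
  }
  list(table = tab, results = res, excluded = excluded,
       n_listed = nrow(manifest), n_included = sum(ok), report = report)
}

#' Group-comparison battery on a cohort table
#'
#' @param table a [cohort_table()] with HC and HSP rows.
#' @param metrics metrics to compare (default FA, RD, MD).
#' @param alpha_levene variance-gate level.
#' @param family Bonferroni family size (default 3: the three regions
#'   compared per metric).
#' @return Data.frame, one row per region x metric, with the test name,
#'   statistic, df, p, Bonferroni-adjusted p, group means, and the
#'   covariate-adjusted Cohen's d with its band.
#' @export
cohort_battery <- function(table, metrics = c("FA", "RD", "MD"),
                           alpha_levene = 0.05, family = 3L) {
  tab <- bilateral_means(as.data.frame(table))
  out <- list()
  for (mt in metrics) {
    block <- list()
    for (rg in roi_regions) {
      col <- paste(rg, mt, sep = "_")
      if (!col %in% names(tab)) next
      hc <- tab[[col]][tab$group == "HC"]
      pt <- tab[[col]][tab$group == "HSP"]
      tr <- two_sample_test(pt, hc, alpha_levene)
      adj <- tryCatch(adjusted_group_effect(cohort_table(tab), col),
                      error = function(e) NULL)
      block[[rg]] <- data.frame(
        region = rg, metric = mt, method = tr$method,
        mean_HSP = mean(pt), sd_HSP = stats::sd(pt),
        mean_HC = mean(hc), sd_HC = stats::sd(hc),
        statistic = tr$statistic, df = tr$df[length(tr$df)],
        p = tr$p_value, p_adj = NA_real_,
        cohens_d = if (is.null(adj)) NA_real_ else adj$effect$cohens_d,
        d_band = if (is.null(adj)) NA_character_ else adj$effect$band,
        stringsAsFactors = FALSE)
    }
    block <- do.call(rbind, block)
    block$p_adj <- bonferroni(block$p, max(family, nrow(block)))
    out[[mt]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

cohort_report <- function(table, results, n_listed = nrow(table),
                          excluded = NULL) {
  n_inc <- nrow(table)
  lines <- c("# Cohort report", "",
             sprintf("Subjects listed: %d; included after QC: %d; excluded: %d.",
                     n_listed, n_inc, n_listed - n_inc), "")
  if (!is.null(excluded) && nrow(excluded))
    lines <- c(lines,
               paste0("Excluded: ",
                      paste(sprintf("%s (%s)", excluded$id, excluded$reason),
                            collapse = "; ")), "")
  lines <- c(lines,
             sprintf("Groups: HC n = %d, HSP n = %d.",
                     sum(table$group == "HC"), sum(table$group == "HSP")), "",
             "| region | metric | HSP mean (SD) | HC mean (SD) | test | p | p (Bonferroni) | Cohen's d |",
             "|---|---|---|---|---|---|---|---|")
  for (k in seq_len(nrow(results))) {
    r <- results[k, ]
    lines <- c(lines, sprintf(
      "| %s | %s | %.3f (%.3f) | %.3f (%.3f) | %s | %.3g | %.3g | %.2f (%s) |",
      r$region, r$metric, r$mean_HSP, r$sd_HSP, r$mean_HC, r$sd_HC,
      r$method, r$p, r$p_adj, r$cohens_d, r$d_band))
  }
  lines
}
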