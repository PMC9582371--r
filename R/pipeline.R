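#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()].
#'
#' @param dataset_path directory written by [generate_dataset()].
#' @param out_dir output directory for result tables, maps and manifest.
#' @param classification_mode `"one_criterion"` (the grouping used for all
#'   group comparisons) or `"three_criteria"`; both classifications are
#'   always tabulated.
#' @param glms subset of `c("1","2","3a","3b","4","5")` to run.
#' @param thresholds subset of `c("unc_001","unc_005","fdr_05")`.
#' @param roi_strategies subset of `c("peak","mean")`.
#' @param ppi run the two-stage PPI analysis.
#' @param include_all_self_controllers for the PPI stage, include every
#'   participant with any self-control success rather than only the SC
#'   group.
#' @param smooth_fwhm Gaussian smoothing FWHM in mm applied to BOLD before
#'   fitting (0 disables).
#' @param sim a [sim_config()] describing the dataset (used for grid/TR
#'   metadata; defaults are read from the dataset when possible).
#' @param seed RNG seed for any stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset_path, out_dir,
                            classification_mode = "one_criterion",
                            glms = c("1", "2", "3a", "3b", "4", "5"),
                            thresholds = c("unc_001", "unc_005", "fdr_05"),
                            roi_strategies = c("peak", "mean"),
                            ppi = TRUE, include_all_self_controllers = FALSE,
                            smooth_fwhm = 8, sim = sim_config(), seed = 1L) {
  stopifnot(all(thresholds %in% c("unc_001", "unc_005", "fdr_05")),
            all(roi_strategies %in% c("peak", "mean")),
            classification_mode %in% c("one_criterion", "three_criteria"))
  if (!dir.exists(dataset_path))
    stop(sprintf("dataset path '%s' does not exist", dataset_path))
  structure(list(dataset_path = dataset_path, out_dir = out_dir,
                 classification_mode = classification_mode, glms = glms,
                 thresholds = thresholds, roi_strategies = roi_strategies,
                 ppi = ppi,
                 include_all_self_controllers = include_all_self_controllers,
                 smooth_fwhm = smooth_fwhm, sim = sim,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

load_subject_bold <- function(subject, blocks, smooth_fwhm, voxel_size) {
  runs <- lapply(blocks, function(b) {
    arr <- RNifti::readNifti(subject$bold_paths[[b]])
    arr <- array(as.numeric(arr), dim(arr))
    if (smooth_fwhm > 0) arr <- smooth_bold(arr, smooth_fwhm, voxel_size)
    arr
  })
  names(runs) <- blocks
  runs
}

flatten_runs <- function(runs, mask) {
  do.call(rbind, lapply(runs, function(a) {
    dm <- dim(a)
    t(matrix(a, prod(dm[1:3]), dm[4]))[, as.logical(mask), drop = FALSE]
  }))
}

#' Run the full analysis pipeline
#'
#' Orchestrates, over a generated dataset: participant classification (both
#' modes); GLM1 group goal-value map (decision vs. taste modulation,
#' one-sample t, thresholded cluster tables); GLM2 goal-value level
#' profiles in vmPFC by peak-voxel and mask-mean extraction; GLM3a/3b
#' health/taste modulator extractions by group (order robustness);
#' the robust regression of behavioural health weights on neural health
#' encoding; GLM4 SC-vs-NSC group comparison; the white-matter peak-voxel
#' circularity control; and (optionally) GLM5 plus the two-stage PPI.
#' Stage failures are caught, logged in the manifest, and downstream
#' dependent stages are skipped with explicit status.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with per-stage outputs and a
#'   `manifest` (config hash, per-stage status, wall-clock, output files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_dataset(config$dataset_path)
  sim <- config$sim
  grid <- if (!is.null(ds$labels)) dim(ds$labels) else sim$grid_shape
  affine <- if (!is.null(ds$affine)) ds$affine else grid_affine(grid)
  labels <- ds$labels
  mask_all <- array(TRUE, grid)
  results <- list()
  manifest <- list(config = unclass(config)[setdiff(names(unclass(config)),
                                                    "sim")],
                   package_version = as.character(
                     utils::packageVersion("scfmri")),
                   stages = list(), files = character())
  stage <- function(name, deps = character(), fun) {
    for (d in deps) {
      st <- manifest$stages[[d]]$status
      if (is.null(st) || st != "ok") {
        manifest$stages[[name]] <<- list(status = "skipped",
                                         reason = sprintf("dependency '%s' not ok", d))
        return(invisible(NULL))
      }
    }
    t0 <- proc.time()[3]
    res <- tryCatch(list(value = fun(), status = "ok", reason = NA),
                    error = function(e) list(value = NULL, status = "failed",
                                             reason = conditionMessage(e)))
    manifest$stages[[name]] <<- list(status = res$status,
                                     reason = res$reason,
                                     seconds = round(proc.time()[3] - t0, 2))
    if (res$status == "ok") results[[name]] <<- res$value
    invisible(NULL)
  }
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    manifest$files <<- c(manifest$files, file)
    path
  }

  ids <- ds$participants$participant_id
  profiles <- lapply(ids, function(sid)
    profile_from_events(ds$subjects[[sid]]$events))
  names(profiles) <- ids

  # ---- classification -------------------------------------------------
  stage("classification", fun = function() {
    tab <- do.call(rbind, lapply(ids, function(sid) {
      p <- profiles[[sid]]
      c3 <- classify_participant(p, "three_criteria")
      c1 <- classify_participant(p, "one_criterion")
      data.frame(participant_id = sid, label_three = c3$label,
                 label_one = c1$label, success_rate = c1$criterion1_rate,
                 n_sc_trials = c1$n_sc_trials, stringsAsFactors = FALSE)
    }))
    emit(tab, "classification.csv")
    labels_used <- if (config$classification_mode == "one_criterion")
      tab$label_one else tab$label_three
    chi <- tryCatch(group_choice_table(profiles, labels_used),
                    error = function(e) NULL)
    if (!is.null(chi)) {
      emit(chi$proportions, "choice_proportions.csv")
      emit(chi$rating_correlations, "rating_correlations.csv")
    }
    list(table = tab, labels = labels_used, choice = chi)
  })

  labels_used <- results$classification$labels

  # ---- first-level fits (cached per GLM) ------------------------------
  fits_cache <- new.env(parent = emptyenv())
  bold_cache <- new.env(parent = emptyenv())
  get_bold <- function(sid) {
    if (!is.null(bold_cache[[sid]])) return(bold_cache[[sid]])
    # keep at most 2 subjects in memory
    if (length(ls(bold_cache)) >= 2) rm(list = ls(bold_cache),
                                        envir = bold_cache)
    b <- load_subject_bold(ds$subjects[[sid]],
                           names(ds$subjects[[sid]]$events),
                           config$smooth_fwhm, sim$voxel_size)
    bold_cache[[sid]] <- b
    b
  }
  get_fits <- function(glm_id, all_trials = TRUE) {
    key <- paste0("glm", glm_id)
    if (!is.null(fits_cache[[key]])) return(fits_cache[[key]])
    fits <- lapply(ids, function(sid) {
      sub <- ds$subjects[[sid]]
      runs <- get_bold(sid)
      ev <- sub$events
      use <- if (glm_id %in% c("2", "4", "5", "ppi_seed")) "decision"
             else names(ev)
      des <- suppressWarnings(build_design(
        ev[use], glm_id, profiles[[sid]],
        motion = sub$motion[use], tr = sim$tr,
        n_volumes = sim$n_volumes_per_run, all_trials = all_trials))
      Y <- flatten_runs(runs[use], mask_all)
      fit_first_level(Y, des, mask = mask_all, affine = affine)
    })
    names(fits) <- ids
    fits_cache[[key]] <- fits
    fits
  }

  # ---- GLM1: goal value in vmPFC --------------------------------------
  vm_functional <- NULL
  if ("1" %in% config$glms) {
    stage("glm1_group", deps = "classification", fun = function() {
      fits <- get_fits("1")
      maps <- do.call(rbind, lapply(fits, function(f)
        contrast_map(f, c(decision_gv = 1, taste_gv = -1))$effect))
      gt <- group_ttest(maps, mask = mask_all, affine = affine)
      out <- list(group = gt, thresholds = list())
      for (th in config$thresholds) {
        thr <- threshold_map(gt$p_map, th, stat_map = gt$t_map)
        out$thresholds[[th]] <- thr
        emit(thr$clusters, sprintf("glm1_clusters_%s.csv", th))
      }
      out
    })
    if (!is.null(results$glm1_group) && !is.null(labels)) {
      sig <- results$glm1_group$thresholds[["unc_005"]]
      if (!is.null(sig) && sig$n_voxels > 0) {
        vm_anat <- region_mask_from_labels(labels, "vmpfc", affine)
        m <- sig$binary & vm_anat$mask
        if (any(m))
          vm_functional <- region_mask(m, "vmpfc_functional", "functional",
                                       affine)
      }
    }
  }
  if (is.null(vm_functional) && !is.null(labels))
    vm_functional <- region_mask_from_labels(labels, "vmpfc", affine)

  # ---- GLM2: goal-value level profiles --------------------------------
  if ("2" %in% config$glms) {
    stage("glm2_profiles", deps = "glm1_group", fun = function() {
      fits1 <- get_fits("1")
      fits2 <- get_fits("2")
      lev <- c("strong_no", "no", "neutral", "yes", "strong_yes")
      tc <- lapply(lev, function(l) setNames(1, l))
      names(tc) <- lev
      out <- list()
      for (strat in config$roi_strategies) {
        per <- do.call(rbind, lapply(seq_along(ids), function(s) {
          f2 <- fits2[[s]]
          have <- intersect(lev, rownames(f2$betas))
          if (strat == "peak") {
            sel <- contrast_map(fits1[[s]],
                                c(decision_gv = 1))$effect_map
            pk <- select_peak_voxel(sel, vm_functional)
            vals <- vapply(have, function(l)
              contrast_map(f2, setNames(1, l))$effect_map$values[pk$index],
              0)
          } else {
            vals <- vapply(have, function(l)
              mean(contrast_map(f2, setNames(1, l))$effect_map$values[
                vm_functional$mask], na.rm = TRUE), 0)
          }
          data.frame(subject = ids[s], strategy = strat, level = have,
                     beta = vals, stringsAsFactors = FALSE)
        }))
        out[[strat]] <- per
      }
      prof <- do.call(rbind, out)
      emit(prof, "glm2_goalvalue_profiles.csv")
      prof
    })
  }

  # ---- GLM3: health/taste encoding by group ---------------------------
  if (any(c("3a", "3b") %in% config$glms)) {
    stage("glm3_extractions", deps = "classification", fun = function() {
      fits1 <- if ("1" %in% config$glms) get_fits("1") else NULL
      rows <- list()
      for (g in intersect(c("3a", "3b"), config$glms)) {
        fits <- get_fits(g)
        for (strat in config$roi_strategies) {
          for (s in seq_along(ids)) {
            f <- fits[[s]]
            vals <- c(health = NA_real_, taste = NA_real_)
            if (strat == "peak") {
              # individual peaks located on the goal-value contrast (GLM1
              # when available, else this model's health+taste sum)
              sel <- if (!is.null(fits1))
                contrast_map(fits1[[s]], c(decision_gv = 1))$effect_map
              else contrast_map(f, c(decision_health = 1,
                                     decision_taste = 1))$effect_map
              pk <- select_peak_voxel(sel, vm_functional)
              for (cn in names(vals))
                vals[cn] <- contrast_map(
                  f, setNames(1, paste0("decision_", cn)))$effect_map$values[
                    pk$index]
            } else {
              for (cn in names(vals))
                vals[cn] <- mean(contrast_map(
                  f, setNames(1, paste0("decision_", cn)))$effect_map$values[
                    vm_functional$mask], na.rm = TRUE)
            }
            rows[[length(rows) + 1L]] <- data.frame(
              subject = s, glm = g, strategy = strat,
              contrast = names(vals), value = unname(vals),
              stringsAsFactors = FALSE)
          }
        }
      }
      ext_all <- do.call(rbind, rows)
      ext_all$group <- labels_used[ext_all$subject]
      emit(ext_all, "glm3_vmpfc_extractions.csv")
      tests <- do.call(rbind, lapply(split(
        ext_all, list(ext_all$glm, ext_all$strategy, ext_all$contrast,
                      ext_all$group), drop = TRUE), function(d) {
        tt <- t.test(d$value)
        data.frame(glm = d$glm[1], strategy = d$strategy[1],
                   contrast = d$contrast[1], group = d$group[1],
                   mean = mean(d$value), t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value, n = nrow(d),
                   stringsAsFactors = FALSE)
      }))
      emit(tests, "glm3_group_tests.csv")
      list(extractions = ext_all, tests = tests)
    })

    stage("health_weight_regression", deps = "glm3_extractions",
          fun = function() {
      ext <- results$glm3_extractions$extractions
      d <- ext[ext$glm == intersect(c("3a", "3b"), config$glms)[1] &
                 ext$strategy == config$roi_strategies[1] &
                 ext$contrast == "health", ]
      b_beh <- vapply(d$subject, function(s)
        choice_regressions(profiles[[s]])$b_health, 0)
      rr <- robust_regression(d$value, b_beh)
      emit(rr, "health_weight_robust_regression.csv")
      rr
    })
  }

  # ---- GLM4: SC vs NSC during successful self-control -----------------
  if ("4" %in% config$glms) {
    stage("glm4_group", deps = "classification", fun = function() {
      fits <- get_fits("4")
      ok <- vapply(fits, function(f) "sc_success" %in% rownames(f$betas),
                   TRUE)
      maps <- do.call(rbind, lapply(fits[ok], function(f)
        contrast_map(f, c(sc_success = 1))$effect))
      grp <- labels_used[ok]
      if (sum(grp == "SC") < 2 || sum(grp == "NSC") < 2)
        stop("need at least two subjects per group for GLM4")
      gt <- group_ttest(maps[grp == "SC", , drop = FALSE],
                        maps[grp == "NSC", , drop = FALSE],
                        mask = mask_all, affine = affine)
      out <- list(group = gt, thresholds = list())
      for (th in config$thresholds) {
        thr <- threshold_map(gt$p_map, th, stat_map = gt$t_map)
        out$thresholds[[th]] <- thr
        emit(thr$clusters, sprintf("glm4_clusters_%s.csv", th))
      }
      out
    })

    stage("white_matter_control", deps = "glm4_group", fun = function() {
      if (is.null(labels)) stop("dataset has no region labels")
      wm <- region_mask_from_labels(labels, "white_matter", affine)
      fits <- get_fits("4")
      ok <- vapply(fits, function(f)
        all(c("sc_success", "sc_failure") %in% rownames(f$betas)), TRUE)
      rows <- list()
      for (strat in config$roi_strategies) {
        ext <- extract_roi_signal(
          fits[ok], wm, strategy = strat,
          selection_contrast = c(sc_success = 1, sc_failure = -1),
          test_contrasts = list(successful = c(sc_success = 1),
                                unsuccessful = c(sc_failure = 1)))
        wide <- merge(ext[ext$contrast == "successful",
                          c("subject", "value")],
                      ext[ext$contrast == "unsuccessful",
                          c("subject", "value")], by = "subject")
        tt <- t.test(wide$value.x, wide$value.y, paired = TRUE)
        rows[[strat]] <- data.frame(
          strategy = strat, mean_successful = mean(wide$value.x),
          mean_unsuccessful = mean(wide$value.y),
          t = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value, stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, rows)
      emit(out, "white_matter_control.csv")
      out
    })
  }

  # ---- GLM5 + PPI -----------------------------------------------------
  if (config$ppi && "5" %in% config$glms) {
    stage("ppi", deps = "classification", fun = function() {
      if (is.null(labels)) stop("dataset has no region labels")
      dl <- region_mask_from_labels(labels, "dlpfc", affine)
      dl$provenance <- "meta_analytic"
      use_ids <- if (config$include_all_self_controllers) {
        rates <- results$classification$table$success_rate
        ids[!is.na(rates) & rates > 0]
      } else ids[labels_used == "SC"]
      if (length(use_ids) < 2) stop("not enough subjects for PPI")
      betas1 <- list(); seeds <- list()
      for (sid in use_ids) {
        sub <- ds$subjects[[sid]]
        bold_d <- get_bold(sid)[["decision"]]
        sd1 <- extract_seed(bold_d, sub$events$decision, profiles[[sid]],
                            sub$motion$decision, dl, sim)
        sd1$neural <- deconvolve_neural(sd1, tr = sim$tr)
        pp <- run_ppi(bold_d, sd1, sub$events$decision, profiles[[sid]],
                      sub$motion$decision, sim, grid_mask = mask_all)
        betas1[[sid]] <- pp$beta
        seeds[[sid]] <- sd1
      }
      g1 <- group_ttest(do.call(rbind, betas1), mask = mask_all,
                        affine = affine)
      thr1 <- threshold_map(g1$p_map, "unc_005", stat_map = g1$t_map)
      emit(thr1$clusters, "ppi1_clusters_unc_005.csv")
      out <- list(ppi1 = list(group = g1, clusters = thr1$clusters,
                              seeds = lapply(seeds, function(s) s$peak$mm)))
      # PPI2: reseed from the largest PPI1 cluster within IFG
      ifg <- region_mask_from_labels(labels, "ifg", affine)
      cl <- thr1$clusters
      seed2_mm <- NULL
      if (nrow(cl) > 0) {
        for (i in seq_len(nrow(cl))) {
          vx <- world_to_voxel(as.numeric(cl[i, c("peak_x", "peak_y",
                                                  "peak_z")]), affine)
          if (ifg$mask[vx[1] + 1, vx[2] + 1, vx[3] + 1]) {
            seed2_mm <- as.numeric(cl[i, c("peak_x", "peak_y", "peak_z")])
            break
          }
        }
      }
      if (is.null(seed2_mm)) {
        out$ppi2 <- list(status = "skipped: no PPI1 cluster within IFG")
        return(out)
      }
      sph2 <- make_sphere_mask(seed2_mm, 4, grid, affine)
      betas2 <- list()
      for (sid in use_ids) {
        sub <- ds$subjects[[sid]]
        bold_d <- get_bold(sid)[["decision"]]
        dm <- dim(bold_d)
        Y <- t(matrix(bold_d, prod(dm[1:3]), dm[4]))
        raw <- rowMeans(Y[, as.logical(sph2$mask), drop = FALSE])
        Z <- cbind(1, sub$motion$decision)
        ser <- as.numeric(raw - Z %*% qr.coef(qr(Z), raw))
        s2 <- list(series = ser,
                   neural = deconvolve_neural(ser, tr = sim$tr))
        pp <- run_ppi(Y, s2, sub$events$decision, profiles[[sid]],
                      sub$motion$decision, sim, grid_mask = mask_all)
        betas2[[sid]] <- pp$beta
      }
      g2 <- group_ttest(do.call(rbind, betas2), mask = mask_all,
                        affine = affine)
      thr2 <- threshold_map(g2$p_map, "unc_005", stat_map = g2$t_map)
      emit(thr2$clusters, "ppi2_clusters_unc_005.csv")
      out$ppi2 <- list(group = g2, clusters = thr2$clusters,
                       seed_mm = seed2_mm)
      out
    })
  } else {
    manifest$stages[["ppi"]] <- list(status = "skipped",
                                     reason = "PPI disabled in config")
  }

  # ---- manifest -------------------------------------------------------
  cfg_file <- file.path(config$out_dir, "pipeline_config.json")
  jsonlite::write_json(manifest$config, cfg_file, auto_unbox = TRUE,
                       digits = NA)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  paths <- file.path(config$out_dir, manifest$files)
  manifest$file_hashes <- as.list(setNames(unname(tools::md5sum(paths)),
                                           manifest$files))
  jsonlite::write_json(
    manifest[c("config_hash", "package_version", "stages", "file_hashes")],
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE,
    digits = NA, force = TRUE)
  results$manifest <- manifest
  structure(results, class = "pipeline_result")
}

#' Human-readable hypothesis summary of a pipeline run
#'
#' Writes a markdown summary with one row per hypothesis (goal value in
#' vmPFC; health encoding in SC vmPFC; dlPFC activity during successful
#' self-control; dlPFC-vmPFC connectivity), each judged from the run's own
#' tables against the simulation ground truth conventions.
#'
#' @param results a `pipeline_result`.
#' @param file optional path to write the markdown to.
#' @return character vector of markdown lines, invisibly when `file` is
#'   given.
#' @export
report_pipeline <- function(results, file = NULL) {
  if (length(setdiff(names(results), "manifest")) == 0) {
    warning("empty results: nothing to report")
    lines <- c("# Pipeline report", "", "No completed stages.")
  } else {
    say <- function(x) if (is.null(x)) "stage not run" else x
    h1 <- if (!is.null(results$glm1_group)) {
      k <- results$glm1_group$thresholds[[1]]$n_voxels
      sprintf("%d suprathreshold voxels for goal value (decision > taste)",
              k)
    } else NULL
    h2 <- if (!is.null(results$glm3_extractions)) {
      tst <- results$glm3_extractions$tests
      sc_h <- tst[tst$group == "SC" & tst$contrast == "health", ]
      sprintf("SC health encoding in vmPFC: mean beta %.3f (min p %.3g)",
              mean(sc_h$mean), min(sc_h$p))
    } else NULL
    h3 <- if (!is.null(results$glm4_group)) {
      k <- results$glm4_group$thresholds[[1]]$n_voxels
      sprintf("%d suprathreshold voxels for SC > NSC successful self-control",
              k)
    } else NULL
    h4 <- if (!is.null(results$ppi)) {
      n1 <- nrow(results$ppi$ppi1$clusters)
      sprintf("PPI1: %d clusters at p < .005 unc.; PPI2 %s", n1,
              if (!is.null(results$ppi$ppi2$clusters))
                sprintf("%d clusters", nrow(results$ppi$ppi2$clusters))
              else "skipped")
    } else NULL
    lines <- c(
      "# Pipeline report", "",
      "| Hypothesis | Finding |", "|---|---|",
      sprintf("| vmPFC correlates with goal value | %s |", say(h1)),
      sprintf("| vmPFC reflects health ratings in SC | %s |", say(h2)),
      sprintf("| dlPFC more active in successful self-control | %s |",
              say(h3)),
      sprintf("| dlPFC-vmPFC functional connectivity | %s |", say(h4)))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
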