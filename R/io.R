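# --- BIDS-style readers/writers ------------------------------------------

write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.numeric(df2[[j]]))
      df2[[j]] <- ifelse(is.na(df2[[j]]), "n/a",
                         format(df2[[j]], digits = 10, trim = TRUE,
                                scientific = FALSE))
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "n/a")
  invisible(path)
}

read_tsv <- function(path, numeric_cols = NULL) {
  df <- read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE)
  for (nm in intersect(numeric_cols, names(df)))
    df[[nm]] <- as.numeric(df[[nm]])
  df
}

read_events_tsv <- function(path) {
  need <- c("onset", "duration", "trial_type", "stimulus_id", "response")
  df <- read_tsv(path, numeric_cols = c("onset", "duration", "response"))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("malformed events file %s: missing column(s) %s",
                 basename(path), paste(miss, collapse = ", ")))
  df
}

write_nifti_vol <- function(arr, affine, path, tr = NULL) {
  img <- RNifti::asNifti(arr)
  vs <- affine[1, 1]
  RNifti::pixdim(img) <- if (length(dim(arr)) == 4 && !is.null(tr))
    c(vs, vs, vs, tr) else rep(vs, 3)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Generate a BIDS-like synthetic dataset on disk
#'
#' Per subject: three runs (health/taste rating blocks, counterbalanced
#' order, decision block last) with events TSVs, gzipped BOLD NIfTI volumes
#' and 6-column motion TSVs; dataset-level participants table, region-label
#' mask NIfTIs and a ground-truth JSON sidecar (true classes, weights,
#' latent stimulus attributes, amplitudes, seed). Fully reproducible from
#' `(config, config$seed)`.
#'
#' @param config a [sim_config()].
#' @param path output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the dataset path, invisibly.
#' @export
generate_dataset <- function(config, path, overwrite = FALSE) {
  if (dir.exists(path) && length(dir(path)) > 0 && !overwrite)
    stop(sprintf("output directory '%s' is not empty (use overwrite = TRUE)",
                 path))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  labels <- region_labels(config$grid_shape)
  affine <- grid_affine(config$grid_shape, config$voxel_size)
  stimuli <- simulate_stimuli(config)
  n_sc <- round(config$frac_sc * config$n_subjects)
  classes <- c(rep("SC", n_sc), rep("NSC", config$n_subjects - n_sc))
  gender <- rep(c("F", "M"), length.out = config$n_subjects)
  participants <- data.frame(
    participant_id = sprintf("sub-%02d", seq_len(config$n_subjects)),
    gender = gender,
    age = round(pmin(43, pmax(18, rnorm(config$n_subjects, 25, 4)))),
    bmi = round(rnorm(config$n_subjects, 22.7, 2.6), 1),
    true_class = classes, stringsAsFactors = FALSE)
  write_tsv(participants, file.path(path, "participants.tsv"))
  # masks
  dir.create(file.path(path, "masks"), showWarnings = FALSE)
  write_nifti_vol(array(as.numeric(labels), dim(labels)), affine,
                  file.path(path, "masks", "labels.nii.gz"))
  lv <- attr(labels, "levels")
  for (i in seq_along(lv))
    if (lv[i] != "background")
      write_nifti_vol(array(as.numeric(labels == i), dim(labels)), affine,
                      file.path(path, "masks", paste0(lv[i], ".nii.gz")))
  truth <- list(seed = config$seed, stimuli = stimuli,
                classes = classes, region_levels = lv,
                effect_size_map = config$effect_size_map,
                subjects = list())
  for (s in seq_len(config$n_subjects)) {
    sid <- participants$participant_id[s]
    sdir <- file.path(path, sid, "func")
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    profile <- simulate_subject(config, stimuli, classes[s])
    blocks <- if (s %% 2 == 1) c("health", "taste", "decision") else
      c("taste", "health", "decision")
    for (r in seq_along(blocks)) {
      ord <- sample(config$n_stimuli)
      timing <- simulate_timing(config$n_stimuli, config)
      ev <- make_events(blocks[r], profile, timing, ord)
      write_tsv(ev, file.path(sdir, sprintf("%s_task-food_run-%d_events.tsv",
                                            sid, r)))
      td <- truth_design(ev, profile, config)
      run <- simulate_bold(td, labels, config, classes[s],
                           with_coupling = blocks[r] == "decision")
      write_nifti_vol(run$data, affine,
                      file.path(sdir, sprintf("%s_task-food_run-%d_bold.nii.gz",
                                              sid, r)),
                      tr = config$tr)
      write_tsv(as.data.frame(run$motion),
                file.path(sdir, sprintf("%s_task-food_run-%d_motion.tsv",
                                        sid, r)))
    }
    truth$subjects[[sid]] <- list(
      true_class = classes[s],
      w_health = attr(profile, "w_health"),
      w_taste = attr(profile, "w_taste"),
      block_order = blocks)
  }
  jsonlite::write_json(truth, file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a generated dataset
#'
#' Validates and loads the layout written by [generate_dataset()]:
#' participants table, per-subject events (all runs), motion tables, BOLD
#' file paths (loaded lazily with [RNifti::readNifti()]), region masks and
#' the ground-truth sidecar when present. Missing motion or mask files are
#' reported per subject.
#'
#' @param path dataset directory.
#' @return list of class `sc_dataset`: `participants`, `subjects` (each
#'   with `events` named by block, `motion`, `bold_paths`), `labels`,
#'   `affine`, `ground_truth`, `problems`.
#' @export
read_dataset <- function(path) {
  pfile <- file.path(path, "participants.tsv")
  if (!file.exists(pfile)) stop(sprintf("no participants.tsv under %s", path))
  participants <- read_tsv(pfile, numeric_cols = c("age", "bmi"))
  if (!"participant_id" %in% names(participants))
    stop("participants.tsv lacks column participant_id")
  lab_file <- file.path(path, "masks", "labels.nii.gz")
  labels <- NULL; affine <- NULL
  if (file.exists(lab_file)) {
    img <- RNifti::readNifti(lab_file)
    labels <- array(as.integer(round(img)), dim(img))
    attr(labels, "levels") <- c("background", "vmpfc", "caudate", "dlpfc",
                                "ifg", "white_matter")
    affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
    affine <- matrix(as.numeric(affine), 4, 4)
  }
  problems <- character()
  subjects <- list()
  for (sid in participants$participant_id) {
    sdir <- file.path(path, sid, "func")
    evf <- sort(dir(sdir, pattern = "_events\\.tsv$", full.names = TRUE))
    if (length(evf) == 0) {
      problems <- c(problems, sprintf("%s: no events files", sid))
      next
    }
    events <- lapply(evf, read_events_tsv)
    names(events) <- vapply(events, function(e) e$trial_type[1], "")
    motion <- list()
    bold <- character()
    for (r in seq_along(evf)) {
      mf <- sub("_events\\.tsv$", "_motion.tsv", evf[r])
      bf <- sub("_events\\.tsv$", "_bold.nii.gz", evf[r])
      motion[[r]] <- if (file.exists(mf))
        as.matrix(read_tsv(mf)) else {
          problems <- c(problems, sprintf("%s: missing %s", sid, basename(mf)))
          NULL
        }
      if (!file.exists(bf)) {
        problems <- c(problems, sprintf("%s: missing %s", sid, basename(bf)))
        bf <- NA_character_
      }
      bold[r] <- bf
    }
    names(motion) <- names(events)
    names(bold) <- names(events)
    subjects[[sid]] <- list(events = events, motion = motion,
                            bold_paths = bold)
  }
  gt_file <- file.path(path, "ground_truth.json")
  ground_truth <- if (file.exists(gt_file))
    jsonlite::read_json(gt_file, simplifyVector = TRUE) else NULL
  structure(list(participants = participants, subjects = subjects,
                 labels = labels, affine = affine,
                 ground_truth = ground_truth, problems = problems,
                 path = path),
            class = "sc_dataset")
}

#' Reconstruct a subject profile from rating-block events
#'
#' Inverts the events layout: collects each stimulus's health, taste and
#' decision responses from the three run events tables.
#'
#' @param events named list of events data.frames (`health`, `taste`,
#'   `decision`).
#' @return per-stimulus profile data.frame.
#' @export
profile_from_events <- function(events) {
  stopifnot(all(c("health", "taste", "decision") %in% names(events)))
  ids <- sort(unique(events$decision$stimulus_id))
  get <- function(block) {
    ev <- events[[block]]
    ev$response[match(ids, ev$stimulus_id)]
  }
  data.frame(stimulus_id = ids, health = get("health"),
             taste = get("taste"), decision = get("decision"),
             stringsAsFactors = FALSE)
}
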