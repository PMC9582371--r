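#' Sequential orthogonalization of parametric modulator columns
#'
#' Gram-Schmidt residualization in the order given: each modulator column is
#' residualized against the columns in `against` (typically its condition's
#' onset boxcar) and against all earlier modulator columns. The span of the
#' full set is unchanged; only the attribution of shared variance shifts
#' toward earlier-entered columns.
#'
#' @param columns numeric matrix, one modulator per column, in entry order.
#' @param against numeric matrix of columns every modulator is residualized
#'   against (may have zero columns).
#' @return matrix of the same shape as `columns`.
#' @export
orthogonalize_modulators <- function(columns, against = NULL) {
  columns <- as.matrix(columns)
  if (ncol(columns) < 1L) stop("need at least one modulator column")
  basis <- if (is.null(against)) matrix(0, nrow(columns), 0) else as.matrix(against)
  out <- columns
  for (j in seq_len(ncol(columns))) {
    v <- columns[, j]
    if (sqrt(sum(v^2)) < 1e-12)
      stop(sprintf("zero-norm modulator column %d cannot be orthogonalized", j))
    if (ncol(basis) > 0) {
      qb <- qr(basis)
      v <- v - basis %*% qr.coef(qb, v)
      v[is.na(v)] <- 0
    }
    out[, j] <- v
    basis <- cbind(basis, columns[, j])
  }
  out
}

# discrete cosine high-pass basis: components with period > cutoff seconds
dct_basis <- function(n, tr, cutoff = 128) {
  k_max <- floor(2 * n * tr / cutoff)
  if (k_max < 1) return(matrix(0, n, 0))
  t0 <- seq_len(n) - 1
  b <- sapply(seq_len(k_max), function(k) cos(pi * (2 * t0 + 1) * k / (2 * n)))
  matrix(b, nrow = n)
}

# trial categorisation shared by GLM4/GLM5 condition assignment; one label
# per decision trial, evaluated in priority order
glm45_category <- function(cat_row) {
  if (cat_row$missing_any) return("missing_ratings")
  if (cat_row$neutral_decision) return("neutral_response")
  if (!cat_row$requires_self_control) return("sc_not_required")
  if (isTRUE(cat_row$self_control_success)) "sc_success" else "sc_failure"
}

# per-run regressor recipe: returns list of conditions, each with trial
# indices into the run's events and optional named modulator list
glm_conditions <- function(glm_id, events, profile, block) {
  prof <- profile[match(events$stimulus_id, profile$stimulus_id), , drop = FALSE]
  gv <- prof$decision; hh <- prof$health; tt <- prof$taste
  own <- switch(block, health = hh, taste = tt, decision = gv)
  n <- nrow(events)
  conds <- list()
  add <- function(name, idx, modulators = NULL) {
    if (length(idx) > 0)
      conds[[length(conds) + 1L]] <<- list(name = name, idx = idx,
                                           modulators = modulators)
    conds
  }
  if (glm_id %in% c("1", "3a", "3b")) {
    if (glm_id == "1") miss <- is.na(gv) | is.na(own)
    else miss <- is.na(hh) | is.na(tt)
    ok <- which(!miss)
    mods <- switch(glm_id,
      "1"  = list(gv = gv[ok]),
      "3a" = list(health = hh[ok], taste = tt[ok]),
      "3b" = list(taste = tt[ok], health = hh[ok]))
    add(block, ok, mods)
    add("missing_ratings", which(miss))
  } else if (glm_id == "2") {
    lev <- c(`2` = "strong_yes", `1` = "yes", `0` = "neutral",
             `-1` = "no", `-2` = "strong_no")
    for (v in names(lev)) add(lev[[v]], which(!is.na(gv) & gv == as.numeric(v)))
    add("missing_gv", which(is.na(gv)))
  } else if (glm_id %in% c("4", "5")) {
    cats <- categorize_trials(prof)
    if (glm_id == "4") {
      lab <- vapply(seq_len(n), function(i) glm45_category(cats[i, ]), "")
    } else {
      lab <- vapply(seq_len(n), function(i) {
        if (cats$missing_any[i]) "missing_ratings"
        else if (cats$neutral_decision[i]) "neutral_response"
        else if (!cats$requires_self_control[i]) "sc_not_required"
        else if (cats$liked[i] && cats$unhealthy[i]) "liked_unhealthy"
        else "disliked_healthy"
      }, "")
    }
    order5 <- if (glm_id == "4")
      c("sc_success", "sc_failure", "sc_not_required", "neutral_response",
        "missing_ratings")
    else c("liked_unhealthy", "disliked_healthy", "sc_not_required",
           "neutral_response", "missing_ratings")
    for (nm in order5) add(nm, which(lab == nm))
  } else if (glm_id == "ppi_seed") {
    add("healthy_food", which(!is.na(hh) & hh > 0))
    add("unhealthy_food", which(!is.na(hh) & hh < 0))
  } else stop(sprintf("unknown GLM id '%s'", glm_id))
  conds
}

#' Build a first-level design matrix
#'
#' Constructs the time-by-regressor matrix for one of the study's GLMs.
#' Boxcars last each trial's reaction time; parametric modulators are
#' mean-centred within condition, sequentially orthogonalized in entry order
#' (health first for GLM 3a, taste first for 3b) against the condition
#' boxcar and earlier modulators, then convolved with the canonical HRF on a
#' microtime grid (16 bins per TR) and sampled at the middle bin. Feedback
#' periods are left unmodelled. Six motion columns, per-run discrete-cosine
#' high-pass columns (cutoff 128 s) and per-run constants are appended.
#' Conditions with zero trials are dropped with a warning and recorded in
#' the `dropped` field.
#'
#' @param events a single events data.frame (columns `onset`, `duration`,
#'   `trial_type`, `stimulus_id`, `response`) or a named list of them, one
#'   per run, names giving the block (`health`, `taste`, `decision`).
#' @param glm_id one of `"1"`, `"2"`, `"3a"`, `"3b"`, `"4"`, `"5"`,
#'   `"ppi_seed"`.
#' @param profile subject profile (per-stimulus `health`, `taste`,
#'   `decision` ratings; see [simulate_subject()]).
#' @param motion matrix of 6 motion parameters per run (list parallel to
#'   `events`), or `NULL` to omit.
#' @param tr repetition time in seconds.
#' @param n_volumes volumes per run.
#' @param hp_cutoff high-pass cutoff in seconds (128); `Inf` disables.
#' @param microtime bins per TR for convolution (16).
#' @param all_trials for GLMs 3a/3b: use all three runs (the Table-1
#'   definition, default) or only the decision run.
#' @return object of class `fmri_design`: list with matrix `X`, per-column
#'   metadata `cols` (name, kind, run, condition), `frame_times`, `tr`,
#'   `runs`, `dropped`.
#' @export
build_design <- function(events, glm_id, profile, motion = NULL, tr = 2,
                         n_volumes = 343, hp_cutoff = 128, microtime = 16L,
                         all_trials = TRUE) {
  glm_id <- as.character(glm_id)
  if (is.data.frame(events)) {
    blk <- unique(events$trial_type)
    events <- setNames(list(events), if (length(blk) == 1) blk else "decision")
  }
  if (!is.null(motion) && is.matrix(motion)) motion <- list(motion)
  decision_only <- glm_id %in% c("2", "4", "5", "ppi_seed") ||
    (glm_id %in% c("3a", "3b") && !all_trials)
  use <- if (decision_only) which(names(events) == "decision") else seq_along(events)
  if (length(use) == 0) stop("no decision run present in events")
  events <- events[use]
  if (!is.null(motion)) motion <- motion[use]

  n_runs <- length(events)
  dt <- tr / microtime
  n_micro <- n_volumes * microtime
  samp <- (seq_len(n_volumes) - 1L) * microtime + ceiling(microtime / 2)

  task_blocks <- list(); meta <- list(); dropped <- character()
  for (r in seq_len(n_runs)) {
    ev <- events[[r]]
    need <- c("onset", "duration", "trial_type", "stimulus_id", "response")
    if (!all(need %in% names(ev)))
      stop(sprintf("events run %d lacks columns: %s", r,
                   paste(setdiff(need, names(ev)), collapse = ", ")))
    if (any(ev$onset + ev$duration > n_volumes * tr)) {
      bad <- which(ev$onset + ev$duration > n_volumes * tr)[1]
      stop(sprintf("trial %d of run %d ends after the run (onset %.1f s)",
                   bad, r, ev$onset[bad]))
    }
    block <- names(events)[r]
    conds <- glm_conditions(glm_id, ev, profile, block)
    expected <- expected_conditions(glm_id, block)
    got <- vapply(conds, `[[`, "", "name")
    if (length(setdiff(expected, got)) > 0) {
      miss <- setdiff(expected, got)
      dropped <- c(dropped, paste0(miss, "_run", r))
      warning(sprintf("run %d: condition(s) with zero trials dropped: %s",
                      r, paste(miss, collapse = ", ")), call. = FALSE)
    }
    for (cn in conds) {
      on_bins <- pmax(1L, pmin(n_micro, floor(ev$onset[cn$idx] / dt) + 1L))
      off_bins <- pmax(on_bins, pmin(n_micro,
        floor((ev$onset[cn$idx] + ev$duration[cn$idx]) / dt)))
      box <- numeric(n_micro)
      for (i in seq_along(on_bins)) box[on_bins[i]:off_bins[i]] <- 1
      cols_mt <- matrix(box, ncol = 1)
      nms <- cn$name
      kinds <- "boxcar"
      if (!is.null(cn$modulators)) {
        mods <- matrix(0, n_micro, length(cn$modulators))
        for (m in seq_along(cn$modulators)) {
          val <- cn$modulators[[m]]
          val <- val - mean(val)
          mcol <- numeric(n_micro)
          for (i in seq_along(on_bins)) mcol[on_bins[i]:off_bins[i]] <- val[i]
          mods[, m] <- mcol
        }
        keep <- colSums(mods^2) > 1e-12
        if (any(keep)) {
          mods <- orthogonalize_modulators(mods[, keep, drop = FALSE],
                                           against = cols_mt)
          cols_mt <- cbind(cols_mt, mods)
          nms <- c(nms, paste(cn$name, names(cn$modulators)[keep], sep = "_"))
          kinds <- c(kinds, rep("parametric", sum(keep)))
        }
        if (any(!keep))
          dropped <- c(dropped,
            paste(cn$name, names(cn$modulators)[!keep], "run", r, sep = "_"))
      }
      xs <- convolve_hrf(cols_mt, dt)[samp, , drop = FALSE]
      task_blocks[[length(task_blocks) + 1L]] <- xs
      meta[[length(meta) + 1L]] <- data.frame(
        name = nms, kind = kinds, run = r, condition = cn$name,
        stringsAsFactors = FALSE)
    }
  }
  task <- do.call(cbind, task_blocks)
  cols <- do.call(rbind, meta)
  # merge same-named task columns across runs (each is zero off its run
  # only when blocks differ; here runs never share a condition name except
  # via identical block labels, so sum is safe)
  X_task <- matrix(0, n_runs * n_volumes, 0)
  uniq <- unique(cols$name)
  Xfull <- matrix(0, n_runs * n_volumes, length(uniq),
                  dimnames = list(NULL, uniq))
  kind_of <- character(length(uniq)); names(kind_of) <- uniq
  cond_of <- character(length(uniq)); names(cond_of) <- uniq
  for (j in seq_len(ncol(task))) {
    rows <- (cols$run[j] - 1L) * n_volumes + seq_len(n_volumes)
    Xfull[rows, cols$name[j]] <- Xfull[rows, cols$name[j]] + task[, j]
    kind_of[cols$name[j]] <- cols$kind[j]
    cond_of[cols$name[j]] <- cols$condition[j]
  }
  col_meta <- data.frame(name = uniq, kind = unname(kind_of[uniq]),
                         condition = unname(cond_of[uniq]), run = NA_integer_,
                         stringsAsFactors = FALSE)
  X <- Xfull
  # motion (six shared columns, values stacked run-wise)
  if (!is.null(motion)) {
    mo <- do.call(rbind, lapply(motion, function(m) {
      m <- as.matrix(m)
      stopifnot(ncol(m) == 6L, nrow(m) == n_volumes)
      m
    }))
    colnames(mo) <- paste0("motion", 1:6)
    X <- cbind(X, mo)
    col_meta <- rbind(col_meta, data.frame(
      name = colnames(mo), kind = "nuisance", condition = "motion",
      run = NA_integer_, stringsAsFactors = FALSE))
  }
  # per-run DCT high-pass + constants
  for (r in seq_len(n_runs)) {
    rows <- (r - 1L) * n_volumes + seq_len(n_volumes)
    if (is.finite(hp_cutoff)) {
      B <- dct_basis(n_volumes, tr, hp_cutoff)
      if (ncol(B) > 0) {
        Bf <- matrix(0, n_runs * n_volumes, ncol(B))
        Bf[rows, ] <- B
        colnames(Bf) <- sprintf("dct%d_run%d", seq_len(ncol(B)), r)
        X <- cbind(X, Bf)
        col_meta <- rbind(col_meta, data.frame(
          name = colnames(Bf), kind = "nuisance", condition = "highpass",
          run = r, stringsAsFactors = FALSE))
      }
    }
    cst <- numeric(n_runs * n_volumes); cst[rows] <- 1
    X <- cbind(X, cst)
    colnames(X)[ncol(X)] <- sprintf("constant_run%d", r)
    col_meta <- rbind(col_meta, data.frame(
      name = sprintf("constant_run%d", r), kind = "constant",
      condition = "constant", run = r, stringsAsFactors = FALSE))
  }
  structure(list(X = X, cols = col_meta,
                 frame_times = rep((seq_len(n_volumes) - 0.5) * tr, n_runs),
                 tr = tr, n_volumes = n_volumes, runs = n_runs,
                 glm_id = glm_id, hp_cutoff = hp_cutoff, dropped = dropped),
            class = "fmri_design")
}

# the Table-1 condition list a run could contribute, for drop reporting
expected_conditions <- function(glm_id, block) {
  switch(glm_id,
    "1" = c(block, "missing_ratings"),
    "3a" = , "3b" = c(block, "missing_ratings"),
    "2" = c("strong_yes", "yes", "neutral", "no", "strong_no", "missing_gv"),
    "4" = c("sc_success", "sc_failure", "sc_not_required",
            "neutral_response", "missing_ratings"),
    "5" = c("liked_unhealthy", "disliked_healthy", "sc_not_required",
            "neutral_response", "missing_ratings"),
    "ppi_seed" = c("healthy_food", "unhealthy_food"))
}

#' @export
print.fmri_design <- function(x, ...) {
  cat(sprintf("<fmri_design GLM%s> %d scans x %d regressors (%d runs)\n",
              x$glm_id, nrow(x$X), ncol(x$X), x$runs))
  print(table(x$cols$kind))
  invisible(x)
}
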