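#' Simulation configuration
#'
#' Defaults reproduce the study conditions this package emulates: 80
#' subjects with roughly 15/80 self-controllers, 50 food stimuli rated on
#' 5-point scales, three task runs (health, taste, decision blocks) of 343
#' volumes at TR 2 s, a 20x20x20 grid of 3 mm voxels, AR(1) BOLD noise,
#' trial windows of at most 4 s (boxcar duration = reaction time), 0.5 s
#' feedback and inter-trial intervals uniform on 4-15 s.
#'
#' @param n_subjects number of simulated participants.
#' @param n_stimuli number of food stimuli (50).
#' @param frac_sc fraction of subjects simulated with self-controller
#'   ground-truth weights.
#' @param w_health_sc,w_taste_sc,w_health_nsc,w_taste_nsc true decision
#'   weights on the health and taste ratings for the two classes
#'   (SC: health-dominated; NSC: taste-dominated).
#' @param stim_corr latent health-taste correlation parameter in (-1, 1).
#' @param rating_noise_sd sd of subject-level rating noise on the latent
#'   scale (0 = noise-free ratings).
#' @param decision_noise_sd scale of the logistic noise in the
#'   ordered-choice decision model (0 = deterministic decisions).
#' @param missing_prob per-response probability of a missing rating.
#' @param tr repetition time, seconds.
#' @param n_volumes_per_run volumes per run (343).
#' @param grid_shape integer vector of 3 voxel counts (20, 20, 20).
#' @param voxel_size voxel edge, mm (3).
#' @param effect_size_map data.frame of true amplitudes (percent-signal
#'   scale) with columns `region`, `regressor`, `amp_sc`, `amp_nsc`; see
#'   [default_effect_sizes()].
#' @param ar1_rho lag-1 autocorrelation of the BOLD noise, in \[0, 1).
#' @param noise_sd BOLD noise standard deviation.
#' @param drift_sd amplitude scale of the low-frequency cosine drift.
#' @param ppi_coupling coupling-modulation amplitude: extra connectivity of
#'   the `ppi_target` region to the `ppi_seed` region's neural series during
#'   unhealthy-food decision trials.
#' @param ppi_seed,ppi_target region labels for the generative connectivity
#'   component.
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 80, n_stimuli = 50, frac_sc = 15 / 80,
                       w_health_sc = 1.8, w_taste_sc = 0.6,
                       w_health_nsc = 0.6, w_taste_nsc = 1.8,
                       stim_corr = 0, rating_noise_sd = 0.35,
                       decision_noise_sd = 1.2, missing_prob = 0.02,
                       tr = 2, n_volumes_per_run = 343,
                       grid_shape = c(20, 20, 20), voxel_size = 3,
                       effect_size_map = default_effect_sizes(),
                       ar1_rho = 0.3, noise_sd = 1, drift_sd = 1,
                       ppi_coupling = 0.5, ppi_seed = "dlpfc",
                       ppi_target = "ifg", seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_stimuli = n_stimuli,
              frac_sc = frac_sc, w_health_sc = w_health_sc,
              w_taste_sc = w_taste_sc, w_health_nsc = w_health_nsc,
              w_taste_nsc = w_taste_nsc, stim_corr = stim_corr,
              rating_noise_sd = rating_noise_sd,
              decision_noise_sd = decision_noise_sd,
              missing_prob = missing_prob, tr = tr,
              n_volumes_per_run = n_volumes_per_run,
              grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
              effect_size_map = effect_size_map, ar1_rho = ar1_rho,
              noise_sd = noise_sd, drift_sd = drift_sd,
              ppi_coupling = ppi_coupling, ppi_seed = ppi_seed,
              ppi_target = ppi_target, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_stimuli >= 2)
  if (cfg$frac_sc < 0 || cfg$frac_sc > 1) stop("frac_sc must be in [0, 1]")
  if (cfg$tr <= 0) stop("tr must be positive")
  if (cfg$ar1_rho < 0 || cfg$ar1_rho >= 1) stop("ar1_rho must be in [0, 1)")
  if (abs(cfg$stim_corr) >= 1)
    stop("stim_corr must lie strictly inside (-1, 1)")
  w <- c(cfg$w_health_sc, cfg$w_taste_sc, cfg$w_health_nsc, cfg$w_taste_nsc)
  if (!all(is.finite(w))) stop("choice weights must be finite")
  amp <- cfg$effect_size_map
  stopifnot(all(c("region", "regressor", "amp_sc", "amp_nsc") %in% names(amp)))
  if (!all(is.finite(amp$amp_sc)) || !all(is.finite(amp$amp_nsc)))
    stop("effect amplitudes must be finite")
  if (any(amp$region == "white_matter" &
          (amp$amp_sc != 0 | amp$amp_nsc != 0)))
    stop("white_matter amplitudes must be zero by construction")
  invisible(cfg)
}

#' Default ground-truth effect amplitudes
#'
#' Encodes the hypotheses under test as simulation truth: vmPFC carries
#' goal value in decision trials in everyone, additionally health in SC
#' subjects and taste in both groups; caudate weakly carries goal value;
#' dlPFC responds to unhealthy foods (giving the PPI seed its localizer
#' signal) with no successful-vs-unsuccessful difference; white matter has
#' zero amplitude for every task regressor.
#'
#' @param strong amplitude used for the "strong" effects (percent signal
#'   per rating unit, default 0.6).
#' @return data.frame with columns `region`, `regressor`, `amp_sc`,
#'   `amp_nsc`.
#' @export
default_effect_sizes <- function(strong = 0.6) {
  weak <- strong / 2
  df <- rbind(
    data.frame(region = "vmpfc", regressor = "decision_gv",
               amp_sc = strong, amp_nsc = strong),
    data.frame(region = "vmpfc", regressor = "decision_health",
               amp_sc = weak, amp_nsc = 0),
    data.frame(region = "vmpfc", regressor = "decision_taste",
               amp_sc = weak, amp_nsc = weak),
    data.frame(region = "caudate", regressor = "decision_gv",
               amp_sc = weak, amp_nsc = weak),
    data.frame(region = "dlpfc", regressor = "unhealthy_food",
               amp_sc = strong, amp_nsc = strong),
    data.frame(region = "white_matter", regressor = "decision_gv",
               amp_sc = 0, amp_nsc = 0))
  df
}

#' Deterministic region labels on the simulation grid
#'
#' Places six disjoint rectangular regions (vmPFC, caudate, left dlPFC,
#' left IFG, white matter, background) at fixed fractional positions of the
#' grid, so any grid size yields the same layout up to resolution.
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @return integer 3D array of labels with a `levels` attribute; use
#'   [region_mask_from_labels()] to extract one region.
#' @export
region_labels <- function(grid_shape) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8))
  lv <- c("background", "vmpfc", "caudate", "dlpfc", "ifg", "white_matter")
  lab <- array(1L, grid_shape)
  box <- function(fr) {  # fr = fractional x,y,z ranges
    idx <- lapply(1:3, function(a) {
      lo <- max(1L, ceiling(fr[[a]][1] * grid_shape[a]))
      hi <- min(grid_shape[a], floor(fr[[a]][2] * grid_shape[a]))
      lo:hi
    })
    as.matrix(expand.grid(idx))
  }
  assign_box <- function(code, fr) {
    m <- box(fr)
    lab[m] <<- code
  }
  assign_box(2L, list(c(0.35, 0.65), c(0.65, 0.90), c(0.15, 0.35)))  # vmpfc
  assign_box(3L, list(c(0.35, 0.65), c(0.45, 0.60), c(0.45, 0.60)))  # caudate
  assign_box(4L, list(c(0.10, 0.30), c(0.60, 0.80), c(0.65, 0.85)))  # dlpfc
  assign_box(5L, list(c(0.10, 0.30), c(0.65, 0.85), c(0.40, 0.55)))  # ifg
  assign_box(6L, list(c(0.35, 0.65), c(0.15, 0.40), c(0.55, 0.80)))  # wm
  attr(lab, "levels") <- lv
  lab
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d subjects (%.0f%% SC), %d stimuli, TR %gs x %d volumes, grid %s\n",
    x$n_subjects, 100 * x$frac_sc, x$n_stimuli, x$tr, x$n_volumes_per_run,
    paste(x$grid_shape, collapse = "x")))
  invisible(x)
}
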