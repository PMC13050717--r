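#' Default brain/region geometry
#'
#' An elliptical whole-brain mask with four elliptical regions: bilateral
#' forebrain (anterior) and midbrain (posterior) hemispheres, proportioned
#' like the dorsal widefield view of a stage-47 tadpole with the hindbrain
#' outside the field. Fractional placement means the geometry scales to
#' any frame size.
#'
#' @param h,w Frame size in pixels.
#' @return A [region_masks()].
#' @export
default_region_geometry <- function(h = 96, w = 96) {
  stopifnot(h >= 16, w >= 16)
  ellipse <- function(cr, cc, ar, ac) {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    ((rows - cr * h)^2 / (ar * h)^2 + (cols - cc * w)^2 / (ac * w)^2) <= 1
  }
  brain <- ellipse(0.50, 0.50, 0.440, 0.355)
  regions <- list(
    FB_L = ellipse(0.29, 0.333, 0.146, 0.125),
    FB_R = ellipse(0.29, 0.677, 0.146, 0.125),
    MB_L = ellipse(0.646, 0.313, 0.167, 0.135),
    MB_R = ellipse(0.646, 0.698, 0.167, 0.135))
  ## hemispheric masks are drawn within the brain outline
  regions <- lapply(regions, function(r) r & brain)
  region_masks(brain, regions)
}

#' Render a synthetic calcium movie with ground truth
#'
#' Builds per-region dF/F0 traces from the preset's event statistics --
#' events are drawn at the pair level (midbrain and forebrain separately)
#' and assigned to both hemispheres with probability `p_shared`, otherwise
#' to one side at random, keeping each region's marginal event rate at the
#' preset rate -- and renders them multiplicatively over a static
#' baseline: `F(t, y, x) = F0(y, x) * (1 + trace_region(t) / 100)` inside a
#' region, `F0` elsewhere, plus additive pixel noise. Fluorescence is in
#' arbitrary units inside `[0, 1]` (the unit range of the 32-bit TIFF
#' writer); dF/F0 is scale-free so the choice is immaterial downstream.
#'
#' @param preset A [cohort_preset()].
#' @param geometry A [region_masks()].
#' @param seed Integer seed.
#' @param duration_s Movie length, seconds (default the preset's).
#' @param pixel_noise_sd Additive pixel noise SD in fluorescence units.
#' @return List with `movie` (a [movie_stack()]) and `truth` (data frame
#'   `region`, `event_time_s`, `amplitude`).
#' @export
synthesize_movie <- function(preset, geometry = default_region_geometry(),
                             seed = 1, duration_s = NULL, pixel_noise_sd = 0.003) {
  stopifnot(inherits(preset, "cohort_preset"), inherits(geometry, "region_masks"))
  cfg <- preset$event_train
  if (!is.null(duration_s)) {
    cfg$rate <- cfg$rate * duration_s / cfg$duration_s   # keep temporal density
    cfg$duration_s <- duration_s
  }
  fs <- preset$fs
  p <- preset$synchrony$p_shared
  ## pair-level rate preserving the per-region marginal rate
  pair_rate <- cfg$rate / (p + (1 - p) / 2)
  pair_cfg <- cfg; pair_cfg$rate <- pair_rate
  tt <- seq(0, cfg$duration_s - 1 / fs, by = 1 / fs)
  set.seed(fold_seed(seed))
  drift_phase <- stats::runif(1, 0, 2 * pi)
  drift <- preset$noise$drift_amp * sin(2 * pi * tt / preset$noise$drift_period_s + drift_phase)
  truth <- list()
  traces <- list()
  for (pair_i in seq_along(list(c("MB_L", "MB_R"), c("FB_L", "FB_R")))) {
    sides <- list(c("MB_L", "MB_R"), c("FB_L", "FB_R"))[[pair_i]]
    train <- simulate_event_train(pair_cfg, seed + 1e6 * pair_i)
    set.seed(fold_seed(seed + 1e6 * pair_i + 5e5))
    assign_both <- stats::runif(nrow(train)) < p
    assign_left <- stats::runif(nrow(train)) < 0.5
    for (side_i in 1:2) {
      nm <- sides[side_i]
      use <- assign_both | (assign_left == (side_i == 1))
      ev <- train[use, , drop = FALSE]
      x <- numeric(length(tt))
      for (k in seq_len(nrow(ev)))
        x <- x + ev$amplitude[k] *
          calcium_kernel(tt - ev$event_time_s[k], cfg$rise_tau_s, cfg$decay_tau_s,
                         cfg$plateau_weight, cfg$plateau_sigma_s)
      x <- x + drift + stats::rnorm(length(tt), 0, preset$noise$noise_sd)
      traces[[nm]] <- x
      if (nrow(ev) > 0)
        truth[[nm]] <- data.frame(region = nm, event_time_s = ev$event_time_s,
                                  amplitude = ev$amplitude)
    }
  }
  ## static baseline: smooth radial blob inside the brain, dim background
  H <- nrow(geometry$brain); W <- ncol(geometry$brain)
  rows <- matrix(seq_len(H), H, W); cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  r2 <- ((rows - (H + 1) / 2) / (0.6 * H))^2 + ((cols - (W + 1) / 2) / (0.6 * W))^2
  f0 <- ifelse(geometry$brain, 0.40 + 0.25 * exp(-2 * r2), 0.05)
  nT <- length(tt)
  flat <- matrix(rep(as.vector(f0), each = nT), nrow = nT)   # T x (H*W)
  for (nm in names(geometry$regions)) {
    idx <- which(as.vector(geometry$regions[[nm]]))
    if (length(idx))
      flat[, idx] <- outer(1 + traces[[nm]] / 100, as.vector(f0)[idx])
  }
  set.seed(fold_seed(seed + 9e6))
  if (pixel_noise_sd > 0)
    flat <- flat + stats::rnorm(length(flat), 0, pixel_noise_sd)
  flat <- pmin(pmax(flat, 0), 1)
  movie <- movie_stack(array(flat, dim = c(nT, H, W)), fs)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(region = character(0), event_time_s = numeric(0), amplitude = numeric(0))
  rownames(truth_df) <- NULL
  truth_df <- truth_df[order(truth_df$region, truth_df$event_time_s), , drop = FALSE]
  list(movie = movie, truth = truth_df)
}
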