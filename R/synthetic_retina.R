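#' Configuration of the synthetic retina generator
#'
#' Defines the ground-truth retina the generator emulates: field-of-view
#' (FOV) geometry, cell counts, selectivity-class mixture, functional
#' subtype mixture and tuning, and the concentric-ellipse orientation map.
#'
#' Coordinate frame: origin at the optic nerve, +x temporal, +y dorsal,
#' angles CCW from +x. The ventral cardinal axis is the vertical (90-270
#' degree) axis. FOV centers are sampled within named retinal sectors
#' (VN ventronasal, VT ventrotemporal, V central ventral, T temporal).
#'
#' Defaults encode the study conditions: 425 x 425 um FOVs with 590 +/- 170
#' cells; ~30% orientation-selective (OS), 12% direction-selective (DS),
#' 0.5% both; OS subtype mixture ONs/ONt/OFF = 70/20/10% with tuning
#' concentration ordered inversely (OFF > ONt > ONs); preferred orientations
#' laid out as tangents of concentric ellipses anchored in ventronasal
#' retina (horizontal radius 1.09x the vertical), with an orthogonal
#' underrepresented minority group.
#'
#' @param n_fovs number of FOVs.
#' @param fov_size_um FOV side length in micrometers.
#' @param cells_per_fov_mean,cells_per_fov_sd Gaussian cell count per FOV
#'   (rounded, floored at 10).
#' @param frac_os,frac_ds,frac_both class proportions (remainder is
#'   non-selective).
#' @param subtype_mix proportions of ONs/ONt/OFF among OS cells; must sum
#'   to 1.
#' @param subtype_tuning_kappa named tuning concentrations (double-angle von
#'   Mises) per subtype, OFF > ONt > ONs.
#' @param underrep_frac fraction of OS cells in the orthogonal
#'   (underrepresented) orientation group.
#' @param map_anchor_xy_um anchor (center) of the concentric map, um.
#' @param map_aspect_ratio horizontal/vertical radius ratio of the map
#'   ellipses (1 = circles).
#' @param angular_noise_kappa von Mises concentration of orientation noise
#'   in double-angle space (`Inf` = noiseless).
#' @param quadrants sectors to place FOVs in, recycled across FOVs:
#'   subset of `c("VN","VT","V","T")`.
#' @param quadrant_halfwidth_deg angular half-width of each sector around
#'   its central axis.
#' @param fov_distance_range_um range of FOV center distances from the
#'   optic nerve.
#' @param n_directions,n_reps,frames_per_trial,frame_rate_hz stimulus
#'   protocol parameters (see [stimulus_protocol()]).
#' @param noise_sd i.i.d. Gaussian noise s.d. added to dF/F traces.
#' @param response_amplitude peak dF/F of the kinetic templates.
#' @param ds_modulation_depth depth (0-1) of the raised-cosine direction
#'   gain of DS cells. A raised cosine carries only the first angular
#'   harmonic, so direction tuning contributes no orientation-space signal
#'   on an even direction grid (DSI = depth / (2 - depth)).
#' @param condition experimental condition tag: NR (normal reared), B2KO
#'   (beta2-nAChR knockout) or DR (dark reared). Changes nothing by default
#'   (the map is condition-invariant); `condition_effect` is an optional
#'   multiplier (0-1) on tuning concentration for power analyses.
#' @param condition_effect see `condition`.
#' @param seed integer seed; the same seed and config reproduce the retina
#'   bit-identically.
#' @return object of class `retina_config`.
#' @export
retina_config <- function(n_fovs = 20L,
                          fov_size_um = 425,
                          cells_per_fov_mean = 590,
                          cells_per_fov_sd = 170,
                          frac_os = 0.30,
                          frac_ds = 0.12,
                          frac_both = 0.005,
                          subtype_mix = c(ONs = 0.70, ONt = 0.20, OFF = 0.10),
                          subtype_tuning_kappa = c(ONs = 1.5, ONt = 2.5, OFF = 4),
                          underrep_frac = 0.15,
                          map_anchor_xy_um = c(-100, -250),
                          map_aspect_ratio = 1.09,
                          angular_noise_kappa = 10,
                          quadrants = c("VN", "VT"),
                          quadrant_halfwidth_deg = 18,
                          fov_distance_range_um = c(400, 1400),
                          n_directions = 8L,
                          n_reps = 5L,
                          frames_per_trial = 48L,
                          frame_rate_hz = 10,
                          noise_sd = 0.08,
                          response_amplitude = 1.0,
                          ds_modulation_depth = 1.0,
                          condition = c("NR", "B2KO", "DR"),
                          condition_effect = 1.0,
                          seed = 1L) {
  condition <- match.arg(condition)
  props <- c(frac_os, frac_ds, frac_both, underrep_frac)
  if (any(!is.finite(props)) || any(props < 0) || any(props > 1))
    stop("invalid configuration: proportions must lie in [0, 1]")
  if (frac_os + frac_ds + frac_both > 1)
    stop("invalid configuration: class fractions exceed 1")
  if (abs(sum(subtype_mix) - 1) > 1e-8)
    stop("invalid configuration: subtype_mix must sum to 1")
  if (!all(c("ONs", "ONt", "OFF") %in% names(subtype_mix)))
    stop("subtype_mix must be named ONs, ONt, OFF")
  if (fov_size_um <= 0) stop("fov_size_um must be positive")
  if (ds_modulation_depth < 0 || ds_modulation_depth > 1)
    stop("invalid configuration: ds_modulation_depth must lie in [0, 1]")
  if (as.integer(n_directions) %% 2L != 0L)
    stop("n_directions must be even (orientations pair opposite directions)")
  if (!all(quadrants %in% c("VN", "VT", "V", "T")))
    stop("quadrants must be among VN, VT, V, T")
  out <- as.list(environment())
  class(out) <- "retina_config"
  out
}

## central direction (deg, CCW from +x=temporal) of each named sector;
## ventral = 270, nasal = 180.
sector_center_deg <- c(VN = 225, VT = 315, V = 270, T = 0)

#' Stimulus protocol implied by a retina configuration
#' @param config a [retina_config()].
#' @return a [stimulus_protocol()].
#' @export
protocol_from_config <- function(config) {
  stimulus_protocol(
    direction_angles_deg = seq(0, 360 - 360 / config$n_directions,
                               by = 360 / config$n_directions),
    n_reps = config$n_reps,
    frames_per_trial = config$frames_per_trial,
    frame_rate_hz = config$frame_rate_hz
  )
}

#' Generate a ground-truth synthetic retina
#'
#' Places FOVs within the configured retinal sectors, populates them with
#' cells placed uniformly within each FOV, assigns selectivity classes,
#' functional subtypes and orientation groups, and sets every OS cell's
#' ground-truth preferred orientation to the tangent angle of the
#' configured concentric-ellipse map at the cell's location — rotated 90
#' degrees for the underrepresented group — plus von Mises angular noise in
#' double-angle space. DS preferred directions are uniform.
#'
#' @param config a [retina_config()].
#' @return list with `cells` (one row per cell: `cell_id`, `fov_id`,
#'   `x_um`, `y_um`, `selectivity_class`, `subtype`, `orientation_group`,
#'   `true_pref_orientation_deg`, `true_pref_direction_deg`,
#'   `true_tuning_kappa`) and `fovs` (`fov_id`, `center_x_um`,
#'   `center_y_um`, `quadrant`, `distance_um`), plus the `config`.
#' @export
generate_retina <- function(config) {
  stopifnot(inherits(config, "retina_config"))
  set.seed(config$seed)
  quad <- rep(config$quadrants, length.out = config$n_fovs)
  th <- deg2rad(sector_center_deg[quad] +
                  stats::runif(config$n_fovs, -1, 1) * config$quadrant_halfwidth_deg)
  d <- stats::runif(config$n_fovs, config$fov_distance_range_um[1],
                    config$fov_distance_range_um[2])
  fovs <- data.frame(
    fov_id = sprintf("fov%03d", seq_len(config$n_fovs)),
    center_x_um = d * cos(th),
    center_y_um = d * sin(th),
    quadrant = unname(quad),
    distance_um = d,
    stringsAsFactors = FALSE
  )

  ncell <- pmax(10L, as.integer(round(stats::rnorm(
    config$n_fovs, config$cells_per_fov_mean, config$cells_per_fov_sd))))
  n <- sum(ncell)
  fov_of <- rep(seq_len(config$n_fovs), ncell)
  half <- config$fov_size_um / 2
  x <- fovs$center_x_um[fov_of] + stats::runif(n, -half, half)
  y <- fovs$center_y_um[fov_of] + stats::runif(n, -half, half)

  p_none <- 1 - config$frac_os - config$frac_ds - config$frac_both
  cls <- sample(c("OS", "DS", "both", "none"), n, replace = TRUE,
                prob = c(config$frac_os, config$frac_ds, config$frac_both, p_none))
  is_os <- cls %in% c("OS", "both")
  is_ds <- cls %in% c("DS", "both")

  subtype <- rep("n/a", n)
  subtype[is_os] <- sample(names(config$subtype_mix), sum(is_os),
                           replace = TRUE, prob = config$subtype_mix)
  ogroup <- rep("n/a", n)
  ogroup[is_os] <- ifelse(stats::runif(sum(is_os)) < config$underrep_frac,
                          "underrepresented", "overrepresented")

  ori <- rep(NA_real_, n)
  if (any(is_os)) {
    base <- map_tangent_axis(config$map_anchor_xy_um, config$map_aspect_ratio,
                             x[is_os], y[is_os])
    base[ogroup[is_os] == "underrepresented"] <-
      norm_axis_deg(base[ogroup[is_os] == "underrepresented"] + 90)
    noise <- rvonmises(sum(is_os), 0, config$angular_noise_kappa) / 2
    ori[is_os] <- norm_axis_deg(base + rad2deg(noise))
  }
  dir <- rep(NA_real_, n)
  dir[is_ds] <- stats::runif(sum(is_ds), 0, 360)

  kappa <- rep(0, n)
  eff <- config$condition_effect
  kappa[is_os] <- unname(config$subtype_tuning_kappa[subtype[is_os]]) * eff
  kappa[cls == "DS"] <- config$ds_modulation_depth * eff

  cells <- data.frame(
    cell_id = sprintf("c%06d", seq_len(n)),
    fov_id = fovs$fov_id[fov_of],
    x_um = x, y_um = y,
    selectivity_class = cls,
    subtype = subtype,
    orientation_group = ogroup,
    true_pref_orientation_deg = ori,
    true_pref_direction_deg = dir,
    true_tuning_kappa = kappa,
    stringsAsFactors = FALSE
  )
  list(cells = cells, fovs = fovs, config = config)
}

## Kinetic templates: piecewise double-exponentials on the trial timeline,
## peak-normalized to 1. Time constants (s) are design values emulating the
## three OS subtypes' onset/offset response shapes:
##   ONs - fast rise at onset (0.15), sustained during stim (slow decay 6),
##         pronounced decay after offset (0.8)
##   ONt - fast rise at onset (0.10), transient decay (0.4)
##   OFF - silent during stim; fast rise at offset (0.10), decay (0.4)
kinetic_template <- function(subtype, proto) {
  t <- (seq_len(proto$frames_per_trial) - 1) / proto$frame_rate_hz
  t_on <- proto$stim_on_window[1] / proto$frame_rate_hz
  t_off <- proto$stim_on_window[2] / proto$frame_rate_hz
  f <- numeric(length(t))
  if (subtype == "OFF") {
    post <- t >= t_off
    tp <- t[post] - t_off
    f[post] <- (1 - exp(-tp / 0.10)) * exp(-tp / 0.4)
  } else {
    during <- t >= t_on & t < t_off
    td <- t[during] - t_on
    if (subtype == "ONt") {
      f[during] <- (1 - exp(-td / 0.10)) * exp(-td / 0.4)
      post <- t >= t_off
      v_off <- (1 - exp(-(t_off - t_on) / 0.10)) * exp(-(t_off - t_on) / 0.4)
      f[post] <- v_off * exp(-(t[post] - t_off) / 0.4)
    } else { # ONs (also the generic template for non-OS cells)
      f[during] <- (1 - exp(-td / 0.15)) * exp(-td / 6)
      post <- t >= t_off
      v_off <- (1 - exp(-(t_off - t_on) / 0.15)) * exp(-(t_off - t_on) / 6)
      f[post] <- v_off * exp(-(t[post] - t_off) / 0.8)
    }
  }
  f / max(f)
}

## tuning gains in [0,1], peak 1 at the preferred angle. The OS gain is a
## double-angle von Mises; the DS gain is a raised cosine (pure first
## harmonic), so DS tuning adds no orientation-space energy on an even
## direction grid.
os_gain <- function(theta_deg, pref_ori_deg, kappa)
  exp(kappa * (cos(2 * deg2rad(theta_deg - pref_ori_deg)) - 1))
ds_gain <- function(theta_deg, pref_dir_deg, depth)
  1 - depth / 2 * (1 - cos(deg2rad(theta_deg - pref_dir_deg)))

#' Synthesize calcium responses for generated cells
#'
#' Each trial trace is the cell's subtype kinetic template scaled by a
#' tuning gain — von Mises in double-angle space for OS cells, single-angle
#' for DS cells, flat for non-selective cells, the product of both for
#' cells selective in both spaces — plus i.i.d. Gaussian noise. Non-OS
#' cells use the generic sustained-onset template.
#'
#' @param cells the `cells` data.frame from [generate_retina()] (any subset).
#' @param config the [retina_config()] used to generate them.
#' @param proto optional [stimulus_protocol()]; defaults to
#'   [protocol_from_config()].
#' @return named list (by `cell_id`) of response sets: each a named list of
#'   T x R dF/F matrices keyed by direction angle.
#' @export
synthesize_responses <- function(cells, config, proto = protocol_from_config(config)) {
  set.seed((config$seed + 104729L) %% .Machine$integer.max)
  angles <- proto$direction_angles_deg
  T <- proto$frames_per_trial
  R <- proto$n_reps
  tmpl <- list(ONs = kinetic_template("ONs", proto),
               ONt = kinetic_template("ONt", proto),
               OFF = kinetic_template("OFF", proto))
  out <- vector("list", nrow(cells))
  names(out) <- cells$cell_id
  for (i in seq_len(nrow(cells))) {
    st <- cells$subtype[i]
    f <- tmpl[[if (st %in% names(tmpl)) st else "ONs"]]
    cls <- cells$selectivity_class[i]
    gain <- rep(1, length(angles))
    if (cls %in% c("OS", "both"))
      gain <- gain * os_gain(angles, cells$true_pref_orientation_deg[i],
                             cells$true_tuning_kappa[i])
    if (cls == "DS")
      gain <- gain * ds_gain(angles, cells$true_pref_direction_deg[i],
                             cells$true_tuning_kappa[i])
    if (cls == "both")
      gain <- gain * ds_gain(angles, cells$true_pref_direction_deg[i],
                             config$ds_modulation_depth)
    cell <- vector("list", length(angles))
    names(cell) <- as.character(angles)
    for (k in seq_along(angles)) {
      M <- matrix(config$response_amplitude * gain[k] * f, nrow = T, ncol = R)
      if (config$noise_sd > 0)
        M <- M + matrix(stats::rnorm(T * R, 0, config$noise_sd), T, R)
      cell[[k]] <- M
    }
    out[[i]] <- cell
  }
  out
}
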