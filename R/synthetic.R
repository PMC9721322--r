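#' Synthetic detector simulation configuration
#'
#' Seeded generator settings for dark, gain-indicator and flat-field stacks
#' with ground-truth defect populations.  Defect amplitudes are expressed in
#' units of the population scale of the feature that should detect them, so
#' detectability thresholds are scale-free: an amplitude `a` defect sits `a`
#' population sigmas from the inlier model of its feature.
#'
#' Defaults emulate a multi-gain integrating module: per-ASIC smooth offset
#' planes around 1000 ADU with 2 ADU pixel-to-pixel scatter, 3 ADU dark
#' noise, 1 ADU common-mode frame jitter, gain-indicator levels 5000/7000/
#' 9000 with 10 units temporal noise and 5 units pixel scatter, and a flat
#' field of 500 ADU with 10 ADU noise.
#'
#' @param layout a [detector_layout()].
#' @param T_dark,T_flat frame counts of the dark and flat runs.
#' @param offset_mean,offset_ramp,offset_scatter dark-offset model: mean
#'   level (ADU), maximum per-ASIC plane slope (ADU/pixel), per-pixel
#'   scatter around the ASIC plane (ADU).
#' @param dark_noise temporal noise of a normal pixel in the dark (ADU).
#' @param frame_jitter sd of the common-mode per-frame shift (ADU).
#' @param gain_levels named vector of indicator levels per gain stage.
#' @param gain_noise,gain_scatter indicator temporal noise and per-pixel
#'   level scatter.
#' @param flat_level,flat_noise,illum_gradient flat-field mean signal (ADU),
#'   per-frame pixel noise (ADU), and relative illumination span across the
#'   module width (0.2 = 20% ramp).
#' @param counting_mode `TRUE` to generate photon-counting darks.
#' @param count_rate probability of a spurious single count per frame in
#'   counting mode.
#' @param count_stuck_value constant count emitted by stuck pixels in
#'   counting mode.
#' @param defect_rates named vector of per-class defect rates (each in
#'   `[0, 0.05]`); classes: `hot_offset`, `cold_offset`, `noisy`, `stuck`,
#'   `gain_overlap`, `gain_level_shift`, `flicker_bright`,
#'   `dead_under_light`.
#' @param defect_amplitude defect effect size in population-sigma units;
#'   amplitudes below 6 are by design not reliably detectable at
#'   `lambda = 8` and trigger a warning.
#' @param flicker_duty fraction of frames in which a flickering pixel
#'   spikes.
#' @param bad_frame_rate,bad_frame_shift rate of anomalous frames and their
#'   common-mode shift in units of `frame_jitter`.
#' @param seed integer seed; identical configurations generate bit-identical
#'   stacks.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(layout = detector_layout(),
                       T_dark = 300, T_flat = 200,
                       offset_mean = 1000, offset_ramp = 0.01,
                       offset_scatter = 2, dark_noise = 3,
                       frame_jitter = 1,
                       gain_levels = c(high = 5000, medium = 7000,
                                       low = 9000),
                       gain_noise = 10, gain_scatter = 5,
                       flat_level = 500, flat_noise = 10,
                       illum_gradient = 0,
                       counting_mode = FALSE, count_rate = 1e-3,
                       count_stuck_value = 3,
                       defect_rates = c(hot_offset = 0.005,
                                        cold_offset = 0.005,
                                        noisy = 0.005, stuck = 0.005,
                                        gain_overlap = 0.005,
                                        gain_level_shift = 0.005,
                                        flicker_bright = 0.005,
                                        dead_under_light = 0.005),
                       defect_amplitude = 15, flicker_duty = 0.3,
                       bad_frame_rate = 0.01, bad_frame_shift = 50,
                       seed = 1) {
  stopifnot(inherits(layout, "detector_layout"))
  known <- c("hot_offset", "cold_offset", "noisy", "stuck", "gain_overlap",
             "gain_level_shift", "flicker_bright", "dead_under_light")
  if (!all(names(defect_rates) %in% known))
    stop("unknown defect class in `defect_rates`", call. = FALSE)
  if (any(defect_rates < 0 | defect_rates > 0.05))
    stop("defect rates must lie in [0, 0.05]", call. = FALSE)
  if (!counting_mode && dark_noise <= 0)
    stop("`dark_noise` must be positive in integrating mode", call. = FALSE)
  if (length(gain_levels) >= 2) {
    gaps <- abs(diff(sort(gain_levels)))
    if (any(gaps <= 3 * (2 * gain_noise)))
      stop("gain-indicator levels of normal pixels are closer than 3 ",
           "combined sigma; increase the level separation", call. = FALSE)
  }
  if (defect_amplitude < 6 && any(defect_rates > 0))
    warning("defect amplitude below 6 population sigma is not reliably ",
            "detectable at lambda = 8", call. = FALSE)
  structure(
    list(layout = layout, T_dark = as.integer(T_dark),
         T_flat = as.integer(T_flat), offset_mean = offset_mean,
         offset_ramp = offset_ramp, offset_scatter = offset_scatter,
         dark_noise = dark_noise, frame_jitter = frame_jitter,
         gain_levels = gain_levels, gain_noise = gain_noise,
         gain_scatter = gain_scatter, flat_level = flat_level,
         flat_noise = flat_noise, illum_gradient = illum_gradient,
         counting_mode = counting_mode, count_rate = count_rate,
         count_stuck_value = count_stuck_value,
         defect_rates = defect_rates,
         defect_amplitude = defect_amplitude, flicker_duty = flicker_duty,
         bad_frame_rate = bad_frame_rate, bad_frame_shift = bad_frame_shift,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# deterministic context seed below 2^31, derived from the base seed and a
# label; exact in double arithmetic
derive_seed <- function(seed, label) {
  p <- 2147483629  # prime below 2^31
  h <- seed %% p
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% p
  as.integer(h)
}

#' Ground-truth defect population of a simulated module
#'
#' Draws the defect pixels once per module (shared by every memory cell and
#' gain stage) on the non-edge pixel set, with disjoint classes.  Counts are
#' `round(rate * n_eligible)` per class.
#'
#' @param sim a [sim_config()].
#' @return A tibble with columns `row`, `col` (1-based), `class`,
#'   `amplitude`, `duty`, plus attribute `seed`.
#' @export
synthetic_truth <- function(sim) {
  stopifnot(inherits(sim, "sim_config"))
  set.seed(derive_seed(sim$seed, "truth"))
  lay <- sim$layout
  eligible <- which(!edge_pixels(lay))
  rates <- sim$defect_rates[sim$defect_rates > 0]
  counts <- round(rates * length(eligible))
  total <- sum(counts)
  if (total > length(eligible))
    stop("defect rates exceed the eligible pixel count", call. = FALSE)
  picked <- if (total > 0) sample(eligible, total) else integer(0)
  cls <- rep(names(counts), counts)
  truth <- tibble::tibble(
    row = ((picked - 1L) %% lay$H) + 1L,
    col = ((picked - 1L) %/% lay$H) + 1L,
    class = cls,
    amplitude = sim$defect_amplitude,
    duty = ifelse(cls == "flicker_bright", sim$flicker_duty, 1)
  )
  attr(truth, "seed") <- sim$seed
  truth
}

truth_index <- function(truth, class, H) {
  sel <- truth$class %in% class
  (truth$col[sel] - 1L) * H + truth$row[sel]
}

# draw anomalous frame indices and the common-mode shift per frame
draw_bad_frames <- function(sim, Tn, bad_frames = NULL) {
  if (is.null(bad_frames)) {
    nb <- rbinom(1, Tn, sim$bad_frame_rate)
    bad_frames <- if (nb > 0) sort(sample.int(Tn, nb)) else integer(0)
  }
  shift <- numeric(Tn)
  shift[bad_frames] <- sim$bad_frame_shift * sim$frame_jitter
  list(bad_frames = as.integer(bad_frames), shift = shift)
}

#' Generate a synthetic dark-run stack with ground truth
#'
#' Pixel offsets are a smooth per-ASIC plane plus per-pixel scatter; frames
#' add common-mode jitter and i.i.d. Gaussian noise.  Injected defects:
#' `hot_offset`/`cold_offset` shift a pixel's offset by `amplitude` offset
#' scatters, `noisy` inflates its temporal noise by `amplitude` population
#' sigmas of the per-pixel standard deviation (`dark_noise / sqrt(2(T-1))`),
#' and `stuck` freezes the pixel at its offset.  Anomalous frames receive a
#' global shift of `bad_frame_shift` frame jitters.
#'
#' @param sim a [sim_config()].
#' @param memory_cell,gain_stage context of the stack (each context gets an
#'   independent, reproducible realisation).
#' @param bad_frames optional explicit anomalous-frame indices (overrides
#'   the configured rate).
#' @return A list: `stack` (a [frame_stack()]), `truth` (the defect
#'   tibble), `bad_frames`.
#' @export
generate_dark_stack <- function(sim, memory_cell = 0, gain_stage = "high",
                                bad_frames = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  if (sim$counting_mode)
    return(generate_counting_dark(sim, memory_cell, gain_stage, bad_frames))
  truth <- synthetic_truth(sim)
  lay <- sim$layout
  H <- lay$H; W <- lay$W; Tn <- sim$T_dark
  set.seed(derive_seed(sim$seed, paste("dark", gain_stage, memory_cell)))

  # per-ASIC offset planes
  offsets <- matrix(0, H, W)
  for (ai in seq_len(lay$n_asic_rows)) {
    for (aj in seq_len(lay$n_asic_cols)) {
      ri <- ((ai - 1) * lay$asic_height + 1):(ai * lay$asic_height)
      ci <- ((aj - 1) * lay$asic_width + 1):(aj * lay$asic_width)
      sr <- runif(1, -1, 1) * sim$offset_ramp
      sc <- runif(1, -1, 1) * sim$offset_ramp
      b0 <- sim$offset_mean + runif(1, -5, 5)
      offsets[ri, ci] <- outer(seq_along(ri) - 1, seq_along(ci) - 1,
                               function(r, c) sr * r + sc * c + b0)
    }
  }
  offsets <- offsets + rnorm(H * W, 0, sim$offset_scatter)

  amp <- sim$defect_amplitude
  hot <- truth_index(truth, "hot_offset", H)
  cold <- truth_index(truth, "cold_offset", H)
  offsets[hot] <- offsets[hot] + amp * sim$offset_scatter
  offsets[cold] <- offsets[cold] - amp * sim$offset_scatter

  sd_px <- rep(sim$dark_noise, H * W)
  noisy <- truth_index(truth, "noisy", H)
  sigma_f3 <- sim$dark_noise / sqrt(2 * (Tn - 1))
  sd_px[noisy] <- sim$dark_noise + amp * sigma_f3

  bf <- draw_bad_frames(sim, Tn, bad_frames)
  jitter <- rnorm(Tn, 0, sim$frame_jitter) + bf$shift

  m <- matrix(rnorm(H * W * Tn), H * W, Tn) * sd_px
  m <- m + as.vector(offsets)
  m <- m + rep(jitter, each = H * W)
  stuck <- truth_index(truth, "stuck", H)
  m[stuck, ] <- offsets[stuck]

  list(
    stack = frame_stack(array(m, c(H, W, Tn)), module_id = lay$module_id,
                        memory_cell = memory_cell, gain_stage = gain_stage,
                        kind = "analogue"),
    truth = truth,
    bad_frames = bf$bad_frames
  )
}

#' Generate synthetic gain-indicator stacks with ground truth
#'
#' Normal pixels present well-separated indicator levels per gain stage
#' (level plus per-pixel scatter plus temporal noise).  `gain_overlap`
#' defects place the second stage's level within one combined temporal sigma
#' of the first stage's, so their stage intervals touch; `gain_level_shift`
#' defects shift one stage's level by `amplitude` population sigmas of the
#' per-pixel mean indicator.
#'
#' @inheritParams generate_dark_stack
#' @return A list: `stacks` (named list of [frame_stack()] per stage),
#'   `truth`, `bad_frames` (per stage).
#' @export
generate_gain_stacks <- function(sim, memory_cell = 0, bad_frames = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  if (length(sim$gain_levels) < 2)
    stop("gain-indicator generation needs at least 2 gain stages",
         call. = FALSE)
  truth <- synthetic_truth(sim)
  lay <- sim$layout
  H <- lay$H; W <- lay$W; Tn <- sim$T_dark
  stages <- names(sim$gain_levels)
  overlap <- truth_index(truth, "gain_overlap", H)
  shifted <- truth_index(truth, "gain_level_shift", H)
  sigma_f5 <- sqrt(sim$gain_scatter^2 + sim$gain_noise^2 / Tn)

  base <- list()
  set.seed(derive_seed(sim$seed, paste("gainlevels", memory_cell)))
  for (s in stages)
    base[[s]] <- sim$gain_levels[[s]] + rnorm(H * W, 0, sim$gain_scatter)
  # overlap: second stage indistinguishable from the first
  base[[stages[2]]][overlap] <- base[[stages[1]]][overlap] + sim$gain_noise
  # level shift: second stage displaced by `amplitude` population sigmas
  base[[stages[2]]][shifted] <- base[[stages[2]]][shifted] +
    sim$defect_amplitude * sigma_f5

  stacks <- list()
  bads <- list()
  for (s in stages) {
    set.seed(derive_seed(sim$seed, paste("gain", s, memory_cell)))
    bf <- draw_bad_frames(sim, Tn, bad_frames)
    jitter <- rnorm(Tn, 0, sim$frame_jitter) + bf$shift
    m <- matrix(rnorm(H * W * Tn, 0, sim$gain_noise), H * W, Tn)
    m <- m + base[[s]] + rep(jitter, each = H * W)
    stacks[[s]] <- frame_stack(array(m, c(H, W, Tn)),
                               module_id = lay$module_id,
                               memory_cell = memory_cell, gain_stage = s,
                               kind = "gain")
    bads[[s]] <- bf$bad_frames
  }
  list(stacks = stacks, truth = truth, bad_frames = bads)
}

#' Generate a synthetic near-flat-field stack with ground truth
#'
#' The illumination field is a mean level with an optional linear gradient
#' across the module width; frames add common-mode jitter and Gaussian
#' noise.  `flicker_bright` defects spike by `amplitude` noise sigmas in a
#' `duty` fraction of frames; `dead_under_light` pixels emit only their dark
#' noise.
#'
#' @inheritParams generate_dark_stack
#' @return A list: `stack`, `truth`, `bad_frames`.
#' @export
generate_flat_stack <- function(sim, memory_cell = 0, gain_stage = "high",
                                bad_frames = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  truth <- synthetic_truth(sim)
  lay <- sim$layout
  H <- lay$H; W <- lay$W; Tn <- sim$T_flat
  set.seed(derive_seed(sim$seed, paste("flat", gain_stage, memory_cell)))

  grad <- sim$illum_gradient *
    ((seq_len(W) - 1) / max(W - 1, 1) - 0.5)
  field <- matrix(sim$flat_level, H, W) *
    matrix(1 + grad, H, W, byrow = TRUE)

  bf <- draw_bad_frames(sim, Tn, bad_frames)
  jitter <- rnorm(Tn, 0, sim$frame_jitter) + bf$shift
  m <- matrix(rnorm(H * W * Tn, 0, sim$flat_noise), H * W, Tn)
  m <- m + as.vector(field) + rep(jitter, each = H * W)

  flick <- truth_index(truth, "flicker_bright", H)
  if (length(flick)) {
    on <- matrix(runif(length(flick) * Tn) < sim$flicker_duty,
                 length(flick), Tn)
    sub <- m[flick, , drop = FALSE]
    sub[on] <- sub[on] + sim$defect_amplitude * sim$flat_noise
    m[flick, ] <- sub
  }
  dead <- truth_index(truth, "dead_under_light", H)
  if (length(dead))
    m[dead, ] <- matrix(rnorm(length(dead) * Tn, 0, sim$dark_noise),
                        length(dead), Tn)

  list(
    stack = frame_stack(array(m, c(H, W, Tn)), module_id = lay$module_id,
                        memory_cell = memory_cell, gain_stage = gain_stage,
                        kind = "analogue"),
    truth = truth,
    bad_frames = bf$bad_frames
  )
}

#' Generate a synthetic photon-counting dark stack
#'
#' Normal pixels show zero counts except for spurious single counts at rate
#' `count_rate`.  `stuck` defects emit `count_stuck_value` in every frame;
#' `hot_offset` defects emit it in half of the frames.
#'
#' @inheritParams generate_dark_stack
#' @return A list: `stack`, `truth`, `bad_frames` (always empty).
#' @export
generate_counting_dark <- function(sim, memory_cell = 0,
                                   gain_stage = "single",
                                   bad_frames = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  if (!sim$counting_mode)
    stop("`sim` must have counting_mode = TRUE", call. = FALSE)
  truth <- synthetic_truth(sim)
  lay <- sim$layout
  H <- lay$H; W <- lay$W; Tn <- sim$T_dark
  set.seed(derive_seed(sim$seed, paste("countdark", gain_stage, memory_cell)))
  m <- matrix(as.numeric(runif(H * W * Tn) < sim$count_rate), H * W, Tn)
  stuck <- truth_index(truth, "stuck", H)
  m[stuck, ] <- sim$count_stuck_value
  hot <- truth_index(truth, "hot_offset", H)
  if (length(hot)) {
    on <- matrix(runif(length(hot) * Tn) < 0.5, length(hot), Tn)
    sub <- m[hot, , drop = FALSE]
    sub[on] <- sim$count_stuck_value
    m[hot, ] <- sub
  }
  list(
    stack = frame_stack(array(m, c(H, W, Tn)), module_id = lay$module_id,
                        memory_cell = memory_cell, gain_stage = gain_stage,
                        kind = "analogue"),
    truth = truth,
    bad_frames = integer(0)
  )
}
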