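#' Gamma-variate contrast bolus profile
#'
#' Normalized gamma-variate concentration profile
#' `g(u) = (u / rise_time)^shape * exp(shape * (1 - u / rise_time))` for
#' `u > 0` and `0` otherwise. The profile rises from onset at `u = 0` to its
#' peak value of exactly 1 at `u = rise_time` and then decays; smaller
#' `shape` values give a steeper front and a longer washout tail relative to
#' the rise. The analytically known peak time is what makes the phantom's
#' arrival-time ground truth exact.
#'
#' @param u Time since bolus onset, seconds (vectorized).
#' @param rise_time Time from onset to peak concentration, seconds.
#' @param shape Dimensionless gamma-variate shape parameter (> 0).
#' @return Concentration values in `[0, 1]`, same length as `u`.
#' @export
bolus_profile <- function(u, rise_time, shape) {
  stopifnot(rise_time > 0, shape > 0)
  out <- numeric(length(u))
  pos <- which(u > 0)
  x <- u[pos] / rise_time
  out[pos] <- exp(shape * (log(x) + 1 - x))
  out
}

# shape parameter such that the profile has decayed to 5% of peak at
# u = duration (so `duration` is the effective bolus duration)
bolus_shape_for <- function(duration, rise_time) {
  xe <- duration / rise_time
  if (xe <= 1) stop("bolus duration must exceed the rise time")
  -log(0.05) / (xe - 1 - log(xe))
}

#' Phantom acquisition specification
#'
#' Full parameter set for one synthetic unsubtracted angiographic
#' acquisition: vessel geometry as an explicit centerline with per-point
#' radius and bolus-velocity profiles, bolus timing/amplitude, detector
#' background and noise, and the acquisition frame rate. All randomness in
#' the simulation is controlled by `random_seed`.
#'
#' @param image_height,image_width Image size in pixels.
#' @param frame_rate Frames per second (clinical protocols use 4 or 7.5).
#' @param duration Acquisition duration in seconds (>= 2 s and at least 4
#'   frames).
#' @param vessel_path Ordered `n x 2` matrix of (row, col) centerline
#'   coordinates in pixels (0-based pixel centers at integer coordinates;
#'   sub-pixel sampling allowed).
#' @param vessel_radius_profile Vessel radius in pixels at each centerline
#'   point (> 0 everywhere); a stenosis is a local narrowing.
#' @param bolus_velocity_profile Bolus front speed in pixels/second at each
#'   centerline point (> 0 everywhere); reduced distal to a stenosis before
#'   treatment.
#' @param bolus_injection_time Seconds from acquisition start to contrast
#'   arrival at the first centerline point.
#' @param bolus_duration Effective duration of the contrast transient at a
#'   fixed point, seconds (profile decays to 5% of peak at this age).
#' @param bolus_rise_time Time from bolus onset to peak concentration at a
#'   fixed point, seconds. The default 0.08 s models the near-instantaneous
#'   opacification front of a selective intra-arterial injection.
#' @param contrast_peak_attenuation Peak line-integrated attenuation at the
#'   vessel centerline, dimensionless.
#' @param background_level Detector intensity of the unattenuated
#'   background.
#' @param photon_noise_scale Photon (Poisson) noise scale; the detector
#'   value is drawn as `rpois(value / s) * s` so variance is `value * s`.
#'   `0` disables photon noise.
#' @param readout_noise_sd Additive Gaussian readout noise, detector units.
#'   `0` disables readout noise.
#' @param random_seed Integer seed controlling all simulated noise.
#' @param rois Optional [roi_set()] evaluated against the ground truth.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [stenosis_phantom_spec()] for a high-level constructor,
#'   [simulate_acquisition()] to run the simulation.
#' @export
phantom_spec <- function(image_height, image_width, frame_rate, duration,
                         vessel_path, vessel_radius_profile,
                         bolus_velocity_profile,
                         bolus_injection_time, bolus_duration,
                         bolus_rise_time = 0.08,
                         contrast_peak_attenuation = 0.6,
                         background_level = 2000,
                         photon_noise_scale = 0.2,
                         readout_noise_sd = 5,
                         random_seed = 1L,
                         rois = NULL) {
  spec <- structure(
    list(
      image_height = as.integer(image_height),
      image_width = as.integer(image_width),
      frame_rate = frame_rate,
      duration = duration,
      vessel_path = vessel_path,
      vessel_radius_profile = vessel_radius_profile,
      bolus_velocity_profile = bolus_velocity_profile,
      bolus_injection_time = bolus_injection_time,
      bolus_duration = bolus_duration,
      bolus_rise_time = bolus_rise_time,
      contrast_peak_attenuation = contrast_peak_attenuation,
      background_level = background_level,
      photon_noise_scale = photon_noise_scale,
      readout_noise_sd = readout_noise_sd,
      random_seed = as.integer(random_seed),
      rois = rois
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (!is.numeric(spec$frame_rate) || spec$frame_rate <= 0) {
    stop("frame_rate must be positive")
  }
  if (is.null(spec$vessel_path) || NROW(spec$vessel_path) == 0) {
    stop("vessel_path must not be empty")
  }
  if (NCOL(spec$vessel_path) != 2) {
    stop("vessel_path must be an n x 2 matrix of (row, col) coordinates")
  }
  if (spec$duration < 2) stop("duration must be at least 2 seconds")
  if (floor(spec$duration * spec$frame_rate) < 4) {
    stop("duration x frame_rate must yield at least 4 frames")
  }
  n <- NROW(spec$vessel_path)
  if (length(spec$vessel_radius_profile) != n ||
      any(spec$vessel_radius_profile <= 0)) {
    stop("vessel_radius_profile must be positive at every centerline point")
  }
  if (length(spec$bolus_velocity_profile) != n ||
      any(spec$bolus_velocity_profile <= 0)) {
    stop("bolus_velocity_profile must be positive at every centerline point")
  }
  if (spec$bolus_duration <= spec$bolus_rise_time) {
    stop("bolus_duration must exceed bolus_rise_time")
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d px, %g FPS, %.1f s (%d frames), %d centerline points\n",
    x$image_height, x$image_width, x$frame_rate, x$duration,
    floor(x$duration * x$frame_rate), NROW(x$vessel_path)
  ))
  invisible(x)
}

# cumulative arclength (pixels) and bolus arrival time (seconds) along the
# centerline; arrival via trapezoidal integral of 1 / velocity
centerline_arrival <- function(spec) {
  path <- spec$vessel_path
  n <- NROW(path)
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] - path[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  inv <- 1 / spec$bolus_velocity_profile
  transit <- c(0, cumsum(seg * (inv[-1] + inv[-n]) / 2))
  list(arclength = s, arrival = spec$bolus_injection_time + transit)
}

# assign each vessel pixel to its nearest centerline point; returns flat
# pixel indices (row-major into an H x W matrix stored column-major:
# index = row + (col - 1) * H, 1-based), squared distance and point index
rasterize_vessel <- function(spec) {
  path <- spec$vessel_path
  rad <- spec$vessel_radius_profile
  H <- spec$image_height
  W <- spec$image_width
  n <- NROW(path)
  pix <- vector("list", n)
  d2l <- vector("list", n)
  idx <- vector("list", n)
  for (i in seq_len(n)) {
    r0 <- max(1, floor(path[i, 1] - rad[i])):min(H, ceiling(path[i, 1] + rad[i]))
    c0 <- max(1, floor(path[i, 2] - rad[i])):min(W, ceiling(path[i, 2] + rad[i]))
    gr <- expand.grid(r = r0, c = c0)
    d2 <- (gr$r - path[i, 1])^2 + (gr$c - path[i, 2])^2
    keep <- d2 <= rad[i]^2
    pix[[i]] <- gr$r[keep] + (gr$c[keep] - 1L) * H
    d2l[[i]] <- d2[keep]
    idx[[i]] <- rep.int(i, sum(keep))
  }
  pix <- unlist(pix); d2 <- unlist(d2l); idx <- unlist(idx)
  if (length(pix) == 0) stop("vessel does not intersect the image")
  o <- order(pix, d2)
  pix <- pix[o]; d2 <- d2[o]; idx <- idx[o]
  keep <- !duplicated(pix)
  list(pixel = pix[keep], dist2 = d2[keep], point = idx[keep])
}

#' Simulate one unsubtracted angiographic acquisition
#'
#' Generates the detector frame series for a contrast bolus propagating
#' along the phantom's vessel, together with the ground truth the simulation
#' knows exactly. The image model is Beer-Lambert attenuation of a uniform
#' detector background: `value = background_level * exp(-attenuation) +
#' noise`, where the attenuation at a vessel pixel is the chord-depth-scaled
#' gamma-variate bolus concentration peaking at the pixel's arrival time.
#' Arrival at centerline arclength `s` is `bolus_injection_time +`
#' the integral of `1 / velocity` from 0 to `s`. Photon noise is Poisson
#' (scaled), readout noise additive Gaussian; both are reproducible from
#' `spec$random_seed`, so identical specs give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{series}{[frame_series()] of `floor(duration * frame_rate)`
#'       frames.}
#'     \item{truth}{`ground_truth` object: `arrival_time_map` (seconds per
#'       pixel, `NA` outside the vessel), `peak_attenuation_map` (peak
#'       attenuation per pixel), `centerline_arclength` / `centerline_arrival`
#'       along the path, and `roi_true_ttp` — the continuous-time peak of the
#'       ROI-averaged noise-free concentration, per ROI serial, when the spec
#'       carries ROIs.}
#'   }
#' @export
simulate_acquisition <- function(spec) {
  validate_phantom_spec(spec)
  H <- spec$image_height; W <- spec$image_width
  n_frm <- floor(spec$duration * spec$frame_rate)
  times <- (seq_len(n_frm) - 1) / spec$frame_rate

  cl <- centerline_arrival(spec)
  ras <- rasterize_vessel(spec)
  arr_px <- cl$arrival[ras$point]
  # chord depth through a cylinder, normalized to 1 at the centerline
  depth <- sqrt(pmax(0, 1 - ras$dist2 / spec$vessel_radius_profile[ras$point]^2))
  amp_px <- spec$contrast_peak_attenuation * depth

  shape <- bolus_shape_for(spec$bolus_duration, spec$bolus_rise_time)
  # attenuation(t, p): profile peaks exactly at the pixel's arrival time
  u <- outer(times, arr_px, "-") + spec$bolus_rise_time
  att <- bolus_profile(u, spec$bolus_rise_time, shape) *
    rep(amp_px, each = n_frm)

  frames <- matrix(spec$background_level, n_frm, H * W)
  frames[, ras$pixel] <- spec$background_level * exp(-att)

  set.seed(spec$random_seed)
  if (spec$photon_noise_scale > 0) {
    s <- spec$photon_noise_scale
    frames[] <- stats::rpois(length(frames), frames / s) * s
  }
  if (spec$readout_noise_sd > 0) {
    frames[] <- frames + stats::rnorm(length(frames), 0, spec$readout_noise_sd)
  }
  frames[frames < 0] <- 0
  dim(frames) <- c(n_frm, H, W)

  arrival_map <- matrix(NA_real_, H, W)
  arrival_map[ras$pixel] <- arr_px
  amp_map <- matrix(0, H, W)
  amp_map[ras$pixel] <- amp_px

  truth <- structure(
    list(
      arrival_time_map = arrival_map,
      peak_attenuation_map = amp_map,
      centerline_arclength = cl$arclength,
      centerline_arrival = cl$arrival,
      roi_true_ttp = NULL
    ),
    class = "ground_truth"
  )
  if (!is.null(spec$rois)) {
    truth$roi_true_ttp <- vapply(spec$rois, function(r) {
      px <- roi_pixels(r, H, W)
      j <- match(px, ras$pixel)
      j <- j[!is.na(j)]
      if (length(j) == 0) return(NA_real_)
      tg <- seq(0, spec$duration, by = 0.002)
      conc <- rep(0, length(tg))
      for (k in j) {
        conc <- conc + amp_px[k] *
          bolus_profile(tg - arr_px[k] + spec$bolus_rise_time,
                        spec$bolus_rise_time, shape)
      }
      tg[which.max(conc)]
    }, numeric(1))
    names(truth$roi_true_ttp) <- vapply(spec$rois, `[[`, 0L, "serial")
  }

  list(
    series = frame_series(frames, spec$frame_rate, "acquisition_start"),
    truth = truth
  )
}

#' High-level phantom: sinuous artery with a stenotic segment
#'
#' Builds a [phantom_spec()] for the standard study geometry: a sinuous
#' vessel running down a square field of view, a stenotic lesion over a
#' fraction of its length (narrowed lumen, reduced bolus velocity from the
#' lesion onward, emulating flow limitation distal to the stenosis), and
#' four circular ROIs placed along the centerline: ROI1 proximal to the
#' lesion, ROI2 at the lesion start, ROI3 at the lesion end and ROI4 distal
#' to it.
#'
#' @param frame_rate Frames per second (4 or 7.5 in the emulated protocols).
#' @param image_size Square image side, pixels.
#' @param base_velocity Bolus front speed proximal to the lesion, px/s.
#' @param stenosis_factor Multiplier on `base_velocity` from the lesion
#'   start onward (< 1 pre-intervention; near 1 after treatment).
#' @param lesion_start_frac,lesion_length_frac Lesion start and length as
#'   fractions of the centerline arclength.
#' @param lesion_radius_factor Lumen narrowing inside the lesion (multiplier
#'   on `vessel_radius`).
#' @param sinuosity_amplitude,sinuosity_cycles,sinuosity_phase Lateral
#'   sine-wave geometry of the centerline (pixels, cycles over the vessel,
#'   radians).
#' @param vessel_radius Vessel radius outside the lesion, pixels.
#' @param roi_offset_proximal,roi_offset_distal Arclength distance of ROI1
#'   before the lesion start and of ROI4 after the lesion end, pixels.
#' @param roi_radius ROI radius, pixels.
#' @param duration Acquisition duration in seconds, or `NULL` to cover the
#'   full bolus transit plus washout (capped at `max_duration`).
#' @param max_duration Upper bound for the automatic duration, seconds.
#' @param n_rois Number of ROIs to place (3 or 4; 3 emulates acquisitions
#'   where no distal ROI could be placed).
#' @inheritParams phantom_spec
#' @return A [phantom_spec()] whose ROIs carry their centerline arclength
#'   (used by [true_passage_time()]).
#' @export
stenosis_phantom_spec <- function(frame_rate = 4,
                                  image_size = 128,
                                  base_velocity = 29,
                                  stenosis_factor = 0.45,
                                  lesion_start_frac = 0.42,
                                  lesion_length_frac = 0.15,
                                  lesion_radius_factor = 0.6,
                                  sinuosity_amplitude = 12,
                                  sinuosity_cycles = 1,
                                  sinuosity_phase = 0,
                                  vessel_radius = 3,
                                  bolus_injection_time = 1.2,
                                  bolus_duration = 2.4,
                                  bolus_rise_time = 0.08,
                                  contrast_peak_attenuation = 0.6,
                                  background_level = 2000,
                                  photon_noise_scale = 0.2,
                                  readout_noise_sd = 5,
                                  roi_offset_proximal = 25,
                                  roi_offset_distal = 25,
                                  roi_radius = 2.5,
                                  n_rois = 4,
                                  duration = NULL,
                                  max_duration = 20,
                                  random_seed = 1L) {
  stopifnot(n_rois %in% c(3L, 4L))
  H <- image_size; W <- image_size
  margin <- max(10, ceiling(vessel_radius) + 2)
  rows <- seq(margin, H - margin, by = 0.5)
  span <- H - 2 * margin
  cols <- W / 2 + sinuosity_amplitude *
    sin(2 * pi * sinuosity_cycles * (rows - margin) / span + sinuosity_phase)
  path <- cbind(rows, cols)
  n <- nrow(path)
  seg <- sqrt(rowSums((path[-1, ] - path[-n, ])^2))
  s <- c(0, cumsum(seg))
  L <- s[n]

  les0 <- lesion_start_frac * L
  les1 <- les0 + lesion_length_frac * L
  in_lesion <- s >= les0 & s <= les1
  radius <- rep(vessel_radius, n)
  radius[in_lesion] <- vessel_radius * lesion_radius_factor
  velocity <- ifelse(s < les0, base_velocity, base_velocity * stenosis_factor)

  roi_arcs <- c(max(roi_radius + 1, les0 - roi_offset_proximal),
                les0, les1,
                min(L - roi_radius - 1, les1 + roi_offset_distal))[seq_len(n_rois)]
  rois <- lapply(seq_along(roi_arcs), function(k) {
    i <- which.min(abs(s - roi_arcs[k]))
    r <- roi(serial = k, row = path[i, 1], col = path[i, 2],
             radius = roi_radius)
    r$arclength <- s[i]
    r
  })

  if (is.null(duration)) {
    inv <- 1 / velocity
    transit_end <- sum(seg * (inv[-1] + inv[-n]) / 2)
    duration <- min(max_duration,
                    ceiling(bolus_injection_time + transit_end +
                              bolus_duration + 0.5))
    duration <- max(duration, 2)
  }

  spec <- phantom_spec(
    image_height = H, image_width = W, frame_rate = frame_rate,
    duration = duration, vessel_path = path,
    vessel_radius_profile = radius, bolus_velocity_profile = velocity,
    bolus_injection_time = bolus_injection_time,
    bolus_duration = bolus_duration, bolus_rise_time = bolus_rise_time,
    contrast_peak_attenuation = contrast_peak_attenuation,
    background_level = background_level,
    photon_noise_scale = photon_noise_scale,
    readout_noise_sd = readout_noise_sd,
    random_seed = random_seed, rois = roi_set(rois)
  )
  attr(spec, "lesion_arclength") <- c(start = les0, end = les1)
  spec
}

#' Ground-truth bolus passage time between ROI1 and ROI4
#'
#' The time the bolus front needs to travel from the proximal ROI (serial 1)
#' to the distal ROI (serial 4), computed as the arclength integral of
#' `1 / velocity` along the centerline between the two ROI positions. Only
#' available for specs whose ROIs carry centerline arclengths (those built
#' by [stenosis_phantom_spec()]).
#'
#' @param spec A [phantom_spec()] with 4 arclength-tagged ROIs.
#' @return Passage time in seconds.
#' @export
true_passage_time <- function(spec) {
  serials <- vapply(spec$rois, `[[`, 0L, "serial")
  if (!all(c(1L, 4L) %in% serials)) {
    stop("true passage time needs ROIs with serials 1 and 4")
  }
  arc <- vapply(spec$rois, function(r) {
    if (is.null(r$arclength)) NA_real_ else r$arclength
  }, numeric(1))
  if (anyNA(arc[match(c(1L, 4L), serials)])) {
    stop("ROIs carry no centerline arclength; build the spec with stenosis_phantom_spec()")
  }
  cl <- centerline_arrival(spec)
  a <- stats::approx(cl$arclength, cl$arrival, xout = arc[match(c(1L, 4L), serials)])$y
  a[2] - a[1]
}

#' Generate a paired pre/post-intervention study cohort
#'
#' Draws a cohort of paired acquisitions emulating an interventional study:
#' each pair shares one vessel geometry, lesion and ROI set, with a flow-
#' limiting stenosis before treatment (`stenosis_factor` drawn from
#' `U(0.25, 0.55)`) and restored flow after (`U(0.80, 1.00)`), so the true
#' passage time always decreases with treatment when `paired = TRUE`.
#' Acquisition frame rates are assigned by `frame_rate_weights` (default
#' 14:8 across 4 and 7.5 FPS), and the first `n_three_roi` pairs of the
#' first frame-rate group carry only ROIs 1-3, emulating runs where no
#' distal ROI could be placed. All per-pair parameters (geometry, bolus
#' timing, severity, noise seeds) are drawn reproducibly from `seed`.
#'
#' @param n_acquisitions Number of pre/post pairs (>= 1).
#' @param frame_rates Frame rates to assign across the cohort.
#' @param paired If `TRUE` (default) the post spec restores flow across the
#'   treated segment; if `FALSE` the post severity is drawn from the same
#'   distribution as the pre severity.
#' @param seed Integer seed for the cohort draw.
#' @param frame_rate_weights Relative number of pairs per frame rate.
#' @param n_three_roi Number of pairs with only 3 ROIs (all in the first
#'   frame-rate group).
#' @param noise `"default"` for realistic photon/readout noise, `"none"`
#'   for noise-free acquisitions.
#' @return A list of class `study_cohort`; each element has `id`,
#'   `frame_rate`, `n_rois`, and [phantom_spec()]s `pre` and `post`.
#' @export
make_study_cohort <- function(n_acquisitions = 22,
                              frame_rates = c(4, 7.5),
                              paired = TRUE,
                              seed = 1L,
                              frame_rate_weights = c(14, 8),
                              n_three_roi = 3,
                              noise = c("default", "none")) {
  noise <- match.arg(noise)
  if (length(frame_rates) == 0) stop("frame_rates must not be empty")
  if (n_acquisitions < 1) stop("n_acquisitions must be at least 1")
  if (length(frame_rate_weights) != length(frame_rates)) {
    frame_rate_weights <- rep(1, length(frame_rates))
  }
  counts <- floor(n_acquisitions * frame_rate_weights / sum(frame_rate_weights))
  rem <- n_acquisitions - sum(counts)
  if (rem > 0) {
    o <- order(-(n_acquisitions * frame_rate_weights / sum(frame_rate_weights) - counts))
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  rate_of <- rep(frame_rates, counts)
  n_three_roi <- min(n_three_roi, counts[1])

  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_acquisitions)
  pairs <- vector("list", n_acquisitions)
  for (i in seq_len(n_acquisitions)) {
    base_v <- stats::runif(1, 20, 38)
    sten_pre <- stats::runif(1, 0.25, 0.55)
    sten_post <- if (paired) stats::runif(1, 0.80, 1.00) else stats::runif(1, 0.25, 0.55)
    geom <- list(
      lesion_start_frac = stats::runif(1, 0.35, 0.50),
      lesion_length_frac = stats::runif(1, 0.08, 0.22),
      lesion_radius_factor = stats::runif(1, 0.5, 0.7),
      sinuosity_amplitude = stats::runif(1, 6, 20),
      sinuosity_cycles = stats::runif(1, 0.5, 1.5),
      sinuosity_phase = stats::runif(1, 0, 2 * pi),
      roi_offset_proximal = stats::runif(1, 15, 35),
      roi_offset_distal = stats::runif(1, 15, 35)
    )
    bolus_dur <- stats::runif(1, 2, 3)
    atten <- stats::runif(1, 0.4, 0.8)
    inj <- stats::runif(2, 0.5, 3.5)  # pre, post
    n_rois <- if (i <= n_three_roi) 3L else 4L
    build <- function(sf, inj_t, sd) {
      do.call(stenosis_phantom_spec, c(geom, list(
        frame_rate = rate_of[i], base_velocity = base_v,
        stenosis_factor = sf, bolus_injection_time = inj_t,
        bolus_duration = bolus_dur, contrast_peak_attenuation = atten,
        photon_noise_scale = if (noise == "none") 0 else 0.2,
        readout_noise_sd = if (noise == "none") 0 else 5,
        n_rois = n_rois, random_seed = sd
      )))
    }
    pairs[[i]] <- list(
      id = i, frame_rate = rate_of[i], n_rois = n_rois,
      pre = build(sten_pre, inj[1], seeds[2 * i - 1]),
      post = build(sten_post, inj[2], seeds[2 * i])
    )
  }
  structure(pairs, class = "study_cohort")
}

#' @export
print.study_cohort <- function(x, ...) {
  rates <- vapply(x, `[[`, 0, "frame_rate")
  cat(sprintf(
    "<study_cohort> %d pre/post pairs (%s); %d with 3 ROIs\n",
    length(x),
    paste(sprintf("%d @ %g FPS", as.vector(table(rates)), sort(unique(rates))),
          collapse = ", "),
    sum(vapply(x, `[[`, 0L, "n_rois") == 3L)
  ))
  invisible(x)
}
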