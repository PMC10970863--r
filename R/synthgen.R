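#' Particle diameter distribution specification
#'
#' A mixture of lognormal components describing particle diameters in
#' micrometres, the standard model for milled powders. An in-specification
#' batch is a single unimodal component; an out-of-specification batch adds
#' a coarse second mode (bimodal, right-shifted).
#'
#' @param median_um per-component median diameter(s), um.
#' @param sdlog per-component log-scale standard deviation(s).
#' @param weight per-component mixing weight(s); must sum to 1.
#' @param n number of particles to draw.
#' @param floor_um,cap_um hard lower/upper diameter limits, um.
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(median_um, sdlog, weight = 1, n = 150,
                          floor_um = 2, cap_um = 400) {
  k <- length(median_um)
  if (length(sdlog) != k || length(weight) != k) {
    stop("median_um, sdlog and weight must have equal length")
  }
  if (abs(sum(weight) - 1) > 1e-9 || any(weight < 0)) {
    stop("mixture weights must be non-negative and sum to 1")
  }
  if (any(median_um <= 0) || any(sdlog < 0)) {
    stop("medians must be positive and sdlog non-negative")
  }
  if (cap_um < floor_um) stop("cap_um must be at least floor_um")
  structure(list(median_um = median_um, sdlog = sdlog, weight = weight,
                 n = as.integer(n), floor_um = floor_um, cap_um = cap_um),
            class = "particle_spec")
}

#' Default in-specification particle mixture
#'
#' Single lognormal mode, median 40 um: a unimodal milled powder inside its
#' size specification.
#' @param n number of particles per image.
#' @return A [particle_spec].
#' @export
is_particle_defaults <- function(n = 150) {
  particle_spec(median_um = 40, sdlog = 0.35, weight = 1, n = n)
}

#' Default out-of-specification particle mixture
#'
#' Bimodal: 60% of particles from the in-specification 40 um mode plus 40%
#' from a coarse 120 um mode — a right-shifted, bimodal size distribution of
#' the kind produced by particle aggregation during drying.
#' @param n number of particles per image.
#' @return A [particle_spec].
#' @export
oos_particle_defaults <- function(n = 150) {
  particle_spec(median_um = c(40, 120), sdlog = c(0.35, 0.25),
                weight = c(0.6, 0.4), n = n)
}

#' Draw particle diameters from a mixture specification
#'
#' i.i.d. draws: a mixture component per particle, then a lognormal diameter
#' with `meanlog = log(median)`, floored and capped at the hard limits.
#'
#' @param spec a [particle_spec].
#' @param seed optional integer seed for reproducible draws.
#' @return Numeric vector of diameters (um), length `spec$n`.
#' @export
sample_diameters <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "particle_spec"))
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(spec$weight), spec$n, replace = TRUE,
                     prob = spec$weight)
  d <- stats::rlnorm(spec$n, meanlog = log(spec$median_um[comp]),
                     sdlog = spec$sdlog[comp])
  pmin(pmax(d, spec$floor_um), spec$cap_um)
}

#' Scene specification for particle placement
#'
#' @param width_px,height_px canvas size in pixels.
#' @param um_per_px spatial calibration (default 1.7 um/px).
#' @param placement `"uniform"` (complete spatial randomness) or
#'   `"clustered"` (Neyman-Scott parent-child process, the aggregation
#'   surrogate: particles scatter around a smaller number of parent points).
#' @param cluster_radius_um Gaussian scatter radius of children around their
#'   parent, um.
#' @param mean_children mean number of particles per parent cluster.
#' @param overlap `"allow"` (particles may overlap) or `"reject"`
#'   (non-overlapping centers enforced by rejection sampling).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 512, height_px = 512, um_per_px = 1.7,
                       placement = c("uniform", "clustered"),
                       cluster_radius_um = 200, mean_children = 10,
                       overlap = c("allow", "reject")) {
  placement <- match.arg(placement)
  overlap <- match.arg(overlap)
  if (width_px < 1 || height_px < 1 || um_per_px <= 0) {
    stop("canvas dimensions and calibration must be positive")
  }
  if (cluster_radius_um <= 0 || mean_children <= 0) {
    stop("cluster parameters must be positive")
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 um_per_px = um_per_px, placement = placement,
                 cluster_radius_um = cluster_radius_um,
                 mean_children = mean_children, overlap = overlap),
            class = "scene_spec")
}

#' Rendering specification for transmitted-light emulation
#'
#' Dark particles on a bright field: the background level must exceed the
#' particle level. Where particles overlap, transmitted light is attenuated
#' multiplicatively through the stack, so aggregated regions render darker
#' than a single particle layer (the pseudo-three-dimensional signature of
#' aggregation). Blur emulates optical defocus at particle edges; Gaussian
#' intensity noise emulates sensor noise at the couple-of-gray-levels scale
#' typical of microscope cameras.
#'
#' @param background_level background gray level (default 230).
#' @param particle_level gray level of a single particle layer (default 40);
#'   k stacked layers render at `background * (particle/background)^k`.
#' @param noise_sd Gaussian intensity noise standard deviation (gray
#'   levels; default 2).
#' @param blur_sd Gaussian blur standard deviation in pixels (default 2).
#' @param seed optional integer seed.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(background_level = 230, particle_level = 40,
                        noise_sd = 2, blur_sd = 2, seed = NULL) {
  if (background_level < 0 || background_level > 255 ||
      particle_level < 0 || particle_level > 255) {
    stop("gray levels must lie in [0, 255]")
  }
  if (background_level <= particle_level) {
    stop("transmitted light: background must be brighter than particles")
  }
  if (noise_sd < 0 || blur_sd < 0) stop("noise_sd and blur_sd must be >= 0")
  structure(list(background_level = background_level,
                 particle_level = particle_level,
                 noise_sd = noise_sd, blur_sd = blur_sd, seed = seed),
            class = "render_spec")
}

# sample particle centers (rows, cols) honoring placement and overlap policy
.place_centers <- function(scene, radii_px) {
  n <- length(radii_px)
  H <- scene$height_px; W <- scene$width_px
  lo <- radii_px + 1
  if (any(2 * radii_px + 1 > min(H, W))) {
    stop("a particle diameter exceeds the canvas at this calibration")
  }
  propose <- function(k) {
    if (scene$placement == "uniform") {
      cbind(stats::runif(k, lo[seq_len(k)], H - radii_px[seq_len(k)]),
            stats::runif(k, lo[seq_len(k)], W - radii_px[seq_len(k)]))
    } else {
      n_parents <- max(1L, round(n / scene$mean_children))
      parents <- cbind(stats::runif(n_parents, 1, H),
                       stats::runif(n_parents, 1, W))
      sd_px <- scene$cluster_radius_um / scene$um_per_px
      pa <- sample.int(n_parents, k, replace = TRUE)
      cy <- stats::rnorm(k, parents[pa, 1], sd_px)
      cx <- stats::rnorm(k, parents[pa, 2], sd_px)
      cbind(pmin(pmax(cy, lo[seq_len(k)]), H - radii_px[seq_len(k)]),
            pmin(pmax(cx, lo[seq_len(k)]), W - radii_px[seq_len(k)]))
    }
  }
  if (scene$overlap == "allow") return(propose(n))
  # rejection sampling for non-overlapping centers, bounded retries
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      cand <- propose(i)[i, , drop = FALSE]
      if (placed == 0L) { ok <- TRUE; break }
      dd <- sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
                   (centers[seq_len(placed), 2] - cand[2])^2)
      if (all(dd > radii_px[seq_len(placed)] + radii_px[i])) { ok <- TRUE; break }
    }
    if (!ok) {
      if (placed == 0L) stop("no particle placeable under reject policy")
      warning(sprintf("placed %d of %d particles under reject policy",
                      placed, n))
      return(centers[seq_len(placed), , drop = FALSE])
    }
    centers[i, ] <- cand
    placed <- placed + 1L
  }
  centers
}

#' Render a synthetic transmitted-light powder image
#'
#' Draws each particle as a filled disk of its calibrated pixel radius at a
#' sampled center (uniform or clustered placement). Intensity follows the
#' transmitted-light attenuation model: a pixel under k particle layers
#' renders at `background * (particle/background)^k`, so isolated particles
#' sit at the particle level and overlapping (aggregated) stacks are darker.
#' Gaussian blur and Gaussian intensity noise are then applied and the
#' result clipped to [0, 255].
#'
#' @param scene a [scene_spec].
#' @param diameters particle diameters in um (from [sample_diameters()]).
#' @param render a [render_spec].
#' @return A [gray_image]; the clean pre-blur disk mask is attached as
#'   attribute `"clean_mask"` (a [binary_image]).
#' @export
place_and_render <- function(scene, diameters, render = render_spec()) {
  stopifnot(inherits(scene, "scene_spec"), inherits(render, "render_spec"))
  if (!is.null(render$seed)) set.seed(render$seed)
  radii_px <- diameters / 2 / scene$um_per_px
  centers <- .place_centers(scene, radii_px)
  H <- scene$height_px; W <- scene$width_px
  layers <- matrix(0L, H, W)
  for (i in seq_len(nrow(centers))) {
    r <- radii_px[i]; cy <- centers[i, 1]; cx <- centers[i, 2]
    rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
    cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
    inside <- outer((rows - cy)^2, (cols - cx)^2, "+") <= r^2
    layers[rows, cols] <- layers[rows, cols] + inside
  }
  mask <- layers > 0L
  transmittance <- render$particle_level / render$background_level
  canvas <- render$background_level * transmittance^layers
  if (render$blur_sd > 0) {
    img <- EBImage::gblur(EBImage::Image(t(canvas)),
                          sigma = render$blur_sd,
                          boundary = render$background_level)
    canvas <- t(EBImage::imageData(img))
  }
  if (render$noise_sd > 0) {
    canvas <- canvas + stats::rnorm(length(canvas), 0, render$noise_sd)
  }
  canvas <- pmin(pmax(round_half_up(canvas), 0), 255)
  out <- gray_image(canvas, source = "synthetic")
  attr(out, "clean_mask") <- binary_image(mask)
  out
}

#' Analytic binary masks with known fractal dimension
#'
#' Test fixtures for the box-counting engine: iterated Sierpinski
#' constructions and elementary shapes whose dimensions are known in closed
#' form (triangle log3/log2, carpet log8/log3, line 1, full square 2).
#'
#' @param kind one of `"sierpinski_triangle"`, `"sierpinski_carpet"`,
#'   `"line"`, `"disk"`, `"full"`.
#' @param depth iteration depth for the Sierpinski constructions (canvas
#'   side 2^depth for the triangle, 3^depth for the carpet).
#' @param size canvas side in pixels for `"line"`, `"disk"`, `"full"`.
#' @return A [binary_image].
#' @export
make_fractal_mask <- function(kind = c("sierpinski_triangle",
                                       "sierpinski_carpet",
                                       "line", "disk", "full"),
                              depth = 7, size = 256) {
  kind <- match.arg(kind)
  if (kind %in% c("sierpinski_triangle", "sierpinski_carpet")) {
    if (depth < 1) stop("depth must be at least 1")
  } else if (size < 1) {
    stop("size must be at least 1")
  }
  mask <- switch(kind,
    sierpinski_triangle = {
      s <- 2^depth
      if (depth > 14) stop("depth too large: canvas side would exceed 2^14")
      idx <- 0:(s - 1L)
      outer(idx, idx, bitwAnd) == 0L
    },
    sierpinski_carpet = {
      if (depth > 8) stop("depth too large: canvas side would exceed 3^8")
      s <- 3^depth
      idx <- 0:(s - 1L)
      # middle base-3 digit removal: background where some digit position
      # has digit 1 in both coordinates
      digit <- function(v, k) (v %/% 3^k) %% 3
      m <- matrix(TRUE, s, s)
      for (k in 0:(depth - 1L)) {
        one_r <- digit(idx, k) == 1L
        m <- m & !outer(one_r, one_r, "&")
      }
      m
    },
    line = {
      m <- matrix(FALSE, size, size)
      m[max(1L, size %/% 2L), ] <- TRUE
      m
    },
    disk = {
      idx <- seq_len(size)
      c0 <- (size + 1) / 2
      outer((idx - c0)^2, (idx - c0)^2, "+") <= (size / 2 - 1)^2
    },
    full = matrix(TRUE, size, size)
  )
  binary_image(mask)
}

#' Volume-based particle size distribution from diameters
#'
#' Bins diameters and weights each particle by its volume (d^3, the sphere
#' assumption of laser diffraction), normalizing to 100% total.
#'
#' @param diameters particle diameters, um.
#' @param bins ascending bin edges, um (length nbins + 1).
#' @return Named numeric vector of volume percentages per bin (names are
#'   bin centers, um), summing to 100. Diameters outside the bin range are
#'   counted in the first/last bin with a warning.
#' @export
psd_from_diameters <- function(diameters, bins) {
  if (length(diameters) == 0L) stop("no diameters supplied")
  if (length(bins) < 2L || is.unsorted(bins, strictly = TRUE)) {
    stop("`bins` must be ascending edges with at least 2 values")
  }
  nb <- length(bins) - 1L
  idx <- findInterval(diameters, bins, rightmost.closed = TRUE)
  if (any(idx < 1L | idx > nb)) {
    warning("diameter(s) outside bin range counted in the end bins")
    idx <- pmin(pmax(idx, 1L), nb)
  }
  vol <- diameters^3
  out <- vapply(seq_len(nb), function(b) sum(vol[idx == b]), numeric(1))
  out <- out / sum(out) * 100
  names(out) <- (bins[-1] + bins[-length(bins)]) / 2
  out
}

#' Generate a synthetic IS/OOS image ensemble
#'
#' Produces the study-like layout: `n_samples` samples per condition, each
#' with `images_per_sample` images, plus per-sample pooled diameters for PSD
#' tables. In-specification samples use the unimodal default mixture with
#' uniform placement; out-of-specification samples the bimodal default with
#' clustered placement. Per-image seeds are derived deterministically from
#' `seed`, so the ensemble is fully reproducible.
#'
#' @param condition `"IS"` or `"OOS"`.
#' @param n_samples samples in the ensemble (default 3).
#' @param images_per_sample images per sample (default 2).
#' @param seed base integer seed.
#' @param scene base [scene_spec]; its placement is overridden by the
#'   condition default (`uniform` for IS, `clustered` for OOS).
#' @param render a [render_spec] (its seed field is ignored; per-image seeds
#'   are derived from `seed`).
#' @param n_particles particles per image (default 150).
#' @return List of class `synth_ensemble` with one element per sample:
#'   `sample_id`, `condition`, `images` (list of [gray_image]),
#'   `diameters` (pooled across the sample's images).
#' @export
synth_ensemble <- function(condition = c("IS", "OOS"), n_samples = 3,
                           images_per_sample = 2, seed = 1,
                           scene = scene_spec(), render = render_spec(),
                           n_particles = 60) {
  condition <- match.arg(condition)
  spec <- if (condition == "IS") is_particle_defaults(n_particles)
          else oos_particle_defaults(n_particles)
  scene$placement <- if (condition == "IS") "uniform" else "clustered"
  base <- as.integer(seed) %% 100000L
  off <- if (condition == "IS") 0L else 500L
  samples <- lapply(seq_len(n_samples), function(s) {
    imgs <- list()
    dia <- numeric(0)
    for (im in seq_len(images_per_sample)) {
      sd_i <- base * 1000L + off + s * 10L + im
      d <- sample_diameters(spec, seed = sd_i)
      r <- render
      r$seed <- sd_i + 1L
      img <- place_and_render(scene, d, r)
      img$source <- sprintf("synthetic/%s_S%02d_I%02d", condition, s, im)
      imgs[[im]] <- img
      dia <- c(dia, d)
    }
    list(sample_id = sprintf("%s_S%02d", condition, s),
         condition = condition, images = imgs, diameters = dia)
  })
  structure(samples, class = "synth_ensemble")
}
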