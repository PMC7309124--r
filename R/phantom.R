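#' Speckle texture parameters
#'
#' Parameters of one fully-developed speckle texture class. The four knobs
#' emulate the visual attributes that separate tumor from parenchyma in
#' B-mode imaging: speckle coarseness (`correlation_length`, the blur scale
#' of the scatterer field in pixels), echogenicity (`mean_brightness`),
#' large-scale inhomogeneity (`heterogeneity`, relative amplitude of a
#' smooth multiplicative gain field) and speckle contrast (`contrast_scale`,
#' multiplier on the log-compressed fluctuation; 1 maps one standard
#' deviation of speckle to roughly 30 gray levels).
#'
#' @param correlation_length Blur scale in pixels, `>= 0.5`.
#' @param mean_brightness Mean output intensity in `[0, 255]`.
#' @param heterogeneity Non-negative gain-field amplitude.
#' @param contrast_scale Non-negative contrast multiplier.
#' @return An object of class `texture_params`.
#' @export
texture_params <- function(correlation_length = 2, mean_brightness = 120,
                           heterogeneity = 0.2, contrast_scale = 1) {
  stopifnot(correlation_length >= 0.5, mean_brightness > 0,
            heterogeneity >= 0, contrast_scale >= 0)
  structure(list(correlation_length = correlation_length,
                 mean_brightness = mean_brightness,
                 heterogeneity = heterogeneity,
                 contrast_scale = contrast_scale),
            class = "texture_params")
}

#' Generate a fully-developed speckle texture
#'
#' Simulates B-mode speckle as the magnitude of a complex circular-Gaussian
#' scattering field blurred at `correlation_length` (the point-spread-scale),
#' multiplied by a smooth multiplicative gain field of relative amplitude
#' `heterogeneity`, log-compressed, and mapped to `[0, 255]` around
#' `mean_brightness`. Deterministic given `seed`.
#'
#' @param size `(height, width)` in pixels, both `>= 8`.
#' @param params A [texture_params()] object.
#' @param seed Integer seed.
#' @return Integer intensity matrix in `[0, 255]`.
#' @export
generate_speckle_texture <- function(size, params, seed) {
  stopifnot(inherits(params, "texture_params"),
            length(size) == 2L, all(size >= 8L))
  h <- as.integer(size[1L]); w <- as.integer(size[2L])
  with_seed(seed, {
    re <- matrix(rnorm(h * w), h, w)
    im <- matrix(rnorm(h * w), h, w)
    gain_noise <- matrix(rnorm(h * w), h, w)
  })
  sig <- params$correlation_length
  env <- sqrt(gaussian_blur(re, sig)^2 + gaussian_blur(im, sig)^2)
  env <- env / sqrt(mean(env^2))
  # low-frequency gain field at a fixed fraction of the image size
  g <- gaussian_blur(gain_noise, max(h, w) / 8)
  gsd <- sd(as.vector(g))
  g <- if (gsd > 0) g / gsd else g * 0
  gain <- pmax(1 + params$heterogeneity * pmin(pmax(g, -2), 2), 0.05)
  # log compression of the envelope; unit-variance then scaled so that
  # contrast_scale = 1 puts one speckle s.d. at ~30 gray levels
  v <- log1p(30 * env * gain)
  v <- v - mean(v)
  vsd <- sd(as.vector(v))
  if (vsd > 0) v <- v / vsd
  out <- params$mean_brightness + params$contrast_scale * 30 * v
  matrix(as.integer(round(pmin(pmax(out, 0), 255))), h, w)
}

#' Phantom specification
#'
#' Describes a two-texture speckle phantom: `outside_texture` everywhere and
#' `inside_texture` composited inside `lesion_polygon` (a [via_polygon()] or
#' `"auto-ellipse"`, which inscribes a 24-vertex ellipse centered in the
#' image). The lesion must keep a margin of at least 56 pixels to every
#' image border so that both classes admit valid 56-pixel patches.
#'
#' @param image_size `(height, width)` in pixels.
#' @param lesion_polygon A [via_polygon()] or the string `"auto-ellipse"`.
#' @param inside_texture,outside_texture [texture_params()] for the lesion
#'   interior (HCC stand-in) and the surrounding parenchyma stand-in.
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(400L, 400L),
                         lesion_polygon = "auto-ellipse",
                         inside_texture = texture_params(
                           correlation_length = 4, mean_brightness = 135,
                           heterogeneity = 0.3),
                         outside_texture = texture_params(
                           correlation_length = 1.5, mean_brightness = 120,
                           heterogeneity = 0.15),
                         seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 168L))
  h <- as.integer(image_size[1L]); w <- as.integer(image_size[2L])
  margin <- 56L
  if (identical(lesion_polygon, "auto-ellipse")) {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    rx <- (w - 1) / 2 - margin - 2; ry <- (h - 1) / 2 - margin - 2
    th <- seq(0, 2 * pi, length.out = 25L)[-25L]
    lesion_polygon <- via_polygon(cx + rx * cos(th), cy + ry * sin(th), "HCC")
  }
  stopifnot(inherits(lesion_polygon, "via_polygon"))
  v <- lesion_polygon$vertices
  if (min(v[, 1L]) < margin || max(v[, 1L]) > w - 1L - margin ||
      min(v[, 2L]) < margin || max(v[, 2L]) > h - 1L - margin) {
    stop("lesion polygon must keep a ", margin, "-pixel margin to the borders")
  }
  structure(list(image_size = c(h, w), lesion_polygon = lesion_polygon,
                 inside_texture = inside_texture,
                 outside_texture = outside_texture,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Boolean lesion mask at pixel centers (0-based coordinates).
polygon_mask <- function(vert, h, w) {
  xs <- rep(seq_len(w) - 1L, each = h)
  ys <- rep(seq_len(h) - 1L, times = w)
  matrix(points_in_polygon(xs, ys, vert), h, w)
}

#' Generate an annotated speckle phantom
#'
#' Renders the two textures of a [phantom_spec()] and composites the inside
#' texture within the lesion polygon, blending the transition over a
#' 2-pixel border to emulate the diffuse tumor/parenchyma interface. The
#' lesion polygon is attached as an HCC annotation.
#'
#' @param spec A [phantom_spec()].
#' @param patient_id,device_tag Provenance attached to the result.
#' @return An [annotated_image()].
#' @export
generate_annotated_phantom <- function(spec, patient_id = "phantom",
                                       device_tag = "SYN") {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  seeds <- split_seeds(spec$seed, 2L)
  outside <- generate_speckle_texture(c(h, w), spec$outside_texture, seeds[1L])
  inside <- generate_speckle_texture(c(h, w), spec$inside_texture, seeds[2L])
  mask <- polygon_mask(spec$lesion_polygon$vertices, h, w)
  alpha <- gaussian_blur(matrix(as.numeric(mask), h, w), 1) # ~2 px transition
  px <- round(alpha * inside + (1 - alpha) * outside)
  annotated_image(pmin(pmax(px, 0), 255),
                  annotations = list(spec$lesion_polygon),
                  patient_id = patient_id, device_tag = device_tag)
}

#' Generate a phantom patient cohort
#'
#' Emulates a clinical acquisition campaign: each synthetic patient gets a
#' small seeded perturbation of the template texture parameters (lesions
#' differ across patients, are stable within a patient) and
#' `images_per_patient` independently speckled frames. All randomness flows
#' from `seed` through a splittable stream, so the cohort is reproducible
#' and its members independent.
#'
#' @param n_patients Number of patients, `>= 1`.
#' @param images_per_patient Frames per patient, in `[1, 1000]` (clinical
#'   annotation counts ran from 3 to 35 per patient).
#' @param spec_template A [phantom_spec()] used as the template.
#' @param seed Integer master seed.
#' @return List of [annotated_image()] with unique `patient_id`s.
#' @export
generate_cohort <- function(n_patients, images_per_patient,
                            spec_template = phantom_spec(), seed = 1L) {
  stopifnot(n_patients >= 1L)
  if (images_per_patient < 1L || images_per_patient > 1000L) {
    stop("images_per_patient must lie in [1, 1000]")
  }
  patient_seeds <- split_seeds(seed, n_patients)
  out <- vector("list", n_patients * images_per_patient)
  k <- 0L
  for (p in seq_len(n_patients)) {
    # acquisition-level jitter: one factor set per patient, applied to both
    # tissue classes (gain/depth settings act on the whole frame, so the
    # inside/outside contrast of the template is preserved exactly — a null
    # template stays null)
    jit <- with_seed(patient_seeds[p], {
      list(cl = exp(rnorm(1L, 0, 0.08)),   # correlation-length factor
           br = rnorm(1L, 0, 4),           # brightness offset
           het = exp(rnorm(1L, 0, 0.15)),  # heterogeneity factor
           img = sample.int(.Machine$integer.max - 1L, images_per_patient))
    })
    jitter_tex <- function(tp) {
      texture_params(
        correlation_length = max(0.5, tp$correlation_length * jit$cl),
        mean_brightness = min(250, max(5, tp$mean_brightness + jit$br)),
        heterogeneity = tp$heterogeneity * jit$het,
        contrast_scale = tp$contrast_scale)
    }
    ins <- jitter_tex(spec_template$inside_texture)
    outs <- jitter_tex(spec_template$outside_texture)
    pid <- sprintf("SYN%03d", p)
    for (i in seq_len(images_per_patient)) {
      sp <- phantom_spec(image_size = spec_template$image_size,
                         lesion_polygon = spec_template$lesion_polygon,
                         inside_texture = ins, outside_texture = outs,
                         seed = jit$img[i])
      k <- k + 1L
      out[[k]] <- generate_annotated_phantom(sp, patient_id = pid)
    }
  }
  out
}

#' Write a cohort to disk as PNG images plus a VIA annotation file
#'
#' @param cohort List of [annotated_image()] (e.g. from [generate_cohort()]).
#' @param out_dir Output directory (created if needed).
#' @param annotations_file Name of the VIA JSON written inside `out_dir`.
#' @return Path of the annotation file, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, annotations_file = "via_annotations.json") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  filenames <- sprintf("%s_img%03d.png",
                       vapply(cohort, function(x) x$patient_id, character(1L)),
                       stats::ave(seq_along(cohort),
                                  vapply(cohort, function(x) x$patient_id,
                                         character(1L)),
                                  FUN = seq_along))
  for (i in seq_along(cohort)) {
    write_gray_image(cohort[[i]], file.path(out_dir, filenames[i]))
  }
  write_via_annotations(cohort, filenames,
                        file.path(out_dir, annotations_file),
                        image_store = out_dir)
}
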