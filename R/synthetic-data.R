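# Synthetic fundus-like images and planted-signal feature matrices.
#
# The image generator emulates the visual logic of retinopathy grading:
# a dark background, a circular retina disc, a bright optic disc, curvilinear
# vessels, and a lesion load whose expected count grows with the grade.
# Placement follows posterior-pole anatomy: dark hemorrhage-like lesions
# cluster in the macular zone, bright hard-exudate-like blobs form a
# circinate ring around it, and vessels deflect off the foveal avascular
# zone. Higher grade = more lesions; class 0 (normal) carries none. No claim
# of photorealism.

#' Synthetic fundus dataset specification
#'
#' @param n_per_class images per class.
#' @param n_classes 3 (normal / NPDR-like / PDR-like) or 5 (the five-grade
#'   scheme of open DR datasets).
#' @param image_side canvas edge (default 256).
#' @param lesion_rate per-class expected count of dark lesions; default
#'   `6 * grade` (grade 0 = normal has none).
#' @param exudate_rate per-class expected count of bright blobs; default
#'   `3 * grade`.
#' @param vessel_count vessels per image (default 6).
#' @param noise_sd Gaussian pixel-noise standard deviation on the 8-bit
#'   scale (default 5).
#' @param seed integer seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_per_class = 50L, n_classes = 3L, image_side = 256L,
                       lesion_rate = NULL, exudate_rate = NULL,
                       vessel_count = 6L, noise_sd = 5, seed = 42L) {
  n_classes <- as.integer(n_classes)
  if (!n_classes %in% c(3L, 5L)) {
    stop("synth_spec: `n_classes` must be 3 or 5")
  }
  grades <- 0:(n_classes - 1L)
  if (is.null(lesion_rate)) lesion_rate <- 6 * grades
  if (is.null(exudate_rate)) exudate_rate <- 3 * grades
  if (length(lesion_rate) != n_classes || length(exudate_rate) != n_classes ||
      any(lesion_rate < 0) || any(exudate_rate < 0)) {
    stop("synth_spec: rates must be nonnegative vectors of length `n_classes`")
  }
  if (n_per_class < 1L) stop("synth_spec: `n_per_class` must be >= 1")
  if (noise_sd < 0) stop("synth_spec: `noise_sd` must be >= 0")
  structure(list(n_per_class = as.integer(n_per_class), n_classes = n_classes,
                 image_side = as.integer(image_side),
                 lesion_rate = lesion_rate, exudate_rate = exudate_rate,
                 vessel_count = as.integer(vessel_count), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Add a filled disc of radius r at centre (cr, cc), colour col (length 3),
# alpha-blended with weight `alpha` falling off at the rim.
.stamp_disc <- function(px, cr, cc, r, col, alpha = 1) {
  side <- dim(px)[1L]
  rows <- max(1L, floor(cr - r)):min(side, ceiling(cr + r))
  cols <- max(1L, floor(cc - r)):min(side, ceiling(cc + r))
  if (length(rows) == 0L || length(cols) == 0L) return(px)
  dist2 <- outer((rows - cr)^2, (cols - cc)^2, "+")
  mask <- dist2 <= r^2
  if (!any(mask)) return(px)
  a <- alpha * pmin(1, (r^2 - dist2[mask]) / max(r^2 * 0.4, 1))
  for (ch in 1:3) {
    block <- px[rows, cols, ch]
    block[mask] <- (1 - a) * block[mask] + a * col[ch]
    px[rows, cols, ch] <- block
  }
  px
}

.synth_one_image <- function(side, grade, spec) {
  px <- array(15, dim = c(side, side, 3L))           # dark surround
  centre <- side / 2
  disc_r <- 0.45 * side
  # retina disc with mild radial falloff
  px <- .stamp_disc(px, centre, centre, disc_r, c(175, 90, 45), alpha = 1)
  px <- .stamp_disc(px, centre, centre, disc_r * 0.75, c(190, 100, 50), alpha = 0.5)
  # optic disc (bright blob, nasal side) and macula (temporal side)
  od <- c(centre - 0.05 * side, centre + 0.22 * side)
  mac <- c(centre + 0.02 * side, centre - 0.20 * side)
  px <- .stamp_disc(px, od[1L], od[2L], 0.07 * side, c(235, 205, 130), alpha = 0.95)
  # vessels: constant-length random walks from the optic disc, reflected at
  # the disc rim and off the foveal avascular zone, so total vessel mass is
  # a class-independent constant and only its placement varies
  faz_r <- 0.125 * side
  for (v in seq_len(spec$vessel_count)) {
    pos <- od
    ang <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(120L)) {
      ang <- ang + stats::rnorm(1, 0, 0.25)
      step <- 2.2 * c(sin(ang), cos(ang))
      if (sqrt(sum((pos + step - centre)^2)) > disc_r * 0.92) {
        ang <- atan2(centre - pos[1L], centre - pos[2L]) + stats::rnorm(1, 0, 0.3)
        step <- 2.2 * c(sin(ang), cos(ang))
      }
      if (sqrt(sum((pos + step - mac)^2)) < faz_r) {
        ang <- atan2(pos[1L] - mac[1L], pos[2L] - mac[2L]) + stats::rnorm(1, 0, 0.3)
        step <- 2.2 * c(sin(ang), cos(ang))
      }
      pos <- pos + step
      px <- .stamp_disc(px, pos[1L], pos[2L], 1.6, c(120, 40, 30), alpha = 0.8)
    }
  }
  # hemorrhage-like lesions cluster in the macular zone; radii span
  # microaneurysm-like dots to blot hemorrhages, large enough to survive
  # the canvas -> backend-input downsample
  for (l in seq_len(stats::rpois(1, spec$lesion_rate[grade + 1L]))) {
    p <- mac + stats::rnorm(2, 0, 0.06 * side)
    px <- .stamp_disc(px, p[1L], p[2L], stats::runif(1, 3, 7), c(70, 20, 15))
  }
  # hard-exudate-like bright blobs in a circinate ring around the macula
  for (e in seq_len(stats::rpois(1, spec$exudate_rate[grade + 1L]))) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::rnorm(1, 0.18 * side, 0.023 * side)
    p <- mac + rad * c(sin(ang), cos(ang))
    px <- .stamp_disc(px, p[1L], p[2L], stats::runif(1, 3, 8), c(225, 215, 140))
  }
  if (spec$noise_sd > 0) {
    px <- px + array(stats::rnorm(length(px), 0, spec$noise_sd), dim = dim(px))
  }
  pmin(pmax(round(px), 0), 255)
}

#' Generate a labeled synthetic fundus dataset
#'
#' Produces `n_per_class * n_classes` images (grades interleaved
#' 0,1,...,C-1,0,1,...) with aligned labels. Deterministic per `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return List with `images` (list of [fundus_image()]) and `labels`
#'   (factor of grades `0..n_classes-1`, aligned).
#' @export
generate_images <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  grades <- rep(0:(spec$n_classes - 1L), times = spec$n_per_class)
  images <- .with_preserved_rng(spec$seed, {
    lapply(seq_along(grades), function(k) {
      fundus_image(.synth_one_image(spec$image_side, grades[k], spec),
                   source_id = sprintf("synth_%03d_g%d", k, grades[k]),
                   label = grades[k])
    })
  })
  list(images = images, labels = factor(grades, levels = 0:(spec$n_classes - 1L)))
}

#' Write a synthetic dataset as PNGs plus a labels CSV
#'
#' Files land in `dir` as `<source_id>.png` with a `labels.csv`
#' (`filename,label`) in the format [read_labels_csv()] expects.
#'
#' @param dataset output of [generate_images()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_image_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fns <- vapply(dataset$images, function(im) paste0(im$source_id, ".png"),
                character(1L))
  for (k in seq_along(dataset$images)) {
    write_image(dataset$images[[k]], file.path(dir, fns[k]))
  }
  utils::write.csv(data.frame(filename = fns,
                              label = as.character(dataset$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Planted-signal feature matrix specification
#'
#' @param n samples; `D` features; `n_informative` features carrying signal.
#' @param D,n_informative see above.
#' @param effect_size between-class mean shift per grade step, in units of
#'   the unit noise standard deviation.
#' @param n_classes number of balanced classes.
#' @param seed integer seed.
#' @return A list of class `planted_matrix_spec`.
#' @export
planted_matrix_spec <- function(n = 200L, D = 50L, n_informative = 10L,
                                effect_size = 1.5, n_classes = 3L, seed = 7L) {
  if (n_informative > D) stop("planted_matrix_spec: `n_informative` must be <= D")
  if (n < n_classes) stop("planted_matrix_spec: need at least one sample per class")
  structure(list(n = as.integer(n), D = as.integer(D),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, n_classes = as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "planted_matrix_spec")
}

#' Generate a feature matrix with planted informative columns
#'
#' Noise features are standard normal; each informative feature is shifted by
#' `effect_size * (grade - mean(grade))` so classes differ in mean only on
#' the planted columns. Ground-truth indices are returned for recovery tests.
#'
#' @param spec a [planted_matrix_spec()].
#' @return List with `X` (`n x D` matrix), `y` (factor of grades) and
#'   `informative` (1-based planted column indices, ascending).
#' @export
generate_planted_matrix <- function(spec) {
  stopifnot(inherits(spec, "planted_matrix_spec"))
  .with_preserved_rng(spec$seed, {
    grades <- rep_len(0:(spec$n_classes - 1L), spec$n)
    X <- matrix(stats::rnorm(spec$n * spec$D), spec$n, spec$D)
    informative <- sort(sample.int(spec$D, spec$n_informative))
    shift <- spec$effect_size * (grades - mean(grades))
    X[, informative] <- X[, informative] + shift
    list(X = X, y = factor(grades, levels = 0:(spec$n_classes - 1L)),
         informative = informative)
  })
}
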