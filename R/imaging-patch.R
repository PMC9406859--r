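# Image loading, canvas resizing and the fixed 4-quadrant / 8-patch division.
#
# Internal pixel convention: a fundus image is a rows x cols x 3 numeric array
# with values in [0, 255] (8-bit scale). EBImage stores images x-first (width,
# height, channel) in [0, 1]; conversion happens only at the file boundary.

#' Construct a fundus image object
#'
#' Wraps a `rows x cols x 3` pixel array (values on the 8-bit scale, 0--255)
#' together with a source identifier and an optional class label. Grayscale
#' matrices are promoted to three identical channels.
#'
#' @param pixels numeric array `rows x cols x 3`, or a matrix (grayscale).
#' @param source_id character scalar naming the image (file name, synthetic id).
#' @param label optional class label (kept as-is; factors recommended).
#' @return An object of class `fundus_image` with elements `pixels`,
#'   `source_id`, `label`.
#' @export
fundus_image <- function(pixels, source_id = "<memory>", label = NULL) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L) {
    stop("fundus_image: `pixels` must be rows x cols x 3 (or a grayscale matrix)")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("fundus_image: pixel values must be finite and within [0, 255]")
  }
  storage.mode(pixels) <- "double"     # canonical storage for bitwise checks
  structure(
    list(pixels = pixels, source_id = as.character(source_id), label = label),
    class = "fundus_image"
  )
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image> %s: %d x %d x %d, label: %s\n",
              x$source_id, d[1L], d[2L], d[3L],
              if (is.null(x$label)) "<none>" else as.character(x$label)))
  invisible(x)
}

#' Load a fundus photograph from a PNG or JPEG file
#'
#' Reads an image file into the package's `rows x cols x 3` 8-bit convention.
#' Grayscale images are replicated across three channels; an alpha channel is
#' dropped with a warning.
#'
#' @param path path to a decodable PNG or JPEG file.
#' @param label optional class label to attach.
#' @return A [fundus_image()].
#' @export
load_image <- function(path, label = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("load_image: file does not exist: '%s'", path))
  }
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) {
      stop(sprintf("load_image: cannot decode '%s' (%s)", path, conditionMessage(e)))
    }
  )
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) {                     # grayscale -> replicate
    dat <- array(rep(dat, 3L), dim = c(dim(dat), 3L))
  } else if (dim(dat)[3L] == 4L) {                  # RGBA -> drop alpha
    warning(sprintf("load_image: dropping alpha channel of '%s'", path))
    dat <- dat[, , 1:3, drop = FALSE]
  } else if (dim(dat)[3L] == 2L) {                  # gray + alpha
    warning(sprintf("load_image: dropping alpha channel of '%s'", path))
    dat <- array(rep(dat[, , 1L], 3L), dim = c(dim(dat)[1:2], 3L))
  } else if (dim(dat)[3L] != 3L) {
    stop(sprintf("load_image: unsupported channel count %d in '%s'",
                 dim(dat)[3L], path))
  }
  px <- aperm(dat, c(2L, 1L, 3L)) * 255             # x,y,c -> rows,cols,c
  fundus_image(round(px), source_id = basename(path), label = label)
}

#' Write a fundus image to a PNG file
#'
#' @param img a [fundus_image()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "fundus_image"))
  e <- EBImage::Image(aperm(img$pixels / 255, c(2L, 1L, 3L)),
                      colormode = "Color")
  EBImage::writeImage(e, path)
  invisible(path)
}

# Separable resampling weights: n_out x n_in row-stochastic matrix mapping
# input sample positions to output positions with the half-pixel-centre
# convention  src = (dst + 0.5) * n_in / n_out - 0.5, edge-clamped.
.resample_weights <- function(n_out, n_in, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5   # 0-based src coords
  W <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    idx <- pmin(pmax(floor(src + 0.5), 0), n_in - 1L)
    W[cbind(seq_len(n_out), idx + 1L)] <- 1
  } else {
    lo <- floor(src)
    frac <- src - lo
    lo <- pmin(pmax(lo, 0), n_in - 1L)
    hi <- pmin(lo + 1L, n_in - 1L)
    W[cbind(seq_len(n_out), lo + 1L)] <- W[cbind(seq_len(n_out), lo + 1L)] + (1 - frac)
    W[cbind(seq_len(n_out), hi + 1L)] <- W[cbind(seq_len(n_out), hi + 1L)] + frac
  }
  W
}

# Resample a rows x cols (x 3) array to out_rows x out_cols. Returns doubles.
.resample_array <- function(px, out_rows, out_cols, method = "bilinear") {
  d <- dim(px)
  Wr <- .resample_weights(out_rows, d[1L], method)
  Wc <- .resample_weights(out_cols, d[2L], method)
  if (length(d) == 2L) return(Wr %*% px %*% t(Wc))
  out <- array(0, dim = c(out_rows, out_cols, d[3L]))
  for (ch in seq_len(d[3L])) out[, , ch] <- Wr %*% px[, , ch] %*% t(Wc)
  out
}

#' Resize a fundus image to the square analysis canvas
#'
#' Resamples anisotropically (no letterboxing) to `side x side` using the
#' chosen interpolation. An input already at the target size is returned
#' unchanged. Output pixels are rounded back to the 8-bit scale.
#'
#' @param img a [fundus_image()].
#' @param side even integer edge length of the square canvas (default 256).
#' @param method interpolation, `"bilinear"` (default) or `"nearest"`.
#' @return A [fundus_image()] of size `side x side x 3`.
#' @export
resize_to_canvas <- function(img, side = 256L, method = "bilinear") {
  stopifnot(inherits(img, "fundus_image"))
  side <- as.integer(side)
  if (side < 2L || side %% 2L != 0L) {
    stop("resize_to_canvas: `side` must be an even integer >= 2 (quadrants must be equal)")
  }
  d <- dim(img$pixels)
  if (d[1L] == side && d[2L] == side) return(img)
  out <- .resample_array(img$pixels, side, side, method)
  fundus_image(pmin(pmax(round(out), 0), 255),
               source_id = img$source_id, label = img$label)
}

# Fixed patch geometry on a side x side canvas (half = side/2, q = side/4):
# quadrants UL, UR, LL, LR; UL and LR cut horizontally (wide, short patches),
# UR and LL cut vertically (tall, narrow patches).
.patch_layout <- function(side = 256L) {
  h <- side %/% 2L; q <- side %/% 4L
  list(
    list(index = 1L, quadrant = "UL", orientation = "horizontal",
         rows = c(0L, q),      cols = c(0L, h)),
    list(index = 2L, quadrant = "UL", orientation = "horizontal",
         rows = c(q, h),       cols = c(0L, h)),
    list(index = 3L, quadrant = "UR", orientation = "vertical",
         rows = c(0L, h),      cols = c(h, h + q)),
    list(index = 4L, quadrant = "UR", orientation = "vertical",
         rows = c(0L, h),      cols = c(h + q, side)),
    list(index = 5L, quadrant = "LL", orientation = "vertical",
         rows = c(h, side),    cols = c(0L, q)),
    list(index = 6L, quadrant = "LL", orientation = "vertical",
         rows = c(h, side),    cols = c(q, h)),
    list(index = 7L, quadrant = "LR", orientation = "horizontal",
         rows = c(h, h + q),   cols = c(h, side)),
    list(index = 8L, quadrant = "LR", orientation = "horizontal",
         rows = c(h + q, side), cols = c(h, side))
  )
}

#' Divide a canvas-sized fundus image into the eight oriented patches
#'
#' The 256x256 canvas is split into four 128x128 quadrants; the upper-left and
#' lower-right quadrants are cut horizontally (two 64-row x 128-col patches,
#' top before bottom), the upper-right and lower-left vertically (two 128-row
#' x 64-col patches, left before right). The eight patches tile the canvas
#' exactly, in the fixed order P1..P8.
#'
#' @param img a [fundus_image()] already resized to the square canvas.
#' @return An object of class `patch_set`: list with `main` (the input) and
#'   `patches`, a list of eight `patch` objects with fields `pixels`, `index`,
#'   `quadrant`, `orientation`, `origin` (0-based `(row, col)` offset).
#' @export
divide_into_patches <- function(img) {
  stopifnot(inherits(img, "fundus_image"))
  d <- dim(img$pixels)
  if (d[1L] != d[2L] || d[1L] %% 4L != 0L) {
    stop(sprintf(paste0("divide_into_patches: requires a square canvas with side ",
                        "divisible by 4 (e.g. 256x256); got %d x %d ",
                        "- call resize_to_canvas() first"), d[1L], d[2L]))
  }
  patches <- lapply(.patch_layout(d[1L]), function(p) {
    structure(
      list(
        pixels = img$pixels[(p$rows[1L] + 1L):p$rows[2L],
                            (p$cols[1L] + 1L):p$cols[2L], , drop = FALSE],
        index = p$index, quadrant = p$quadrant, orientation = p$orientation,
        origin = c(row = p$rows[1L], col = p$cols[1L])
      ),
      class = "patch"
    )
  })
  structure(list(main = img, patches = patches), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> main %dx%d (%s), 8 patches:\n",
              dim(x$main$pixels)[1L], dim(x$main$pixels)[2L], x$main$source_id))
  for (p in x$patches) {
    cat(sprintf("  P%d %s %-10s %3dx%3d @ (%d,%d)\n", p$index, p$quadrant,
                p$orientation, dim(p$pixels)[1L], dim(p$pixels)[2L],
                p$origin[["row"]], p$origin[["col"]]))
  }
  invisible(x)
}

#' Reassemble a patch set back into its canvas
#'
#' Places every patch at its recorded origin. Used to verify that the division
#' is an exact partition of the canvas.
#'
#' @param ps a `patch_set` from [divide_into_patches()].
#' @return A pixel array of the main image's dimensions.
#' @export
reassemble_patches <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  out <- array(NA_real_, dim = dim(ps$main$pixels))
  for (p in ps$patches) {
    pr <- dim(p$pixels)[1L]; pc <- dim(p$pixels)[2L]
    rows <- (p$origin[["row"]] + 1L):(p$origin[["row"]] + pr)
    cols <- (p$origin[["col"]] + 1L):(p$origin[["col"]] + pc)
    if (!all(is.na(out[rows, cols, ]))) {
      stop("reassemble_patches: overlapping patches")
    }
    out[rows, cols, ] <- p$pixels
  }
  if (anyNA(out)) stop("reassemble_patches: patches do not cover the canvas")
  out
}

#' Read a `filename,label` table
#'
#' Labels CSV contract: UTF-8, header required, two columns `filename` and
#' `label`.
#'
#' @param path CSV file path.
#' @return data.frame with character `filename` and factor `label`.
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_labels_csv: no such file: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("filename", "label") %in% names(df))) {
    stop("read_labels_csv: CSV must have header columns 'filename' and 'label'")
  }
  df$label <- factor(df$label)
  df[, c("filename", "label")]
}
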