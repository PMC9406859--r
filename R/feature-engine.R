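# Embedding backends and construction of the concatenated deep-feature matrix.
#
# A backend maps one image to two feature vectors: the activations of a
# 1000-way classification layer ("fc", pre-softmax) and of a global-average-
# pool layer ("pool", 1920-wide for DenseNet201). One fundus image contributes
# nine inputs (main canvas + 8 patches), hence 9 * (fc_dim + pool_dim)
# concatenated features — 26,280 with the published dimensions.

#' Construct an embedding backend
#'
#' A backend bundles its dimensions with an `embed_fn(backend, pixels)` that
#' receives a `input_side x input_side x 3` array on the 8-bit scale and must
#' return `list(fc = <numeric fc_dim>, pool = <numeric pool_dim>)`
#' deterministically.
#'
#' @param name backend name.
#' @param input_side square input edge expected by the network.
#' @param fc_dim width of the classification layer (1000 for DenseNet201).
#' @param pool_dim width of the global-average-pool layer (1920 for DenseNet201).
#' @param embed_fn the embedding function (see Details).
#' @param meta optional list of extra metadata stored with feature matrices.
#' @return An object of class `embedding_backend`.
#' @export
embedding_backend <- function(name, input_side, fc_dim, pool_dim, embed_fn,
                              meta = list()) {
  stopifnot(is.function(embed_fn), input_side >= 1, fc_dim >= 1, pool_dim >= 1)
  structure(
    list(name = name, input_side = as.integer(input_side),
         fc_dim = as.integer(fc_dim), pool_dim = as.integer(pool_dim),
         embed_fn = embed_fn, meta = meta),
    class = "embedding_backend"
  )
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat(sprintf("<embedding_backend> %s: input %dx%d, fc %d + pool %d = %d features/input\n",
              x$name, x$input_side, x$input_side, x$fc_dim, x$pool_dim,
              x$fc_dim + x$pool_dim))
  invisible(x)
}

#' Deterministic stub backend for offline testing
#'
#' A fixed random linear projection (no bias) of the grayscale image: the
#' input is averaged across channels, scaled to `[0, 1]`, flattened
#' (`input_side^2` values, default 32x32 = 1024) and multiplied by two frozen
#' Gaussian matrices drawn once from `seed`. Linear and bias-free, so the
#' all-zero image embeds to zero vectors, and class signal that survives the
#' 32x32 downsample (lesion load, bright blobs) survives the projection.
#'
#' @param fc_dim,pool_dim output widths (defaults match DenseNet201: 1000, 1920).
#' @param input_side square input edge (default 32).
#' @param seed integer seed freezing the projection matrices.
#' @return An `embedding_backend`.
#' @export
stub_backend <- function(fc_dim = 1000L, pool_dim = 1920L, input_side = 32L,
                         seed = 1L) {
  n_in <- as.integer(input_side)^2
  W <- .with_preserved_rng(seed, {
    list(fc = matrix(stats::rnorm(n_in * fc_dim), n_in, fc_dim) / sqrt(n_in),
         pool = matrix(stats::rnorm(n_in * pool_dim), n_in, pool_dim) / sqrt(n_in))
  })
  embed_fn <- function(backend, pixels) {
    gray <- (pixels[, , 1L] + pixels[, , 2L] + pixels[, , 3L]) / 3 / 255
    v <- as.numeric(gray)                       # column-major flatten
    list(fc = as.numeric(v %*% W$fc), pool = as.numeric(v %*% W$pool))
  }
  embedding_backend("stub", input_side, fc_dim, pool_dim, embed_fn,
                    meta = list(seed = as.integer(seed)))
}

#' Pretrained DenseNet201 backend (requires external weights)
#'
#' Carries the published dimensions (224x224 input, fc1000 + avg_pool =
#' 1000 + 1920 features). No deep-learning runtime ships with this package,
#' so calling [embed()] on the default object signals an environment error;
#' supply `embed_fn` wrapping your own forward pass (e.g. reticulate +
#' torchvision's `densenet201(weights="IMAGENET1K_V1")`, reading the
#' pre-softmax classifier and the global-average-pool activations) to use
#' real weights. Inputs should be scaled to `[0, 1]` and standardized with
#' the ImageNet channel means/deviations the pretrained weights assume.
#'
#' @param embed_fn optional user-supplied embedding function.
#' @return An `embedding_backend`.
#' @export
densenet201_backend <- function(embed_fn = NULL) {
  if (is.null(embed_fn)) {
    embed_fn <- function(backend, pixels) {
      stop(paste0("densenet201_backend: no DenseNet201 weights/runtime available ",
                  "in this R session. Supply densenet201_backend(embed_fn=...) ",
                  "wrapping a pretrained forward pass (e.g. via reticulate + ",
                  "torchvision), or use stub_backend() for offline work."),
           call. = FALSE)
    }
  }
  embedding_backend("densenet201", 224L, 1000L, 1920L, embed_fn)
}

#' Embed one image with a backend
#'
#' Resizes the pixel array (any `rows x cols x 3`, e.g. a 64x128 patch) to the
#' backend's square input side with bilinear interpolation, then calls the
#' backend's embedding function. Backend-specific channel normalization is the
#' embedding function's responsibility.
#'
#' @param backend an [embedding_backend()].
#' @param img a [fundus_image()], `patch`, or raw `rows x cols x 3` array.
#' @return `list(fc = <fc_dim vector>, pool = <pool_dim vector>)`.
#' @export
embed <- function(backend, img) {
  stopifnot(inherits(backend, "embedding_backend"))
  px <- if (inherits(img, c("fundus_image", "patch"))) img$pixels else img
  if (length(dim(px)) != 3L || dim(px)[3L] != 3L) {
    stop("embed: input must be a 3-channel rows x cols x 3 array")
  }
  s <- backend$input_side
  if (dim(px)[1L] != s || dim(px)[2L] != s) {
    px <- .resample_array(px, s, s, "bilinear")
  }
  out <- backend$embed_fn(backend, px)
  if (length(out$fc) != backend$fc_dim || length(out$pool) != backend$pool_dim) {
    stop(sprintf("embed: backend '%s' returned %d/%d features, declared %d/%d",
                 backend$name, length(out$fc), length(out$pool),
                 backend$fc_dim, backend$pool_dim))
  }
  out
}

#' Extract the per-input feature vector
#'
#' Concatenation `[fc | pool]` of the two layer read-outs — 2920 features per
#' input with the DenseNet201 dimensions.
#'
#' @inheritParams embed
#' @return Numeric vector of length `fc_dim + pool_dim`.
#' @export
extract_input_features <- function(backend, img) {
  e <- embed(backend, img)
  c(e$fc, e$pool)
}

#' Extract the concatenated patch-set feature vector
#'
#' Runs the backend over the main canvas and the eight patches in the fixed
#' order main, P1..P8 and concatenates the per-input vectors: length
#' `9 * (fc_dim + pool_dim)`, i.e. 26,280 with the published dimensions.
#'
#' @param backend an [embedding_backend()].
#' @param ps a `patch_set` from [divide_into_patches()].
#' @return Numeric vector of length `9 * (fc_dim + pool_dim)`.
#' @export
extract_patchset_features <- function(backend, ps) {
  stopifnot(inherits(ps, "patch_set"))
  inputs <- c(list(ps$main), ps$patches)
  unlist(lapply(inputs, function(im) extract_input_features(backend, im)),
         use.names = FALSE)
}

#' Column provenance of the concatenated feature vector
#'
#' @param backend an [embedding_backend()].
#' @return data.frame with one row per feature column: `source` (`main`,
#'   `P1`..`P8`), `layer` (`fc`/`pool`) and `index` within the layer.
#' @export
feature_provenance <- function(backend) {
  stopifnot(inherits(backend, "embedding_backend"))
  sources <- c("main", paste0("P", 1:8))
  per_input <- data.frame(
    layer = rep(c("fc", "pool"), c(backend$fc_dim, backend$pool_dim)),
    index = c(seq_len(backend$fc_dim), seq_len(backend$pool_dim))
  )
  out <- do.call(rbind, lapply(sources, function(s) cbind(source = s, per_input)))
  rownames(out) <- NULL
  out
}

#' Build the feature matrix for a list of images
#'
#' Each image is resized to the analysis canvas, divided into patches, and
#' embedded; row k of the result is the concatenated feature vector of image
#' k. Failing images abort the run with a summary of all per-image errors, or
#' are dropped with a warning when `skip_errors = TRUE`.
#'
#' @param backend an [embedding_backend()].
#' @param images nonempty list of [fundus_image()] objects.
#' @param labels optional label vector aligned with `images`; when `NULL`,
#'   labels attached to the images are used if present.
#' @param canvas_side analysis canvas edge (default 256).
#' @param skip_errors drop failing images instead of aborting.
#' @return Object of class `feature_matrix`: list with `values`
#'   (`N x 9*(fc_dim+pool_dim)` matrix), `labels` (factor or `NULL`),
#'   `provenance` (see [feature_provenance()]) and `backend_info`.
#' @export
build_feature_matrix <- function(backend, images, labels = NULL,
                                 canvas_side = 256L, skip_errors = FALSE) {
  stopifnot(inherits(backend, "embedding_backend"))
  if (!is.list(images) || length(images) == 0L) {
    stop("build_feature_matrix: `images` must be a nonempty list of fundus images")
  }
  if (is.null(labels)) {
    labs <- lapply(images, function(im) im$label)
    if (!any(vapply(labs, is.null, logical(1L)))) {
      labels <- unlist(lapply(labs, as.character))
    }
  } else if (length(labels) != length(images)) {
    stop("build_feature_matrix: `labels` length must match `images`")
  }
  D <- 9L * (backend$fc_dim + backend$pool_dim)
  X <- matrix(NA_real_, length(images), D)
  errors <- character(0)
  for (k in seq_along(images)) {
    row <- tryCatch({
      ps <- divide_into_patches(resize_to_canvas(images[[k]], canvas_side))
      extract_patchset_features(backend, ps)
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<-
        sprintf("image %d (%s): %s", k, images[[k]]$source_id, conditionMessage(e))
      NULL
    })
    if (!is.null(row)) X[k, ] <- row
  }
  if (length(errors) > 0L) {
    msg <- sprintf("%d/%d images failed:\n%s", length(errors), length(images),
                   paste(errors, collapse = "\n"))
    if (!skip_errors) stop("build_feature_matrix: ", msg)
    warning("build_feature_matrix: dropping failed images; ", msg)
    keep <- !is.na(X[, 1L])
    X <- X[keep, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[keep]
  }
  structure(
    list(values = X,
         labels = if (is.null(labels)) NULL else factor(labels),
         provenance = feature_provenance(backend),
         backend_info = list(name = backend$name, input_side = backend$input_side,
                             fc_dim = backend$fc_dim, pool_dim = backend$pool_dim,
                             meta = backend$meta)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (%s backend)%s\n",
              nrow(x$values), ncol(x$values), x$backend_info$name,
              if (is.null(x$labels)) "" else
                sprintf(", %d classes", nlevels(x$labels))))
  invisible(x)
}

#' Persist / reload a feature matrix
#'
#' The array goes to an `.rds` file; provenance and backend metadata go to a
#' JSON sidecar (`<path>.json`) so runs remain auditable without loading R.
#'
#' @param fm a `feature_matrix`.
#' @param path output `.rds` path.
#' @return `path` (write) or the restored `feature_matrix` (read).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  saveRDS(fm, path)
  sidecar <- list(
    n = nrow(fm$values), d = ncol(fm$values),
    labels = if (is.null(fm$labels)) NULL else as.character(fm$labels),
    backend = fm$backend_info,
    provenance_blocks = as.list(table(fm$provenance$source))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  fm <- readRDS(path)
  if (!inherits(fm, "feature_matrix")) {
    stop(sprintf("read_feature_matrix: '%s' does not contain a feature matrix", path))
  }
  fm
}
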