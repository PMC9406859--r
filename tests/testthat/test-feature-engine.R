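# Embedding backends, concatenation order, and the feature-matrix contract.

test_that("stub backend emits the declared layer widths deterministically", {
  be <- stub_backend(seed = 1)
  img <- random_canvas(64, seed = 4)
  e <- embed(be, img)
  expect_length(e$fc, 1000L)
  expect_length(e$pool, 1920L)
  # linear, bias-free: the all-zero image embeds to zero
  z <- fundus_image(array(0, c(32, 32, 3)))
  ez <- embed(be, z)
  expect_true(all(ez$fc == 0) && all(ez$pool == 0))
  # determinism
  expect_identical(embed(be, img), embed(be, img))
  # same seed rebuilds the same projection
  expect_identical(embed(stub_backend(seed = 7), img),
                   embed(stub_backend(seed = 7), img))
})

test_that("embed rejects non-3-channel input and dimension lies", {
  be <- toy_backend()
  expect_error(embed(be, matrix(0, 8, 8)), "3-channel")
  lying <- embedding_backend("liar", 8, 4, 6,
                             function(b, px) list(fc = 1:3, pool = 1:6))
  expect_error(embed(lying, random_canvas(8)), "declared")
})

test_that("per-input features are the fc|pool concatenation", {
  be <- toy_backend(fc_dim = 4, pool_dim = 6)
  img <- random_canvas(16, seed = 8)
  v <- extract_input_features(be, img)
  expect_length(v, 10L)
  e <- embed(be, img)
  expect_identical(v, c(e$fc, e$pool))          # explicit-concatenation oracle
  expect_identical(v[1:4], e$fc)
  # published dimensions give 2920 per input
  expect_length(extract_input_features(stub_backend(seed = 1), img), 2920L)
})

test_that("patch-set features follow the main,P1..P8 block order", {
  be <- toy_backend(fc_dim = 2, pool_dim = 3)
  ps <- divide_into_patches(random_canvas(256, seed = 3))
  v <- extract_patchset_features(be, ps)
  expect_length(v, 45L)                          # 9 x (2 + 3)
  # block k equals the per-input extraction of that input (manual slicing)
  expect_identical(v[1:5], extract_input_features(be, ps$main))
  expect_identical(v[6:10], extract_input_features(be, ps$patches[[1]]))
  expect_identical(v[41:45], extract_input_features(be, ps$patches[[8]]))
})

test_that("dimensional law D = 9(fc+pool) holds for arbitrary backend dims", {
  ps <- divide_into_patches(random_canvas(256, seed = 6))
  for (dims in list(c(1, 1), c(3, 5), c(10, 2))) {
    be <- toy_backend(fc_dim = dims[1], pool_dim = dims[2])
    expect_length(extract_patchset_features(be, ps), 9 * sum(dims))
  }
})

test_that("feature matrix rows align with images and labels", {
  be <- toy_backend()
  ds <- generate_images(synth_spec(n_per_class = 2, n_classes = 3,
                                   image_side = 64, seed = 1))
  fm <- build_feature_matrix(be, ds$images, labels = ds$labels)
  expect_equal(dim(fm$values), c(6L, 90L))
  expect_equal(as.character(fm$labels), as.character(ds$labels))
  # row k is the patch-set extraction of image k
  ps1 <- divide_into_patches(resize_to_canvas(ds$images[[1]], 256))
  expect_equal(fm$values[1, ], extract_patchset_features(be, ps1))
  # duplicate image gives identical rows
  fm2 <- build_feature_matrix(be, ds$images[c(1, 1)], labels = c("0", "0"))
  expect_identical(fm2$values[1, ], fm2$values[2, ])
  expect_error(build_feature_matrix(be, list()), "nonempty")
})

test_that("failing images abort with a summary, or are dropped in skip mode", {
  be <- toy_backend()
  good <- random_canvas(64, seed = 1)
  bad <- structure(list(pixels = array(0, c(10, 10, 2)),   # malformed by hand
                        source_id = "bad", label = NULL),
                   class = "fundus_image")
  expect_error(build_feature_matrix(be, list(good, bad), labels = c("a", "b")),
               "1/2 images failed")
  expect_warning(
    fm <- build_feature_matrix(be, list(good, bad), labels = c("a", "b"),
                               skip_errors = TRUE),
    "dropping")
  expect_equal(nrow(fm$values), 1L)
  expect_equal(as.character(fm$labels), "a")
})

test_that("column provenance covers every feature exactly once", {
  be <- toy_backend(fc_dim = 3, pool_dim = 5)
  prov <- feature_provenance(be)
  expect_equal(nrow(prov), 9 * 8)
  expect_equal(unname(table(prov$source)[c("main", paste0("P", 1:8))]),
               rep(8L, 9L), ignore_attr = TRUE)
  expect_equal(sum(prov$layer == "fc"), 9 * 3)
  expect_equal(sum(prov$layer == "pool"), 9 * 5)
  # provenance aligns with the matrix width
  ds <- generate_images(synth_spec(n_per_class = 1, n_classes = 3,
                                   image_side = 64, seed = 2))
  fm <- build_feature_matrix(be, ds$images)
  expect_equal(nrow(fm$provenance), ncol(fm$values))
})

test_that("feature matrices persist and reload losslessly with a JSON sidecar", {
  tmp <- withr::local_tempdir()
  be <- toy_backend()
  ds <- generate_images(synth_spec(n_per_class = 1, n_classes = 3,
                                   image_side = 64, seed = 3))
  fm <- build_feature_matrix(be, ds$images)
  fp <- file.path(tmp, "features.rds")
  write_feature_matrix(fm, fp)
  expect_true(file.exists(paste0(fp, ".json")))
  side <- jsonlite::read_json(paste0(fp, ".json"), simplifyVector = TRUE)
  expect_equal(side$d, ncol(fm$values))
  back <- read_feature_matrix(fp)
  expect_identical(back$values, fm$values)
  expect_identical(back$labels, fm$labels)
})

test_that("the DenseNet201 backend declares its published dimensions but needs weights", {
  be <- densenet201_backend()
  expect_equal(be$fc_dim + be$pool_dim, 2920L)
  expect_equal(be$input_side, 224L)
  expect_error(embed(be, random_canvas(32)), "stub_backend|reticulate")
})
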