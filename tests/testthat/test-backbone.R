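test_that("conv geometry reproduces the canonical cases and rejects bad ones", {
  expect_identical(conv_output_size(227, 11, 4), 55L)
  expect_identical(conv_output_size(512, 11, 4), 126L)
  for (k in c(3L, 7L, 11L))
    expect_identical(conv_output_size(k, k, 1), 1L)
  expect_identical(conv_output_size(5, 7, 1, padding = 1), 1L)
  expect_error(conv_output_size(5, 7, 1), "invalid geometry")
  expect_error(conv_output_size(10, 3, 0), "stride")
})

test_that("first-layer raw dimensionality at the original geometry is 290,400", {
  cfg <- backbone_config("random", input_size = 227,
                         layers = list(conv_layer(11, 4, 0, 96)))
  img <- generate_image(synthetic_spec("noise", size = 256, seed = 1))
  resp <- extract_responses(img, cfg)
  expect_identical(dim(resp$maps), c(55L, 55L, 96L))
  expect_equal(prod(dim(resp$maps)), 290400)
})

test_that("builtin banks are zero-mean, unit-norm and seeded-deterministic", {
  w <- richvar:::filter_bank_gabor(11L)
  expect_identical(dim(w), c(363L, 30L))
  # zero DC response: a constant input patch yields exactly zero
  expect_lt(max(abs(colSums(w * 1))), 1e-12)
  expect_equal(colSums(w^2), rep(1, ncol(w)), tolerance = 1e-12)
  r1 <- richvar:::filter_bank_random(11L, 3L, 8L, seed = 3L)
  r2 <- richvar:::filter_bank_random(11L, 3L, 8L, seed = 3L)
  expect_identical(r1, r2)
  expect_false(identical(r1, richvar:::filter_bank_random(11L, 3L, 8L, 4L)))
})

test_that("responses to a constant image are spatially constant per filter", {
  img <- as_image_rgb(array(0.5, c(64, 64, 3)))
  cfg <- backbone_config("random", input_size = 64, seed = 2,
                         apply_relu = FALSE)
  resp <- extract_responses(img, cfg)
  spread <- apply(resp$maps, 3, function(m) max(m) - min(m))
  expect_lt(max(spread), 1e-12)
})

test_that("extraction is deterministic and covariant to stride-sized shifts", {
  img <- generate_image(synthetic_spec("art_like", size = 128, seed = 9))
  cfg <- small_cfg()
  r1 <- extract_responses(img, cfg)
  r2 <- extract_responses(img, cfg)
  expect_identical(r1$maps, r2$maps)
  # periodic image shifted by one stride: interior responses shift one pixel
  stride <- cfg$layers[[1]]$stride
  per <- array(0, c(128, 128, 3))
  set.seed(11)
  base <- array(runif(16 * 128 * 3), c(16, 128, 3))
  for (b in 0:7) per[b * 16 + 1:16, , ] <- base
  shifted <- per[c((stride + 1):128, 1:stride), , , drop = FALSE]
  ra <- extract_responses(as_image_rgb(per), cfg)$maps
  rb <- extract_responses(as_image_rgb(shifted), cfg)$maps
  n <- dim(ra)[1]
  expect_equal(rb[1:(n - 1), , ], ra[2:n, , ], tolerance = 1e-10)
})

test_that("layer bounds and pretrained weight handling error usefully", {
  cfg <- small_cfg()
  img <- generate_image(synthetic_spec("noise", size = 128, seed = 1))
  expect_error(extract_responses(img, cfg, layer = 2), "layer")
  expect_error(backbone_config("pretrained"), "builtin|random")
  # a well-formed weights file round-trips: 96 filters, kernel geometry
  f <- tempfile(fileext = ".csv")
  w <- matrix(rnorm(96 * 363), 96)
  write.table(w, f, sep = ",", row.names = FALSE, col.names = FALSE)
  cfgp <- backbone_config("pretrained", input_size = 128, weights_file = f)
  expect_identical(cfgp$layers[[1]]$filters, 96L)
  expect_identical(dim(extract_responses(img, cfgp)$maps)[3], 96L)
  bad <- tempfile(fileext = ".csv")
  write.table(w[1:10, ], bad, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(backbone_config("pretrained", weights_file = bad), "96")
})

test_that("multi-layer random backbone chains geometry with inter-layer pooling", {
  cfg <- backbone_config("random", input_size = 128,
                         layers = list(conv_layer(11, 4, 0, 6),
                                       conv_layer(5, 1, 2, 4)),
                         apply_pool_between_layers = TRUE)
  img <- generate_image(synthetic_spec("art_like", size = 128, seed = 2))
  r2 <- extract_responses(img, cfg, layer = 2)
  # 128 -> conv(11,4) 30 -> pool/2 15 -> conv(5,1,pad2) 15
  expect_identical(dim(r2$maps), c(15L, 15L, 4L))
  expect_gte(min(r2$maps), 0)
})
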