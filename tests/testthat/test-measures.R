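test_that("subregion maxima match brute force, including uneven grids", {
  m <- max_pool_map(array(matrix(1:16, 4, byrow = TRUE), c(4, 4, 1)), 2)
  expect_equal(m$values[, , 1], matrix(c(6, 14, 8, 16), 2))
  expect_equal(max_pool_map(array(3.5, c(6, 6, 2)), 3)$values,
               array(3.5, c(3, 3, 2)))
  r <- random_resp(9, 9, 3, seed = 1)
  expect_equal(max_pool_map(r, 1)$values[1, 1, ], apply(r, 3, max))
  for (seed in 1:5) {
    x <- random_resp(7, 11, 4, seed)
    for (n in c(2, 3, 5, 7))
      expect_equal(max_pool_map(x, n)$values, naive_pool_max(x, n))
  }
  expect_error(max_pool_map(random_resp(4, 4, 1, 1), 5), "invalid grid")
  expect_error(max_pool_map(random_resp(4, 4, 1, 1), 0), ">= 1")
})

test_that("histogram normalization sums to one, fills degenerate subregions uniformly, and is idempotent", {
  v <- array(0, c(2, 2, 2))
  v[1, 1, ] <- c(2, 6)
  v[1, 2, ] <- c(1, 1)
  v[2, 1, ] <- c(5, 0)
  # v[2,2,] stays all-zero -> uniform fill
  m <- normalize_histograms(max_pool_map(v, 2))
  expect_equal(m$values[1, 1, ], c(0.25, 0.75))
  expect_equal(m$values[2, 2, ], c(0.5, 0.5))
  expect_identical(attr(m, "n_uniform_filled"), 1L)
  sums <- apply(m$values, c(1, 2), sum)
  expect_equal(as.vector(sums), rep(1, 4), tolerance = 1e-9)
  expect_equal(normalize_histograms(m)$values, m$values)
  neg <- max_pool_map(array(1, c(2, 2, 2)), 2)
  neg$values[1] <- -0.1
  expect_error(normalize_histograms(neg), "negative")
})

test_that("variance measures reproduce hand-computed cases", {
  # all four subregions (1, 0): 8 values {1,0,...}, population variance 0.25
  v <- array(0, c(2, 2, 2)); v[, , 1] <- 1
  m <- as_norm_map(v)
  expect_equal(p_a(m), 0.25)
  expect_equal(p_g(m), 0.25)   # each within-histogram variance 0.25
  expect_equal(p_f(m), 0)      # both filters spatially constant
  # checkerboard filters: each filter's values {1,0,1,0}, v_f = 0.25 each
  v2 <- array(0, c(2, 2, 2))
  v2[1, 1, ] <- c(1, 0); v2[2, 2, ] <- c(1, 0)
  v2[1, 2, ] <- c(0, 1); v2[2, 1, ] <- c(0, 1)
  expect_equal(p_f(as_norm_map(v2)), 0.25)
  # three subregions (1,0), one (0.5,0.5): median of {.25,.25,.25,0}
  v3 <- array(0, c(2, 2, 2)); v3[, , 1] <- 1
  v3[2, 2, ] <- c(0.5, 0.5)
  expect_equal(p_g(as_norm_map(v3)), 0.25)
  # uniform histograms everywhere: all three measures vanish
  u <- as_norm_map(array(1 / 5, c(4, 4, 5)))
  expect_equal(p_a(u), 0)
  expect_equal(p_g(u), 0)
  expect_equal(p_f(u), 0)
  # sample estimator applies the n/(n-1) correction
  expect_equal(p_a(m, estimator = "sample"), 0.25 * 8 / 7)
})

test_that("measures demand a normalized map", {
  raw <- max_pool_map(random_resp(6, 6, 3, 2), 3)
  expect_error(p_a(raw), "normalized")
  expect_error(p_g(raw), "normalized")
  expect_error(p_f(raw), "normalized")
})

test_that("vectorized measures agree with naive loop references on random maps", {
  for (seed in 1:50) {
    v <- naive_normalize(random_resp(6, 6, 5, seed))
    m <- as_norm_map(v)
    expect_equal(p_a(m), naive_pa(v), tolerance = 1e-12)
    expect_equal(p_g(m), naive_pg(v), tolerance = 1e-12)
    expect_equal(p_f(m), naive_pf(v), tolerance = 1e-12)
  }
})

test_that("measures are permutation-invariant and bounded for binary histograms", {
  set.seed(31)
  for (trial in 1:5) {
    v <- naive_normalize(random_resp(4, 4, 6, trial + 100))
    m <- as_norm_map(v)
    pf <- sample(6); ps <- sample(4)
    vp <- v[ps, , pf, drop = FALSE][, sample(4), , drop = FALSE]
    mp <- as_norm_map(vp)
    expect_equal(p_a(mp), p_a(m))
    expect_equal(p_g(mp), p_g(m))
    expect_equal(p_f(mp), p_f(m))
  }
  # k = 2 analytic worst case: entries in {0,1} -> p_a at most 0.25
  worst <- array(0, c(3, 3, 2)); worst[, , 1] <- 1
  expect_lte(p_a(as_norm_map(worst)), 0.25)
})

test_that("feature vector has 45 ordered entries and is response-scale invariant", {
  resp <- random_resp(30, 30, 8, seed = 6)
  fv <- variance_features(resp)
  expect_length(fv, 45L)
  grids <- seq(2L, 30L, 2L)
  expect_identical(names(fv),
                   c(paste0("Pa_", grids), paste0("Pg_", grids),
                     paste0("Pf_", grids)))
  expect_true(all(fv >= 0))
  expect_equal(unclass(variance_features(resp * 37.5)), unclass(fv),
               tolerance = 1e-12)
  expect_error(variance_features(random_resp(20, 20, 3, 1)), "at least")
})

test_that("spatially constant per-filter maps zero the variability measure", {
  k <- 6
  consts <- seq(0.2, 1.2, length.out = k)
  resp <- array(rep(consts, each = 30 * 30), c(30, 30, k))
  fv <- variance_features(resp)
  grids <- seq(2L, 30L, 2L)
  expect_equal(unname(fv[paste0("Pf_", grids)]), rep(0, 15))
  # normalized histograms identical in every subregion: Pa constant in n
  pa <- unname(fv[paste0("Pa_", grids)])
  expect_lt(max(pa) - min(pa), 1e-12)
})

test_that("self-similarity is 1 for uniform structure, 0 for disjoint support, in [0,1] generally", {
  expect_equal(self_similarity(array(0.7, c(16, 16, 4))), 1)
  # a subregion histogram disjoint from the ground histogram contributes 0
  expect_equal(sum(pmin(c(1, 0), c(0, 1))), 0)
  # quadrant construction: filter f responds only in quadrant f, so every
  # subregion histogram is concentrated on one filter while the ground
  # histogram is uniform; the intersection is exactly 1/k everywhere
  v <- array(0, c(16, 16, 4))
  v[1:8, 1:8, 1] <- 1; v[1:8, 9:16, 2] <- 1
  v[9:16, 1:8, 3] <- 1; v[9:16, 9:16, 4] <- 1
  expect_equal(self_similarity(v), 0.25)
  resp <- random_resp(33, 33, 5, seed = 8)
  s <- self_similarity(resp)
  expect_gte(s, 0); expect_lte(s, 1)
  expect_error(self_similarity(random_resp(6, 6, 2, 1)), "at least 8")
})
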