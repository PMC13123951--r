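test_that("shock filter: identities, parameter errors, edge sharpening", {
  const <- matrix(0.42, 16, 16)
  expect_equal(shock_filter(const, 9, 5), const, tolerance = 1e-12)
  img <- rand_img(16, 16, 1)
  expect_identical(shock_filter(img, 9, 0), img)
  expect_error(shock_filter(img, 8, 5), "odd")

  # blurred vertical step: the transition band must not widen
  h <- 16; w <- 32
  edge <- t(matrix(1 / (1 + exp(-(seq_len(w) - w / 2) / 3)), w, h))
  edge <- clamp01(edge)
  width_of <- function(m) sum(m[8, ] > 0.25 & m[8, ] < 0.75)
  out <- shock_filter(edge, 9, 5)
  expect_lte(width_of(out), width_of(edge))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("bilateral filter: identity, Gaussian limit, edge preservation", {
  const <- matrix(0.7, 16, 16)
  expect_equal(bilateral_filter(const, 3, 0.1, 9), const, tolerance = 1e-12)
  expect_error(bilateral_filter(const, 3, 0.1, 8), "odd")

  # sigma_range -> Inf collapses to the window-truncated Gaussian blur
  img <- rand_img(16, 16, 7)
  out <- bilateral_filter(img, sigma_spatial = 2, sigma_range = Inf,
                          window = 9)
  expect_lt(max(abs(out - oracle_gauss_window(img, 2, 9))), 1e-6)

  # two-level noiseless step with a narrow range kernel: edge preserved
  step8 <- matrix(rep(c(0.2, 0.8), each = 4 * 8), 8, 8)
  out8 <- bilateral_filter(step8, sigma_spatial = 2, sigma_range = 0.05,
                           window = 5)
  expect_true(all((out8 > 0.5) == (step8 > 0.5)))
  expect_true(all(abs(out8 - step8) < 0.01))

  # convexity: outputs stay inside the global input range
  out2 <- bilateral_filter(img, 3, 0.2, 7)
  expect_gte(min(out2), min(img))
  expect_lte(max(out2), max(img))
})
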