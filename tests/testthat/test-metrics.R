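test_that("CR and CNR match hand arithmetic and the mask oracle", {
  img <- matrix(100 / 255, 8, 8)
  fg <- matrix(FALSE, 8, 8); fg[1:4, ] <- TRUE
  bg <- !fg
  img[fg] <- 200 / 255
  expect_equal(contrast_ratio(img, fg, bg), 100)
  expect_equal(contrast_ratio(img, bg, fg), contrast_ratio(img, fg, bg))

  img2 <- matrix(0, 4, 4)
  fg2 <- matrix(FALSE, 4, 4); fg2[1, 1:2] <- TRUE
  bg2 <- matrix(FALSE, 4, 4); bg2[4, 1:2] <- TRUE
  img2[fg2] <- c(90, 110) / 255
  img2[bg2] <- c(40, 60) / 255
  expect_equal(contrast_to_noise(img2, fg2, bg2), 50 / sqrt(200),
               tolerance = 1e-12)
  # scale invariance of CNR
  expect_equal(contrast_to_noise(img2 * 0.37, fg2, bg2),
               contrast_to_noise(img2, fg2, bg2), tolerance = 1e-10)

  for (seed in 1:5) {
    r <- rand_img(12, 12, seed)
    fg_r <- rand_img(12, 12, seed + 100) > 0.7
    bg_r <- !fg_r & rand_img(12, 12, seed + 200) > 0.5
    expect_equal(contrast_ratio(r, fg_r, bg_r), oracle_cr(r, fg_r, bg_r))
    expect_equal(contrast_to_noise(r, fg_r, bg_r),
                 oracle_cnr(r, fg_r, bg_r))
  }
  expect_error(contrast_ratio(img, matrix(FALSE, 8, 8), bg), "empty")
  expect_error(contrast_to_noise(matrix(0.5, 8, 8), fg, bg), "variance")
})

test_that("patch-wise SSIM: identity, anti-correlation, global equivalence", {
  a <- rand_img(32, 32, 3)
  expect_equal(patchwise_ssim(a, a, 8, 4), 1)
  # whole-image patch equals global single-window SSIM
  b <- clamp01(a + 0.1 * matrix(rnorm(1024), 32, 32))
  expect_equal(patchwise_ssim(a, b, 32, 32), oracle_ssim(a, b),
               tolerance = 1e-12)
  # binary image against its complement: negative on mixed patches
  bin <- matrix(rep(c(0, 1), each = 8 * 16), 16, 16)
  expect_lt(patchwise_ssim(bin, 1 - bin, 16, 16), 0)
  # common luminance shift has a bounded (near-invariant) effect
  s1 <- patchwise_ssim(a * 0.5, b * 0.5, 8, 8)
  s2 <- patchwise_ssim(a * 0.5 + 0.2, b * 0.5 + 0.2, 8, 8)
  expect_lt(abs(s1 - s2), 0.05)
  expect_error(patchwise_ssim(a, matrix(0, 8, 8)), "shape")
})

test_that("first-order statistics match independent oracles", {
  const <- matrix(0.3, 8, 8)
  s <- first_order_stats(const)
  expect_identical(c(s$std, s$skewness, s$entropy), c(0, 0, 0))

  # one pixel at each of the 256 levels: entropy is exactly 8 bits
  levels256 <- matrix((0:255) / 255, 16, 16)
  expect_equal(first_order_stats(levels256)$entropy, 8)

  sym <- matrix(rep(c(0.2, 0.8), 32), 8, 8)
  expect_equal(first_order_stats(sym)$skewness, 0)

  r <- rand_img(16, 16, 9)^2
  fo <- first_order_stats(r)
  expect_equal(fo$mean, mean(r))
  expect_equal(fo$std, sqrt(mean((r - mean(r))^2)))
  expect_equal(fo$skewness, oracle_skewness(r))
  expect_equal(fo$skewness, e1071::skewness(as.vector(r), type = 1),
               tolerance = 1e-10)
  expect_equal(fo$entropy, oracle_entropy(r))
})

test_that("GLCM and its features match brute-force pair enumeration", {
  m <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE) * 0.999
  G <- glcm(m, levels = 2, offset = c(0, 1), symmetric = TRUE)
  expect_equal(G[1, 1], 0.5)
  expect_equal(G[2, 2], 0.5)
  f <- glcm_features(G)
  expect_equal(unlist(f), c(contrast = 0, correlation = 1, energy = 0.5,
                            homogeneity = 1))

  checker <- (outer(1:8, 1:8, "+") %% 2) * 0.999
  fc <- glcm_features(glcm(checker, 2, c(0, 1), TRUE))
  expect_equal(fc$contrast, 1)
  expect_equal(fc$homogeneity, 0.5)
  expect_equal(fc$correlation, -1)

  constG <- glcm(matrix(0.5, 4, 4), 4, c(0, 1), TRUE)
  expect_equal(sum(constG != 0), 1)
  expect_equal(constG[3, 3], 1)  # level floor(0.5*4) = 2, 0-based
  expect_equal(glcm_features(constG)$correlation, 1)

  L <- 4
  expect_equal(glcm_features(matrix(1 / L^2, L, L))$energy, 1 / L^2)

  for (seed in 1:4) {
    r <- rand_img(8, 8, seed + 40)
    for (off in list(c(0, 1), c(1, 0), c(1, 1))) {
      for (sym in c(TRUE, FALSE)) {
        G1 <- glcm(r, 4, off, sym)
        G0 <- oracle_glcm(r, 4, off, sym)
        expect_equal(unclass(G1), G0, ignore_attr = TRUE)
        expect_equal(sum(G1), 1)
        expect_equal(unlist(glcm_features(G1)),
                     unlist(oracle_glcm_features(G0)), tolerance = 1e-12)
      }
    }
  }
  expect_error(glcm(rand_img(4, 4, 1), 4, c(0, 10)), "offset")
})

test_that("Frechet distance matches closed forms and an independent sqrtm", {
  A <- matrix(c(-1, 0, 1), ncol = 1)   # sample mean 0, sample var 1
  B <- matrix(c(0, 1, 2), ncol = 1)    # sample mean 1, sample var 1
  expect_equal(frechet_distance(A, B), 1, tolerance = 1e-6)
  expect_equal(frechet_distance(A, A), 0, tolerance = 1e-6)
  expect_equal(frechet_distance(A, B), frechet_distance(B, A),
               tolerance = 1e-10)

  set.seed(31)
  FA <- matrix(rnorm(40), 10, 4)
  FB <- matrix(rnorm(40, 0.5, 1.3), 10, 4)
  muA <- colMeans(FA); muB <- colMeans(FB)
  SA <- cov(FA); SB <- cov(FB)
  root <- pracma::sqrtm(SA %*% SB)$B
  ref <- sum((muA - muB)^2) + sum(diag(SA + SB - 2 * root))
  expect_equal(frechet_distance(FA, FB), ref, tolerance = 1e-8)
  expect_error(frechet_distance(FA, matrix(0, 4, 2)), "dimension")
})

test_that("FID on image sets: zero for identical, positive for disjoint", {
  imgs1 <- lapply(1:4, function(i) rand_img(16, 16, i))
  expect_lt(fid_score(imgs1, imgs1), 1e-6)
  dark <- lapply(1:3, function(i) matrix(0.2, 16, 16) + 1e-3 * rand_img(16, 16, i))
  bright <- lapply(1:3, function(i) matrix(0.8, 16, 16) - 1e-3 * rand_img(16, 16, i + 5))
  expect_gt(fid_score(dark, bright), 0)
  expect_equal(fid_score(imgs1, rev(imgs1)), fid_score(imgs1, imgs1),
               tolerance = 1e-8)
  # extractor is deterministic across constructions
  e1 <- random_conv_extractor(seed = 5)
  e2 <- random_conv_extractor(seed = 5)
  expect_identical(e1(imgs1[[1]]), e2(imgs1[[1]]))
})

test_that("evaluate_set produces per-image rows, a mean row, and a CSV", {
  d <- withr::local_tempdir()
  generate_dataset(3, d, seed = 21, size = c(64, 64))
  csv <- file.path(d, "report.csv")
  rep1 <- evaluate_set(file.path(d, "X"), mask_dir = file.path(d, "masks"),
                       out_csv = csv)
  expect_identical(nrow(rep1), 4L)
  expect_identical(rep1$file[4], "mean")
  expect_true(file.exists(csv))
  expect_true(all(is.finite(rep1$CR)))
  expect_true(all(rep1$glcm_energy > 0 & rep1$glcm_energy <= 1))
  expect_true(all(rep1$glcm_homogeneity > 0 & rep1$glcm_homogeneity <= 1))

  # an image evaluated against itself has patch_ssim exactly 1
  rep2 <- evaluate_set(file.path(d, "X"), ref_dir = file.path(d, "X"),
                       mask_dir = file.path(d, "masks"))
  expect_equal(rep2$patch_ssim[1:3], rep(1, 3))

  expect_error(evaluate_set(file.path(d, "X"), mask_dir = d,
                            auto_roi = FALSE), "ROI")
})
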