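test_that("adain matches hand arithmetic and handles degenerate channels", {
  f <- matrix(c(1, 2, 3), 1, 3)
  out <- adain(f, shift = 0, scale = 1)
  expect_equal(as.vector(out), c(-1.2247449, 0, 1.2247449), tolerance = 1e-4)

  # identity re-normalization: shift = mean, scale = population sd
  set.seed(1)
  g <- matrix(rnorm(64, 5, 2), 8, 8)
  mu <- mean(g); sd_p <- sqrt(mean((g - mu)^2))
  expect_equal(adain(g, shift = mu, scale = sd_p), g, tolerance = 1e-3)

  # constant channel maps to the target mean
  const <- matrix(0.7, 4, 4)
  expect_equal(adain(const, shift = 0.2, scale = 3),
               matrix(0.2, 4, 4), tolerance = 1e-12)

  expect_error(adain(array(rnorm(32), c(4, 4, 2)), shift = 0, scale = 1),
               "channel")
})

test_that("ACG codes switch with direction, deterministically, scales > 0", {
  b <- tiny_bundle()
  cf <- acg_forward(b, "forward")
  cb <- acg_forward(b, "backward")
  expect_identical(cf, acg_forward(b, "forward"))
  diff_any <- any(mapply(function(a, d)
    any(a$shift != d$shift) || any(a$scale != d$scale), cf, cb))
  expect_true(diff_any)
  for (layer in c(cf, cb)) expect_true(all(layer$scale > 0))
  expect_error(usgan:::acg_fwd(b$acg, b$hp, "sideways"), "direction")
})

test_that("generator is feed-forward, shape preserving, and shared", {
  b <- tiny_bundle()
  x <- rand_img(64, 64, 11)
  y1 <- generate(x, b, "forward")
  expect_identical(dim(y1), dim(x))
  expect_true(all(y1 >= 0 & y1 <= 1))
  expect_identical(y1, generate(x, b, "forward"))
  # the switch: same generator weights, different code, different output
  y2 <- generate(x, b, "backward")
  expect_false(identical(y1, y2))
  expect_identical(generate(x, b, code = acg_forward(b, "forward")), y1)
  expect_error(generate(rand_img(62, 64, 1), b), "multiples of 4")
})

test_that("analytic gradients agree with finite differences", {
  b <- tiny_bundle(seed = 5)
  hp <- b$hp
  ns <- asNamespace("usgan")
  x <- rand_img(16, 16, 2)
  tgt <- matrix(rnorm(256), 16, 16)
  codeF <- ns$acg_fwd(b$acg, hp, "forward")
  fw <- ns$gen_fwd(b$gen, hp, x, codeF$code)
  bw <- ns$gen_bwd(b$gen, hp, fw$cache, tgt)
  gacg <- ns$acg_bwd(b$acg, hp, codeF$cache, bw$gcode)$grads
  loss <- function(gen, acg) {
    code <- ns$acg_fwd(acg, hp, "forward")$code
    sum(ns$gen_fwd(gen, hp, x, code)$y * tgt)
  }
  eps <- 1e-6
  set.seed(8)
  picks <- list(c("gen", "enc0.W"), c("gen", "res2.c1.W"), c("gen", "dec1.W"),
                c("gen", "out.W"), c("acg", "fc2.b"), c("acg", "fc1.W"))
  nonzero <- 0
  for (pk in picks) {
    mod <- pk[1]; nm <- pk[2]
    idx <- sample(length(b[[mod]][[nm]]), 1)
    p2 <- b[[mod]]; p2[[nm]][idx] <- p2[[nm]][idx] + eps
    p3 <- b[[mod]]; p3[[nm]][idx] <- p3[[nm]][idx] - eps
    num <- if (mod == "gen") (loss(p2, b$acg) - loss(p3, b$acg)) / (2 * eps)
           else (loss(b$gen, p2) - loss(b$gen, p3)) / (2 * eps)
    ana <- if (mod == "gen") bw$grads[[nm]][idx] else gacg[[nm]][idx]
    expect_true(is.finite(ana))
    expect_equal(num, ana, tolerance = 1e-4)
    if (abs(ana) > 1e-10) nonzero <- nonzero + 1
  }
  expect_gt(nonzero, 0)
})

test_that("discriminators downsample by 16 and are independent", {
  b <- tiny_bundle()
  x <- rand_img(64, 64, 3)
  sA <- discriminate(x, b, "A")
  expect_identical(dim(sA), c(4L, 4L))
  expect_identical(sA, discriminate(x, b, "A"))
  b2 <- b
  b2$dA$c1.W <- b2$dA$c1.W + 0.1
  expect_identical(discriminate(x, b2, "B"), discriminate(x, b, "B"))
  expect_false(identical(discriminate(x, b2, "A"), sA))
})

test_that("adain exactness: output statistics match the code within 10*eps", {
  eps <- 1e-5
  set.seed(21)
  f <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  shift <- c(-0.4, 0.1, 2)
  scale <- c(0.5, 1.5, 3)
  out <- adain(f, shift, scale, eps = eps)
  for (c in 1:3) {
    expect_lt(abs(mean(out[, , c]) - shift[c]), 10 * eps)
    sd_out <- sqrt(mean((out[, , c] - mean(out[, , c]))^2))
    expect_lt(abs(sd_out - scale[c]), 10 * eps * scale[c])
  }
})

test_that("checkpoints round-trip to bit-identical outputs", {
  b <- tiny_bundle(seed = 9)
  x <- rand_img(32, 32, 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(b, path, history = data.frame(step = 1L, total_G = 0.5))
  b2 <- load_checkpoint(path)
  expect_identical(generate(x, b2, "forward"), generate(x, b, "forward"))
  expect_identical(attr(b2, "history")$total_G, 0.5)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "other"), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
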