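test_that("camera correction performs the stated elementwise arithmetic", {
  dark <- matrix(100, 4, 4)
  expect_true(all(correct_camera(dark, dark, matrix(1, 4, 4)) == 0))

  raw <- matrix(1:16 * 10, 4, 4)
  expect_equal(correct_camera(raw, 100, 3), raw - 100)  # uniform flat

  # flat twice the mean in the left half: scalar-loop oracle
  flat <- cbind(matrix(2, 4, 2), matrix(1, 4, 2))
  got <- correct_camera(raw, 100, flat)
  fn <- flat / mean(flat)
  want <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) want[i, j] <- (raw[i, j] - 100) / fn[i, j]
  expect_equal(got, want)

  expect_error(correct_camera(raw, 0, matrix(0, 4, 4)), "non-positive")
})

test_that("camera correction is linear in the raw frame", {
  withr::with_seed(8, {
    r1 <- matrix(runif(25, 100, 500), 5); r2 <- matrix(runif(25, 100, 500), 5)
    dark <- matrix(runif(25, 90, 110), 5)
    flat <- matrix(runif(25, 0.8, 1.2), 5)
  })
  a <- 2.5; b <- -0.5
  lhs <- correct_camera(a * r1 + b * r2 + (1 - a - b) * dark, dark, flat)
  rhs <- a * correct_camera(r1, dark, flat) + b * correct_camera(r2, dark, flat)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("registration recovers known transforms from synthetic beads", {
  ref <- make_bead_image(seed = 11)

  est <- estimate_registration(ref, ref)
  expect_equal(est$matrix, diag(2), tolerance = 1e-3)
  expect_lt(sqrt(sum(est$offset^2)), 0.05)
  expect_lt(est$residual, 0.05)

  # integer translation by (3, -2): moving = ref relocated exactly
  mov <- matrix(0, 256, 256)
  mov[4:256, 1:254] <- ref[1:253, 3:256]
  est <- estimate_registration(ref, mov)
  expect_equal(est$offset, c(3, -2), tolerance = 0.1)
  expect_equal(est$matrix, diag(2), tolerance = 1e-3)

  # pure scaling about the image centre
  M <- diag(2) * 1.01
  ctr <- c(128.5, 128.5)
  tr <- channel_transform(M, ctr - as.vector(M %*% ctr))
  mov <- apply_registration(ref, invert_transform(tr))
  mov[is.na(mov)] <- 0
  est <- estimate_registration(ref, mov)
  expect_equal(diag(est$matrix), c(1.01, 1.01), tolerance = 0.002)
})

test_that("estimate-apply recovers random affines within 0.2 px", {
  ref <- make_bead_image(seed = 4)
  ctr <- c(128.5, 128.5)
  grid <- as.matrix(expand.grid(seq(32, 224, 32), seq(32, 224, 32)))
  withr::with_seed(17, {
    for (rep in 1:3) {
      th <- runif(1, -2, 2) * pi / 180
      sc <- runif(1, 0.98, 1.02)
      M <- sc * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
      shift <- runif(2, -10, 10)
      tr <- channel_transform(M, shift + ctr - as.vector(M %*% ctr))
      mov <- apply_registration(ref, invert_transform(tr))
      mov[is.na(mov)] <- 0
      est <- estimate_registration(ref, mov)
      derr <- fretq:::transform_coords(tr, grid) -
        fretq:::transform_coords(est, grid)
      expect_lt(mean(sqrt(rowSums(derr^2))), 0.2)
    }
  })
})

test_that("resampling respects interpolation guarantees", {
  ref <- make_bead_image(shape = c(128, 128), n_beads = 60, seed = 3)
  ident <- channel_transform()
  expect_identical(apply_registration(ref, ident, "nearest"), ref)

  # integer shift with nearest neighbour is an exact pixel relocation
  tr <- channel_transform(offset = c(5, -3))
  got <- apply_registration(ref, tr, "nearest")
  expect_identical(got[1:123, 4:128], ref[6:128, 1:125])
  expect_true(all(is.na(got[124:128, ])))

  # shift then inverse shift on a smooth image: small interpolation error
  smooth <- EBImage::imageData(EBImage::gblur(EBImage::Image(ref), 6))
  tr <- channel_transform(offset = c(2.3, -1.7))
  back <- apply_registration(apply_registration(smooth, tr),
                             invert_transform(tr))
  ok <- !is.na(back)
  expect_lt(sqrt(mean((back[ok] - smooth[ok])^2)) / sd(smooth[ok]), 0.01)
})

test_that("segmentation isolates bright cells and drops small debris", {
  zero <- image_triplet(matrix(0, 64, 64), matrix(0, 64, 64),
                        matrix(0, 64, 64))
  expect_warning(seg <- segment_cells(zero), "empty mask")
  expect_false(any(seg$mask))

  sc <- generate_scene(shape = c(128, 128), n_cells = 1, seed = 6,
                       concentration_range = c(5e4, 5e4))
  tr <- render_triplet(sc, bench_inst(),
                       camera_model(read_noise_sd = 3, shot_noise = TRUE),
                       seed = 7)
  seg <- segment_cells(tr)
  truth <- sc$cell_label > 0
  expect_gt(mean(seg$mask[truth]), 0.9)
  expect_lt(mean(seg$mask[!truth]), 0.01)

  sc2 <- generate_scene(shape = c(160, 160), n_cells = 2, seed = 8)
  tr2 <- render_triplet(sc2, bench_inst(), noise_free_cam())
  seg2 <- segment_cells(tr2)
  expect_equal(max(seg2$labels), 2)
})
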