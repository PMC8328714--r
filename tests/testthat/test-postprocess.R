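# helper: put a filled cuboid of 1s into an array
add_box <- function(lab, x, y, z) {
  lab[x[1]:x[2], y[1]:y[2], z[1]:z[2]] <- 1L
  lab
}

test_that("connected components respect the adjacency definition", {
  empty <- binary_mask(array(0L, dim = c(4, 4, 4)))
  expect_equal(connected_components(empty, 26)$n, 0)

  lab <- array(0L, dim = c(4, 4, 4))
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L  # face neighbours
  m <- binary_mask(lab)
  for (conn in c(6, 18, 26))
    expect_equal(connected_components(m, conn)$n, 1)

  lab2 <- array(0L, dim = c(4, 4, 4))
  lab2[1, 1, 1] <- 1L; lab2[2, 2, 2] <- 1L  # corner contact only
  m2 <- binary_mask(lab2)
  expect_equal(connected_components(m2, 26)$n, 1)
  expect_equal(connected_components(m2, 18)$n, 2)
  expect_equal(connected_components(m2, 6)$n, 2)

  lab3 <- array(0L, dim = c(4, 4, 4))
  lab3[1, 1, 1] <- 1L; lab3[2, 2, 1] <- 1L  # edge contact
  m3 <- binary_mask(lab3)
  expect_equal(connected_components(m3, 18)$n, 1)
  expect_equal(connected_components(m3, 6)$n, 2)
})

test_that("component stats report counts, means and the largest volume", {
  lab <- array(0L, dim = c(10, 10, 3))
  lab <- add_box(lab, c(1, 5), c(1, 5), c(1, 2))   # 50 voxels
  lab[8, 8, 3] <- 1L; lab[8, 9, 3] <- 1L; lab[8, 10, 3] <- 1L
  m <- binary_mask(lab)
  ttp <- array(0, dim = c(10, 10, 3))
  ttp[lab == 1L] <- 100
  ttp[8, 8, 3] <- 90; ttp[8, 9, 3] <- 100; ttp[8, 10, 3] <- 110
  tv <- volume3d(ttp)
  st <- component_stats(connected_components(m, 26), tv)
  expect_equal(nrow(st), 2)
  expect_setequal(st$voxels, c(50L, 3L))
  expect_equal(st$mean_ttp[st$voxels == 3L], 100)   # mean of 90/100/110
  expect_equal(st$mean_ttp[st$voxels == 50L], 100)
  expect_true(all(st$v_max == 50L))
  # single-voxel component mean is that voxel's value
  one <- binary_mask(array(c(1L, rep(0L, 7)), dim = c(2, 2, 2)))
  ov <- volume3d(array(c(42, rep(0, 7)), dim = c(2, 2, 2)))
  so <- component_stats(connected_components(one, 26), ov)
  expect_equal(so$mean_ttp, 42)
})

test_that("TTP screen removes components on the configured side only", {
  lab <- array(0L, dim = c(12, 12, 1))
  lab <- add_box(lab, c(1, 3), c(1, 3), c(1, 1))    # mean 120
  lab <- add_box(lab, c(8, 10), c(8, 10), c(1, 1))  # mean 80
  m <- binary_mask(lab)
  ttp <- array(0, dim = c(12, 12, 1))
  ttp[1:3, 1:3, 1] <- 120
  ttp[8:10, 8:10, 1] <- 80
  tv <- volume3d(ttp)
  out <- ttp_filter(m, tv, postprocess_params())     # default: remove below
  expect_equal(sum(out$labels[1:3, 1:3, 1]), 9)
  expect_equal(sum(out$labels[8:10, 8:10, 1]), 0)
  # literal reading: remove above
  out2 <- ttp_filter(m, tv, postprocess_params(ttp_removal_side = "above"))
  expect_equal(sum(out2$labels[1:3, 1:3, 1]), 0)
  expect_equal(sum(out2$labels[8:10, 8:10, 1]), 9)
  # boundary: means exactly at the threshold are retained
  ttp[] <- 0; ttp[lab == 1L] <- 100
  out3 <- ttp_filter(m, volume3d(ttp), postprocess_params())
  expect_identical(out3$labels, m$labels)
  # empty mask passes through
  empty <- binary_mask(array(0L, dim = c(12, 12, 1)))
  expect_identical(ttp_filter(empty, tv, postprocess_params())$labels,
                   empty$labels)
})

test_that("volume-ratio screen keeps components at or above the threshold", {
  lab <- array(0L, dim = c(40, 40, 2))
  lab <- add_box(lab, c(1, 25), c(1, 20), c(1, 1))    # 500 voxels
  lab <- add_box(lab, c(30, 39), c(1, 25), c(1, 1))   # 250 voxels
  lab <- add_box(lab, c(1, 5), c(30, 33), c(2, 2))    # 20 voxels, ratio 0.04
  m <- binary_mask(lab)
  out <- volume_ratio_filter(m, postprocess_params())
  expect_equal(sum(out$labels), 750)
  # single component always survives (ratio 1)
  single <- binary_mask(add_box(array(0L, dim = c(8, 8, 1)),
                                c(2, 4), c(2, 4), c(1, 1)))
  expect_identical(volume_ratio_filter(single, postprocess_params())$labels,
                   single$labels)
  # exact-threshold ratio is retained (strict <)
  lab2 <- array(0L, dim = c(30, 30, 1))
  lab2 <- add_box(lab2, c(1, 10), c(1, 10), c(1, 1))  # 100 voxels
  lab2 <- add_box(lab2, c(20, 29), c(20, 20), c(1, 1))  # 10 voxels: ratio 0.1
  m2 <- binary_mask(lab2)
  expect_equal(sum(volume_ratio_filter(m2, postprocess_params())$labels), 110)
})

test_that("composed postprocess applies TTP then volume screening", {
  lab <- array(0L, dim = c(40, 40, 2))
  lab <- add_box(lab, c(1, 20), c(1, 25), c(1, 1))    # 500: main lesion
  lab <- add_box(lab, c(25, 34), c(1, 10), c(1, 1))   # 100: low TTP
  lab <- add_box(lab, c(25, 28), c(30, 34), c(2, 2))  # 20: tiny, high TTP
  m <- binary_mask(lab)
  ttp <- array(60, dim = c(40, 40, 2))
  ttp[1:20, 1:25, 1] <- 120
  ttp[25:34, 1:10, 1] <- 85
  ttp[25:28, 30:34, 2] <- 115
  tv <- volume3d(ttp)
  out <- postprocess(m, tv, postprocess_params())
  expect_equal(sum(out$labels), 500)
  expect_true(all(out$labels[1:20, 1:25, 1] == 1L))
  # a mask surviving both screens is unchanged (idempotence on clean input)
  expect_identical(postprocess(out, tv, postprocess_params())$labels,
                   out$labels)
})

test_that("postprocess output is always a subset of its input", {
  for (i in 1:20) {
    m <- random_blob_mask(c(12, 12, 4), seed = 500 + i, p = 0.2)
    ttp <- volume3d(array(runif(prod(c(12, 12, 4)), 40, 160),
                          dim = c(12, 12, 4)))
    out <- postprocess(m, ttp, postprocess_params())
    expect_true(all(out$labels <= m$labels))
  }
})

test_that("parameter validation enforces documented ranges", {
  expect_error(postprocess_params(volume_ratio_threshold = 0),
               class = "strokeseg_value_error")
  expect_error(postprocess_params(connectivity = 10),
               class = "strokeseg_value_error")
})
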