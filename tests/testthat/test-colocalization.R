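mk <- function(coords, ny = 4, nx = 4) {
  m <- matrix(0L, ny, nx)
  for (p in coords) m[p[1], p[2]] <- 1L
  m
}

test_that("two-way percent follows the printed overlap formula", {
  # A: 3 on-pixels, B: 4 on-pixels, overlap 1
  A <- mk(list(c(1, 1), c(1, 2), c(2, 1)))
  B <- mk(list(c(1, 2), c(2, 2), c(3, 3), c(3, 4)))
  r_BA <- coloc_percent(A, B, "B_with_A")
  expect_equal(r_BA$percent, 25)
  expect_equal(r_BA$numerator_px, 1)
  expect_equal(r_BA$denominator_px, 4)
  r_AB <- coloc_percent(A, B, "A_with_B")
  expect_equal(r_AB$percent, 100 / 3)
  # numerator symmetric, percent not
  expect_equal(coloc_percent(B, A)$numerator_px, r_BA$numerator_px)
  expect_equal(coloc_percent(A, A)$percent, 100)
  expect_equal(coloc_percent(mk(list(c(1, 1))), mk(list(c(4, 4))))$percent, 0)
})

test_that("zero denominators are undefined, never zero-by-convention", {
  A <- mk(list(c(1, 1)))
  empty <- mk(list())
  r <- coloc_percent(A, empty, "B_with_A")
  expect_true(is.na(r$percent))
  expect_false(r$defined)
  expect_error(coloc_percent(matrix(0L, 3, 3), matrix(0L, 4, 4)),
               class = "vc_geometry_error")
})

test_that("two- and three-way percents match brute-force pixel loops", {
  set.seed(51)
  for (i in 1:200) {
    ny <- sample(2:32, 1); nx <- sample(2:32, 1)
    A <- random_mask(ny, nx, runif(1, 0, 0.4))
    B <- random_mask(ny, nx, runif(1, 0, 0.4))
    o <- oracle_coloc_percent(A, B, "B_with_A")
    r <- coloc_percent(A, B, "B_with_A")
    expect_identical(r$numerator_px, o$num)
    expect_identical(r$denominator_px, o$den)
    expect_identical(r$percent, o$percent)
    o2 <- oracle_coloc_percent(A, B, "A_with_B")
    expect_identical(coloc_percent(A, B, "A_with_B")$percent, o2$percent)
    if (i <= 50) {
      C <- random_mask(ny, nx, runif(1, 0, 0.4))
      expect_identical(coloc_threeway(A, B, C, "A")$percent,
                       oracle_coloc_threeway(A, B, C, A))
      expect_identical(coloc_threeway(A, B, C, "C")$percent,
                       oracle_coloc_threeway(A, B, C, C))
    }
  }
})

test_that("three-way overlap handles the worked examples", {
  A <- mk(list(c(1, 1), c(2, 2)))
  B <- mk(list(c(2, 2), c(3, 3)))
  C <- mk(list(c(2, 2)))
  expect_equal(coloc_threeway(A, B, C, "A")$percent, 50)
  expect_equal(coloc_threeway(A, A, A, "B")$percent, 100)
  expect_equal(coloc_threeway(A, mk(list(c(4, 1))), C, "A")$percent, 0)
})

test_that("180-degree rotation is exact index reversal for any parity", {
  for (n in c(4, 5)) {
    B <- matrix(0L, n, n); B[1, 1] <- 1L
    expect_equal(rotate180(B)[n, n], 1L)
    expect_equal(sum(rotate180(B)), 1L)
    A <- matrix(0L, n, n); A[n, n] <- 1L
    expect_equal(rotation_null(A, B)$null_percent, 100)
  }
  # involution: rotating twice restores the mask
  set.seed(61)
  m <- random_mask(7, 12, 0.3)
  expect_identical(rotate180(rotate180(m)), m)
})

test_that("a centro-symmetric mask is fixed by the rotation null", {
  B <- matrix(0L, 5, 5); B[2, 2] <- 1L; B[4, 4] <- 1L; B[3, 3] <- 1L
  set.seed(62)
  A <- random_mask(5, 5, 0.5)
  r <- rotation_null(A, B)
  expect_equal(r$null_percent, r$percent)
})

test_that("rotation null of independent masks estimates the on-fraction", {
  set.seed(71)
  p_A <- 0.2; p_B <- 0.3
  nulls <- replicate(1000, {
    A <- random_mask(32, 32, p_A)
    B <- random_mask(32, 32, p_B)
    rotation_null(A, B)$null_percent
  })
  nulls <- nulls[!is.na(nulls)]
  se <- sd(nulls) / sqrt(length(nulls))
  expect_lt(abs(mean(nulls) - 100 * p_A), 3 * se)
})

test_that("slab projection groups z-slices as 500 nm optical sections", {
  mk_stack <- function(nz) {
    arr <- array(0, dim = c(1, nz, 4, 4))
    for (z in seq_len(nz)) arr[1, z, , ] <- z
    image_stack(arr, pixel_size_nm = 100, z_spacing_nm = 100)
  }
  pl <- slab_project(mk_stack(50), 1, slab_nm = 500)
  expect_length(pl, 10)
  expect_true(all(attr(pl, "n_slices") == 5))
  expect_false(any(attr(pl, "partial")))
  # max projection keeps the brightest slice of each group
  expect_equal(pl[[1]][1, 1], 5)
  expect_equal(pl[[10]][1, 1], 50)
  # trailing partial slab is kept and flagged
  pl2 <- slab_project(mk_stack(52), 1, slab_nm = 500)
  expect_length(pl2, 11)
  expect_identical(attr(pl2, "partial"),
                   c(rep(FALSE, 10), TRUE))
  expect_equal(attr(pl2, "n_slices")[11], 2L)
  # slab equal to slice spacing is the identity grouping
  pl3 <- slab_project(mk_stack(6), 1, slab_nm = 100)
  expect_length(pl3, 6)
  expect_error(slab_project(
    image_stack(matrix(1, 4, 4), pixel_size_nm = 100), 1),
    class = "vc_geometry_error")
})

test_that("whole-cell integration pools counts, not slab ratios", {
  # pooled (1+3)/(4+4) = 50%; and (1+1)/(4+1) = 40% vs mean-of-ratios 62.5%
  per <- function(nums, dens) 100 * sum(nums) / sum(dens)
  expect_equal(per(c(1, 3), c(4, 4)), 50)
  expect_equal(per(c(1, 1), c(4, 1)), 40)
  # cell_coloc on a two-slab stack must agree with hand pooling of its
  # own per-slab counts (conservation), and differ from mean-of-ratios
  sc <- simulate_scene(scene_spec(n_y = 128L, n_x = 128L, n_z = 10L,
                                  n_puncta = 8L, coloc_fraction = 0.5,
                                  seed = 81))
  r <- cell_coloc(sc$stack, "cargo", "marker")
  expect_equal(r$numerator_px, sum(r$per_slab$numerator_px))
  expect_equal(r$denominator_px, sum(r$per_slab$den_B_px))
  expect_equal(r$percent, 100 * r$numerator_px / r$denominator_px)
  rm <- cell_coloc(sc$stack, "cargo", "marker", aggregate = "mean")
  ok <- r$per_slab$den_B_px > 0
  expect_equal(rm$percent,
               mean(100 * r$per_slab$numerator_px[ok] / r$per_slab$den_B_px[ok]))
})

test_that("a single-slab stack reduces cell_coloc to coloc_percent", {
  sc <- simulate_scene(small_scene_spec(coloc_fraction = 0.5, seed = 91))
  r <- cell_coloc(sc$stack, "cargo", "marker")
  px <- sc$spec$pixel_size_nm
  mA <- global_threshold(dog_filter(channel_plane(sc$stack, "cargo"),
                                    dog_params(), px),
                         r$per_slab$threshold_A[1])
  mB <- global_threshold(dog_filter(channel_plane(sc$stack, "marker"),
                                    dog_params(), px),
                         r$per_slab$threshold_B[1])
  expect_equal(r$percent, coloc_percent(mA, mB)$percent)
  expect_equal(r$null_percent, rotation_null(mA, mB)$null_percent)
})

test_that("well-separated independent scenes show near-zero overlap", {
  sc <- simulate_scene(scene_spec(coloc_fraction = 0, seed = 92,
                                  poisson = FALSE, read_sigma = 0))
  r <- cell_coloc(sc$stack, "cargo", "marker")
  expect_lt(r$percent, 2)
})
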