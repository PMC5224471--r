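# Independent brute-force oracles used to check the vectorized
# implementations. These deliberately share no code with the package.

# direct sliding dot product with symmetric reflection at the borders
oracle_filter_reflect <- function(plane, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  ny <- nrow(plane); nx <- ncol(plane)
  reflect <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i
      if (i > n) i <- 2L * n + 1L - i
    }
    i
  }
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      acc <- 0
      for (dy in -r:r) {
        for (dx in -r:r) {
          acc <- acc + kernel[dy + r + 1L, dx + r + 1L] *
            plane[reflect(y + dy, ny), reflect(x + dx, nx)]
        }
      }
      out[y, x] <- acc
    }
  }
  out
}

# pixel-by-pixel double loop over the printed overlap formula
oracle_coloc_percent <- function(A, B, direction = "B_with_A") {
  num <- 0L; den_A <- 0L; den_B <- 0L
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      num <- num + A[i, j] * B[i, j]
      den_A <- den_A + A[i, j]
      den_B <- den_B + B[i, j]
    }
  }
  den <- if (direction == "B_with_A") den_B else den_A
  list(num = num, den = den,
       percent = if (den > 0) 100 * num / den else NA_real_)
}

oracle_coloc_threeway <- function(A, B, C, den_mask) {
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      num <- num + A[i, j] * B[i, j] * C[i, j]
      den <- den + den_mask[i, j]
    }
  }
  if (den > 0) 100 * num / den else NA_real_
}

random_mask <- function(ny, nx, p) {
  matrix(as.integer(runif(ny * nx) < p), ny, nx)
}

# small, fast scene for unit tests (keeps the acceptance-scale scenes
# out of the per-module suites)
small_scene_spec <- function(...) {
  scene_spec(n_y = 192L, n_x = 192L, n_puncta = 15L, ...)
}
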