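test_that("lattice contiguity matches textbook neighbor counts", {
  g22 <- make_lattice(2, 2)
  expect_equal(vapply(contiguity_weights(g22, "rook")$neighbours,
                      length, integer(1)), rep(2L, 4))
  expect_equal(vapply(contiguity_weights(g22, "queen")$neighbours,
                      length, integer(1)), rep(3L, 4))
  g33 <- make_lattice(3, 3)
  wq <- contiguity_weights(g33, "queen")
  expect_equal(length(wq$neighbours[[5]]), 8L)  # center cell
  wr <- contiguity_weights(g33, "rook")
  expect_equal(length(wr$neighbours[[1]]), 2L)  # corner
  expect_equal(length(wr$neighbours[[5]]), 4L)
  # contiguity is symmetric
  for (i in seq_len(wq$n)) for (j in wq$neighbours[[i]])
    expect_true(i %in% wq$neighbours[[j]])
})

test_that("islands are reported and can be escalated to an error", {
  geo <- geography(c("A", "B", "C"),
                   list(A = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                        B = cbind(c(1, 2, 2, 1), c(0, 0, 1, 1)),
                        C = cbind(c(5, 6, 6, 5), c(5, 5, 6, 6))))
  w <- contiguity_weights(geo, "queen")
  expect_equal(w$islands, "C")
  expect_error(contiguity_weights(geo, "queen", require_connected = TRUE),
               "C")
})

test_that("row standardization normalizes rows, flags islands, idempotent", {
  w <- weights_matrix(list(c(2L, 3L), c(1L), integer(0)))
  ws <- row_standardize(w)
  expect_equal(ws$weights[[1]], c(0.5, 0.5))
  expect_equal(ws$weights[[3]], numeric(0))
  expect_equal(ws$islands, "3")
  expect_equal(row_standardize(ws)$weights, ws$weights)
})

test_that("weights round-trip through GAL and sparse-triplet CSV", {
  w <- contiguity_weights(make_lattice(3, 3), "queen")
  gal <- withr::local_tempfile(fileext = ".gal")
  write_gal(w, gal)
  back <- read_gal(gal)
  expect_equal(back$neighbours, w$neighbours)
  expect_equal(back$ids, w$ids)
  csvp <- withr::local_tempfile(fileext = ".csv")
  write_weights_csv(row_standardize(w), csvp)
  back2 <- read_weights_csv(csvp, ids = w$ids)
  expect_equal(as.matrix(as_spmatrix(back2)),
               as.matrix(as_spmatrix(row_standardize(w))))
})

test_that("checkerboard on a 2x2 rook lattice gives Moran's I of -1", {
  w <- row_standardize(contiguity_weights(make_lattice(2, 2), "rook"))
  m <- morans_i(c(1, -1, -1, 1), w, permutations = 99, seed = 1)
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_equal(m$expected, -1 / 3)
  expect_error(morans_i(rep(2, 4), w), "constant")
})

test_that("Moran's I equals the brute-force double sum on random instances", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    w <- random_weights(n)
    if (runif(1) < 0.5) w <- row_standardize(w)
    v <- rnorm(n)
    expect_equal(morans_i(v, w, permutations = 0)$I,
                 moran_brute(v, dense_weights(w)), tolerance = 1e-12)
  }
})

test_that("permutation null is centered on -1/(n-1) and seed-reproducible", {
  w <- row_standardize(contiguity_weights(make_lattice(5, 5), "queen"))
  set.seed(8)
  v <- rnorm(25)
  m1 <- morans_i(v, w, permutations = 999, seed = 42)
  m2 <- morans_i(v, w, permutations = 999, seed = 42)
  expect_identical(m1$sim, m2$sim)
  expect_identical(m1$p_perm, m2$p_perm)
  mc_se <- sd(m1$sim) / sqrt(length(m1$sim))
  expect_lt(abs(mean(m1$sim) - (-1 / 24)), 3 * mc_se)
  expect_gte(m1$p_perm, 1 / 1000)
})

test_that("permutation draws do not disturb the caller's RNG stream", {
  w <- row_standardize(contiguity_weights(make_lattice(4, 4), "queen"))
  set.seed(13); v <- rnorm(16)
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(morans_i(v, w, permutations = 49, seed = 7))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("mean of local Moran statistics equals the global statistic", {
  set.seed(17)
  for (i in 1:10) {
    n_side <- sample(4:7, 1)
    w <- row_standardize(contiguity_weights(make_lattice(n_side, n_side),
                                            "queen"))
    v <- rnorm(n_side^2)
    li <- lisa(v, w, permutations = 19, seed = 3)
    expect_equal(mean(li$local_I), morans_i(v, w, permutations = 0)$I,
                 tolerance = 1e-9)
  }
})

test_that("LISA quadrants follow the sign logic and find planted clusters", {
  # checkerboard: every unit is high-among-low or low-among-high
  w <- row_standardize(contiguity_weights(make_lattice(4, 4), "rook"))
  chk <- ifelse((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2 == 0, 1, -1)
  li <- lisa(as.numeric(t(chk)), w, permutations = 99, seed = 5)
  expect_true(all(li$quadrant %in% c("HL", "LH")))

  # hot-spot block on a smooth background
  set.seed(30)
  g <- make_lattice(8, 8)
  w8 <- row_standardize(contiguity_weights(g, "queen"))
  vals <- rnorm(64, 0, 0.1)
  block <- which(rep(1:8, each = 8) %in% 3:5 & rep(1:8, 8) %in% 3:5)
  vals[block] <- vals[block] + 5
  li8 <- lisa(vals, w8, permutations = 199, seed = 6, alpha = 0.05)
  core <- which(rep(1:8, each = 8) == 4 & rep(1:8, 8) == 4)
  expect_equal(li8$quadrant[core], "HH")
  expect_true(li8$significant[core])
})

test_that("LISA FDR option only tightens the significance flags", {
  w <- row_standardize(contiguity_weights(make_lattice(5, 5), "queen"))
  set.seed(44); v <- rnorm(25)
  raw <- lisa(v, w, permutations = 199, seed = 9)
  adj <- lisa(v, w, permutations = 199, seed = 9, fdr = TRUE)
  expect_true(all(adj$significant <= raw$significant))
  expect_equal(adj$p_perm, raw$p_perm)  # reported p stays unadjusted
})
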