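test_that("channel lattices reproduce the published counts", {
  expect_equal(nrow(place_off_grid(10, 0.2, 0)), 51^2)
  expect_equal(nrow(place_on_grid(10, 0.2, 0)), 50^2)
  ch <- make_channel_mosaic(10, 0.2, 0.05, seed = 1)
  expect_equal(nrow(ch), 10202)
  expect_equal(sum(ch$eye == "L"), sum(ch$eye == "R"))
  expect_equal(unname(table(ch$sign)[c("off", "on")]), c(2 * 2601, 2 * 2500),
               ignore_attr = TRUE)
  # commensurate widths that are not exactly representable in binary
  expect_equal(nrow(place_off_grid(2.4, 0.2, 0)), 13^2)
  expect_equal(nrow(place_on_grid(4.8, 0.2, 0)), 24^2)
})

test_that("unjittered lattices sit exactly on the expected nodes", {
  off <- place_off_grid(2, 0.5, 0)
  expect_true(all(abs((off$x / 0.5) - round(off$x / 0.5)) < 1e-12))
  expect_equal(range(off$x), c(-1, 1))
  on <- place_on_grid(2, 0.5, 0)
  # innermost on-nodes equidistant from the centre at (+-s/2, +-s/2)
  d <- sqrt(on$x^2 + on$y^2)
  inner <- sort(d)[1:4]
  expect_equal(inner, rep(sqrt(2) * 0.25, 4), tolerance = 1e-12)
  on10 <- place_on_grid(10, 0.2, 0)
  d10 <- sqrt(on10$x^2 + on10$y^2)
  expect_equal(sort(d10)[1:4], rep(sqrt(2) * 0.1, 4), tolerance = 1e-12)
})

test_that("mean nearest-neighbour distance between the unjittered on and off lattices is spacing/sqrt(2)", {
  off <- place_off_grid(4, 0.4, 0)
  on <- place_on_grid(4, 0.4, 0)
  # brute-force nearest neighbour from each on-node to the off lattice
  nn <- vapply(seq_len(nrow(on)), function(i) {
    min(sqrt((off$x - on$x[i])^2 + (off$y - on$y[i])^2))
  }, 0)
  expect_equal(mean(nn), 0.4 / sqrt(2), tolerance = 1e-12)
})

test_that("mosaics are deterministic in the seed and differ across seeds", {
  a <- make_channel_mosaic(2, 0.2, 0.05, seed = 5)
  b <- make_channel_mosaic(2, 0.2, 0.05, seed = 5)
  c <- make_channel_mosaic(2, 0.2, 0.05, seed = 6)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_true(sum(a$x != c$x) >= 1)
})

test_that("left- and right-eye jitter displacements are statistically independent", {
  ch <- make_channel_mosaic(10, 0.2, 0.05, seed = 2)
  # displacement from the nominal lattice, per eye; matched by lattice node
  nominal <- make_channel_mosaic(10, 0.2, 0, seed = 2)
  dx <- ch$x - nominal$x
  dL <- dx[ch$eye == "L"]
  dR <- dx[ch$eye == "R"]
  n <- length(dL)
  expect_gte(n, 1000)
  obs <- abs(cor(dL, dR))
  set.seed(99)
  perm <- replicate(1000, abs(cor(dL, sample(dR))))
  p <- (sum(perm >= obs) + 1) / 1001
  expect_gt(p, 0.01)
})

test_that("halving the field width quarters the node counts", {
  n10 <- nrow(place_off_grid(10, 0.2, 0))
  n5 <- nrow(place_off_grid(5, 0.2, 0))
  expect_lte(abs(sqrt(n10) - 2 * sqrt(n5)), 2 + 1)
  expect_lt(abs(n10 / n5 - 4), 0.25)
})

test_that("cortical grid matches the analysis window counts", {
  g <- cortical_grid(10, 0.2)
  expect_equal(nrow(g), 2601)
  # central 6x6 deg window holds 31^2 = 961 neurons
  win <- abs(g$x) <= 3 + 1e-9 & abs(g$y) <= 3 + 1e-9
  expect_equal(sum(win), 961)
  expect_warning(cortical_grid(2, 0.6, r_cort = 0.95), "undersamples")
  # degenerate: spacing equal to the field width gives a 2 x 2 grid
  expect_equal(nrow(suppressWarnings(cortical_grid(1, 1))), 4)
})

test_that("grid argument validation rejects bad configurations", {
  expect_error(place_off_grid(10, -0.2), "positive")
  expect_error(place_off_grid(10, 0.2, -1), "non-negative")
  expect_error(place_on_grid(0.1, 0.5), "exceeds")
})
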