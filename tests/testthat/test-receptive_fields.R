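test_that("edge kernels split the grid into balanced ON and OFF half-planes", {
  k <- make_edge_kernel(4, 4, orientation = 0)
  expect_true(all(k$grid[1:2, ] == 1))   # ON: top half
  expect_true(all(k$grid[3:4, ] == -1))  # OFF: bottom half
  expect_identical(sum(k$grid), 0)
  flipped <- make_edge_kernel(4, 4, orientation = pi)
  expect_identical(flipped$grid, -k$grid)
  # odd dimensions: areas equal to within one pixel row
  k5 <- make_edge_kernel(5, 5)
  expect_lte(abs(sum(k5$grid)), 5)
  expect_error(make_edge_kernel(1, 4), "degenerate")
})

test_that("difference-of-Gaussians kernels are balanced, center-dominant and sign-symmetric", {
  on <- make_dog_kernel(33, 33, sigma_center = 2, sigma_surround = 4)
  expect_gt(on$grid[17, 17], 0)                       # ON center dominates
  expect_lt(abs(sum(on$grid)), 1e-6)                  # zero net weight
  off <- make_dog_kernel(33, 33, 2, 4, on_center = FALSE)
  expect_identical(off$grid, -on$grid)
  expect_error(make_dog_kernel(8, 8, 3, 2), "sigma_center")
})

test_that("Gabor kernels honor phase, orientation periodicity and grating tuning", {
  H <- W <- 64
  # odd grid puts a pixel exactly at the center, where cos(pi/2) kills the
  # carrier
  kq <- make_gabor_kernel(65, 65, phase = pi / 2)
  expect_lt(abs(kq$grid[33, 33]), 1e-12)
  expect_equal(make_gabor_kernel(H, W, orientation = 0.4)$grid,
               make_gabor_kernel(H, W, orientation = 0.4 + pi)$grid)

  k <- make_gabor_kernel(H, W, orientation = pi / 6, sigma_x = 8,
                         sigma_y = 8, wavelength = 8)
  matched <- field_response(k, make_grating(H, W, pi / 6, wavelength = 8))
  orth <- field_response(k, make_grating(H, W, pi / 6 + pi / 2,
                                         wavelength = 8))
  expect_gte(abs(matched) / abs(orth), 5)
  # brute-force sweep in 15-degree steps: the kernel's own orientation wins
  sweep <- vapply(seq(0, 165, by = 15) * pi / 180, function(th) {
    abs(field_response(k, make_grating(H, W, th, wavelength = 8)))
  }, numeric(1))
  expect_equal(which.max(sweep), 3L)  # 30 degrees = pi/6
})

test_that("uniform stimuli produce zero response for all three kernel types", {
  flat <- visual_stimulus(matrix(0.7, 32, 32))
  expect_identical(field_response(make_edge_kernel(32, 32, 0.3), flat), 0)
  expect_lt(abs(field_response(make_dog_kernel(32, 32, 2, 4), flat)), 1e-9)
  gab <- make_gabor_kernel(32, 32, sigma_x = 4, sigma_y = 4, wavelength = 4)
  # the discrete Gabor integral is only approximately zero; its residual DC
  # response is orders of magnitude below any grating response
  expect_lt(abs(field_response(gab, flat)), 1e-5)
})

test_that("responses are linear, antisymmetric under stimulus flips and size-normalized", {
  k <- make_edge_kernel(16, 16)
  step_img <- visual_stimulus(rbind(matrix(1, 8, 16), matrix(0, 8, 16)))
  flip_img <- visual_stimulus(rbind(matrix(0, 8, 16), matrix(1, 8, 16)))
  r1 <- field_response(k, step_img)
  r2 <- field_response(k, flip_img)
  expect_equal(r1, -r2)
  expect_equal(r1, 0.5)  # ON half fully lit, normalized by pixel count
  expect_error(field_response(k, visual_stimulus(matrix(0.5, 8, 8))),
               "do not match")
})

test_that("responses are covariant under quarter-turn rotations of kernel and stimulus", {
  for (kind in c("edge", "gabor")) {
    mk <- function(th) switch(kind,
      edge = make_edge_kernel(32, 32, th),
      gabor = make_gabor_kernel(32, 32, th, sigma_x = 4, sigma_y = 4,
                                wavelength = 6))
    r0 <- field_response(mk(0.2), make_grating(32, 32, 0.2, wavelength = 6))
    r90 <- field_response(mk(0.2 + pi / 2),
                          make_grating(32, 32, 0.2 + pi / 2, wavelength = 6))
    expect_equal(r0, r90, tolerance = 1e-10)
  }
})

test_that("PNG stimuli load as grayscale matrices in [0, 1]", {
  skip_if_not_installed("png")
  f <- tempfile(fileext = ".png")
  gray <- matrix(seq(0, 1, length.out = 64), 8, 8)
  png::writePNG(gray, f)
  expect_equal(unclass(read_stimulus_png(f)), gray, tolerance = 1 / 255,
               ignore_attr = TRUE)
  rgb <- array(0.5, dim = c(4, 4, 3))
  png::writePNG(rgb, f)
  expect_equal(max(abs(read_stimulus_png(f) - 0.5)), 0, tolerance = 1 / 255)
})

test_that("spike encoding is rectified, gain-scaled and rate-faithful", {
  set.seed(1)
  expect_false(any(vapply(1:50, function(i) encode_response(-2, 100, 1e-4),
                          logical(1))))
  expect_false(any(vapply(1:50, function(i) encode_response(1, 0, 1e-4),
                          logical(1))))
  n <- 20000; dt <- 1e-4; gain <- 100
  fires <- sum(vapply(seq_len(n), function(i) encode_response(1, gain, dt),
                      logical(1)))
  p <- gain * dt
  expect_lt(abs(fires - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("a visual-input node drives spiking through the engine", {
  k <- make_edge_kernel(16, 16)
  bright_top <- visual_stimulus(rbind(matrix(1, 8, 16), matrix(0, 8, 16)))
  net <- add_node(network(), "visual_input", kernel = k,
                  stimulus = bright_top, gain = 200)
  net <- add_node(net, "neuron")
  net <- connect(net, "n1", "n2", synapse_params(2e-10))
  rec <- run_network(net, sim_config(duration = 1, seed = 3))
  # response 0.5, gain 200 -> ~100 Hz Bernoulli source
  expect_gt(length(rec$spikes[["n1"]]), 60)
  expect_lt(length(rec$spikes[["n1"]]), 140)

  # dark stimulus (rectified negative response): silent
  dark <- visual_stimulus(rbind(matrix(0, 8, 16), matrix(1, 8, 16)))
  net2 <- add_node(network(), "visual_input", kernel = k, stimulus = dark,
                   gain = 200)
  net2 <- add_node(net2, "neuron")
  net2 <- connect(net2, "n1", "n2", synapse_params(2e-10))
  rec2 <- run_network(net2, sim_config(duration = 0.5, seed = 3))
  expect_length(rec2$spikes[["n1"]], 0)
})
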