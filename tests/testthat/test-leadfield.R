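test_that("point-electrode weights match the closed form", {
  # sigma = 0.3 S/m, r = 1 mm, reference at infinity
  w <- point_electrode_weights(cbind(0, 0, 0),
                               electrode_spec(c(0, 0, -1000), sigma = 0.3))
  expect_equal(w$weights, 1 / (4 * pi * 0.3 * 1e-3) * 1e-9,
               tolerance = 1e-12)

  # compartment equidistant from recording and reference -> weight 0
  spec <- electrode_spec(c(0, 0, -500), reference = c(0, 0, 500))
  w0 <- point_electrode_weights(cbind(0, 0, 0), spec)
  expect_equal(w0$weights, 0)

  # doubling sigma halves every weight
  ctr <- cbind(runif(5, -100, 100), runif(5, -100, 100), runif(5, 0, 1000))
  w1 <- point_electrode_weights(ctr, electrode_spec(c(0, 0, -2000), sigma = 0.3))
  w2 <- point_electrode_weights(ctr, electrode_spec(c(0, 0, -2000), sigma = 0.6))
  expect_equal(w1$weights, 2 * w2$weights)

  expect_error(point_electrode_weights(cbind(0, 0, -1000),
                                       electrode_spec(c(0, 0, -1000))),
               "coincides")
})

test_that("line-source coefficients have the correct limits and symmetry", {
  seg <- data.frame(x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 0, z1 = 10,
                    radius = 1, is_soma = 0)
  # far field: r > 20 L -> within 1% of the point-source coefficient
  for (pos in list(c(300, 0, 5), c(0, 250, 5), c(200, 200, 5))) {
    wl <- line_source_weights(seg, pos, sigma = 0.3)
    r <- sqrt(sum((pos - c(0, 0, 5))^2)) * 1e-6
    wp <- 1 / (4 * pi * 0.3 * r) * 1e-9
    expect_equal(wl, wp, tolerance = 0.01)
  }

  # mirror-symmetric segments about the electrode's perpendicular plane
  segs <- data.frame(x0 = c(0, 0), y0 = 0, z0 = c(100, -100),
                     x1 = c(0, 0), y1 = 0, z1 = c(200, -200),
                     radius = 1, is_soma = c(0, 0))
  w <- line_source_weights(segs, c(50, 0, 0), sigma = 0.3)
  expect_equal(w[1], w[2], tolerance = 1e-12)

  # soma point coefficient at 80 um
  soma <- data.frame(x0 = 0, y0 = 0, z0 = 10, x1 = 0, y1 = 0, z1 = -10,
                     radius = 10, is_soma = 1)
  ws <- line_source_weights(soma, c(80, 0, 0), sigma = 0.3)
  expect_equal(ws, 1 / (4 * pi * 0.3 * 80e-6) * 1e-9, tolerance = 1e-12)

  expect_error(line_source_weights(seg, c(0, 0, 5)), "segment axis")
})

test_that("two-compartment dipole reproduces the analytic dipole potential", {
  # currents +I/-I separated by d along the electrode axis, far field
  d_um <- 20
  I <- 1    # nA
  sigma <- 0.3
  for (r_um in c(500, 1000, 3000)) {
    spec <- electrode_spec(c(0, 0, -r_um), sigma = sigma)
    ctr <- rbind(c(0, 0, -d_um / 2), c(0, 0, d_um / 2))
    w <- point_electrode_weights(ctr, spec)
    eeg <- sum(w$weights * c(I, -I))
    # p cos(theta) / (4 pi sigma r^2), theta = 0, p = I d
    p <- I * 1e-9 * d_um * 1e-6
    phi <- p / (4 * pi * sigma * (r_um * 1e-6)^2)
    expect_equal(eeg, phi, tolerance = 0.02)
  }
})

test_that("gauge shift centers the range and leaves the EEG unchanged", {
  w <- weights_table(c(1, 3), comp_neuron = c(1L, 1L))
  ws <- gauge_shift(w)
  expect_equal(ws$weights, c(-1, 1))
  expect_equal(gauge_shift(weights_table(rep(4, 5)))$weights, rep(0, 5))

  # zero-sum per-neuron currents: EEG invariant to 1e-12 relative
  set.seed(31)
  n_neuron <- 6L; n_comp <- 5L; n_t <- 40L
  comp_neuron <- rep(seq_len(n_neuron), each = n_comp)
  I <- matrix(rnorm(n_t * n_neuron * n_comp), n_t)
  for (id in seq_len(n_neuron)) {
    cols <- which(comp_neuron == id)
    I[, cols] <- I[, cols] - rowMeans(I[, cols])
  }
  wt <- weights_table(runif(n_neuron * n_comp), comp_neuron = comp_neuron)
  cur <- structure(list(time = seq_len(n_t) * 0.1, currents = I,
                        comp_neuron = comp_neuron), class = "currents_report")
  before <- compute_signal(cur, wt, keep_contributions = FALSE)$values
  after <- compute_signal(cur, gauge_shift(wt), keep_contributions = FALSE)$values
  expect_lt(max(abs(before - after)) / max(abs(before)), 1e-12)
})

test_that("weights-range statistic matches the percentile closed form", {
  # uniform weights on one neuron -> 0
  w <- weights_table(rep(2, 10), comp_neuron = rep(1L, 10))
  expect_equal(weights_range_stat(w, sample = 1L), 0)

  # linear gradient of slope s over length L: 90th - 10th -> 0.8 s L
  s <- 3e-12; L <- 1000; n <- 2001
  wlin <- weights_table(s * seq(0, L, length.out = n),
                        comp_neuron = rep(1L, n))
  expect_equal(weights_range_stat(wlin, sample = 1L), 0.8 * s * L,
               tolerance = 1e-3)

  # a sample of identical neurons averages to the single-neuron range
  w3 <- weights_table(rep(c(0, 1, 2, 3, 4), 3),
                      comp_neuron = rep(1:3, each = 5))
  expect_equal(weights_range_stat(w3, sample = 1:3),
               weights_range_stat(w3, sample = 1L))

  # single-compartment neuron contributes range 0
  w4 <- weights_table(c(5, 0, 1), comp_neuron = c(1L, 2L, 2L))
  expect_equal(weights_range_stat(w4, sample = 1L), 0)
})

test_that("weights files round-trip losslessly", {
  spec <- electrode_spec(c(0, 0, -1500), reference = c(4000, 0, -500),
                        sigma = 0.3)
  w <- point_electrode_weights(matrix(rnorm(30, sd = 300), 10), spec)
  w$comp_neuron <- rep(1:2, each = 5)
  path <- tempfile(fileext = ".tsv")
  write_weights(w, path)
  w2 <- read_weights(path)
  expect_identical(w$weights, w2$weights)
  expect_equal(w$comp_neuron, w2$comp_neuron)
  expect_equal(w2$electrode$position, spec$position)
  expect_equal(w2$electrode$sigma, spec$sigma)
  unlink(path)
})
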