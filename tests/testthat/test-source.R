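# Epoched sensor data from one oscillating voxel projected through the
# toy leadfield; used by the beamforming round-trip tests.
single_source_epochs <- function(lf, voxel, freq = 10, sf = 300,
                                 n_trials = 10, snr = Inf, seed = 1) {
  len <- 2 * round(0.5 * sf) + 1
  set.seed(seed)
  arr <- array(0, c(n_trials, length(lf$sensor_names), len))
  src_all <- matrix(0, n_trials, len)
  t <- seq_len(len) / sf
  for (tr in seq_len(n_trials)) {
    src <- sin(2 * pi * freq * t + runif(1, 0, 2 * pi)) * runif(1, 0.8, 1.2)
    sens <- project_to_sensors(ts_set(matrix(src, 1), sf), lf, voxel,
                               snr = snr, seed = seed + tr)
    arr[tr, , ] <- sens$data
    src_all[tr, ] <- src
  }
  list(epochs = epoch_set_from_array(arr, sf, lf$sensor_names),
       source = src_all)
}

test_that("band CSD is conjugate-symmetric with coherent duplicate channels", {
  sf <- 200
  set.seed(2)
  arr <- array(rnorm(5 * 2 * 201), c(5, 2, 201))
  arr[, 2, ] <- arr[, 1, ]           # identical channels
  ep <- epoch_set_from_array(arr, sf)
  csd <- band_csd(ep, c(8, 12))
  expect_equal(csd$csd, Conj(t(csd$csd)), tolerance = 1e-10)
  expect_true(all(Re(diag(csd$csd)) >= 0))
  coh <- Mod(csd$csd[1, 2]) / sqrt(Re(csd$csd[1, 1]) * Re(csd$csd[2, 2]))
  expect_equal(coh, 1, tolerance = 1e-10)
})

test_that("off-diagonal CSD of independent noise shrinks with trial count", {
  sf <- 200
  off_mag <- sapply(c(10, 160), function(n_tr) {
    set.seed(3)
    arr <- array(rnorm(n_tr * 2 * 201), c(n_tr, 2, 201))
    csd <- band_csd(epoch_set_from_array(arr, sf), c(8, 12))
    Mod(csd$csd[1, 2]) / sqrt(Re(csd$csd[1, 1]) * Re(csd$csd[2, 2]))
  })
  expect_lt(off_mag[2], off_mag[1])
  expect_lt(off_mag[2], 0.35)
})

test_that("DICS peaks at the true voxel and satisfies the unit-gain constraint", {
  lf <- make_toy_leadfield(c(4, 4, 2), spacing = 0.5, n_sensors = 16)
  voxel <- 22
  sim <- single_source_epochs(lf, voxel, snr = 50)
  csd <- band_csd(sim$epochs, c(8, 12))
  src <- dics(csd, lf)
  expect_equal(which.max(src$nai), voxel)
  for (v in c(1, voxel, nrow(lf$gain)))
    expect_equal(Re(sum(src$filters[v, ] * lf$gain[v, ])), 1,
                 tolerance = 1e-8)
  expect_true(all(src$nai >= 0))
  expect_equal(src$db, 10 * log10(src$nai), tolerance = 1e-12)
})

test_that("NAI is flat for pure white noise when gain norms are equal", {
  lf <- make_toy_leadfield(c(3, 3, 2), spacing = 0.5, n_sensors = 12)
  lf$gain <- lf$gain / sqrt(rowSums(lf$gain^2))   # equal-norm columns
  sf <- 200
  set.seed(5)
  arr <- array(rnorm(60 * 12 * 201), c(60, 12, 201))
  csd <- band_csd(epoch_set_from_array(arr, sf, lf$sensor_names), c(8, 12))
  src <- dics(csd, lf)
  expect_lt((max(src$nai) - min(src$nai)) / mean(src$nai), 0.1)
})

test_that("NAI is invariant to a global rescaling of the sensor data", {
  lf <- make_toy_leadfield(c(3, 3, 2), n_sensors = 12)
  sim <- single_source_epochs(lf, 7, snr = 5)
  csd1 <- band_csd(sim$epochs, c(8, 12))
  ep2 <- sim$epochs
  ep2$data <- ep2$data * 7.3
  csd2 <- band_csd(ep2, c(8, 12))
  s1 <- dics(csd1, lf); s2 <- dics(csd2, lf)
  expect_equal(s1$nai, s2$nai, tolerance = 1e-8)
})

test_that("DBSCAN top-percentile clusters match the flood-fill oracle", {
  lf <- make_toy_leadfield(c(10, 10, 10), spacing = 0.5, n_sensors = 9)
  set.seed(10)
  src <- structure(list(nai = runif(1000), leadfield = lf),
                   class = "source_model")
  # two blobs well separated (> eps apart); 8 voxels = top 0.8%
  blob1 <- c(1, 2, 11, 12)            # corner block in x-y plane
  blob2 <- c(555, 556, 565, 566)
  src$nai[blob1] <- 10; src$nai[blob2] <- 12
  cl <- dbscan_top(src, top_pct = 0.8, min_size = 2)
  expect_length(cl$clusters, 2)
  supra <- sort(c(blob1, blob2))
  oracle <- flood_fill_components(lf$voxel_positions[supra, ], eps = 0.5)
  oracle_sets <- lapply(unique(oracle), function(k) sort(supra[oracle == k]))
  got_sets <- lapply(cl$clusters, sort)
  expect_setequal(got_sets, oracle_sets)
})

test_that("randomized NAI maps cluster identically to a brute-force DBSCAN", {
  lf <- make_toy_leadfield(c(8, 8, 8), spacing = 1, n_sensors = 9)
  set.seed(11)
  for (rep in 1:5) {
    src <- structure(list(nai = rexp(512), leadfield = lf),
                     class = "source_model")
    cl <- dbscan_top(src, top_pct = 5, min_size = 2)
    thr <- quantile(src$nai, 0.95, names = FALSE)
    supra <- which(src$nai >= thr)
    # with min_size = 2, DBSCAN clusters on a grid equal flood-fill
    # components of size >= 2 (every member of such a component is core)
    oracle <- flood_fill_components(lf$voxel_positions[supra, , drop = FALSE], 1)
    osets <- Filter(function(s) length(s) >= 2,
                    lapply(unique(oracle), function(k) sort(supra[oracle == k])))
    expect_setequal(lapply(cl$clusters, sort), osets)
  }
})

test_that("single suprathreshold voxels are noise and ties are kept at the threshold", {
  lf <- make_toy_leadfield(c(5, 5, 1), spacing = 0.5, n_sensors = 4)
  src <- structure(list(nai = rep(1, 25), leadfield = lf),
                   class = "source_model")
  src$nai[13] <- 5                    # isolated peak
  cl <- dbscan_top(src, top_pct = 3, min_size = 2)
  expect_length(cl$clusters, 0)
  expect_equal(cl$noise_voxels, 13)
  # all-equal map: every voxel sits on the threshold and is included
  src2 <- structure(list(nai = rep(2, 25), leadfield = lf),
                    class = "source_model")
  cl2 <- dbscan_top(src2, top_pct = 3, min_size = 2)
  expect_length(cl2$clusters, 1)
  expect_length(cl2$clusters[[1]], 25)
})

test_that("LCMV reconstructs a noiseless source almost perfectly (up to sign)", {
  lf <- make_toy_leadfield(c(4, 4, 2), spacing = 0.5, n_sensors = 16)
  voxel <- 22
  sim <- single_source_epochs(lf, voxel, snr = Inf, n_trials = 10)
  csd <- band_csd(sim$epochs, c(8, 12))
  src <- dics(csd, lf)
  rec <- lcmv_timeseries(sim$epochs, lf, cluster = voxel, band = c(8, 12),
                         nai = src$nai)
  sf <- 300
  expect_equal(n_samples(rec), 10 * (2 * round(0.5 * sf) + 1))
  truth <- as.vector(t(sim$source))
  expect_gte(abs(cor(rec$data[1, ], truth)), 0.99)
})

test_that("LCMV round-trip fidelity does not improve when noise increases", {
  lf <- make_toy_leadfield(c(4, 4, 2), n_sensors = 16)
  voxel <- 22
  cors <- sapply(c(100, 0.05), function(snr) {
    sim <- single_source_epochs(lf, voxel, snr = snr, n_trials = 8, seed = 3)
    rec <- lcmv_timeseries(sim$epochs, lf, cluster = voxel, band = c(8, 12))
    abs(cor(rec$data[1, ], as.vector(t(sim$source))))
  })
  expect_gt(cors[1], cors[2])
})

test_that("empty clusters are rejected", {
  lf <- make_toy_leadfield(c(2, 2, 1), n_sensors = 4)
  sim <- single_source_epochs(lf, 1, n_trials = 2)
  expect_error(lcmv_timeseries(sim$epochs, lf, integer(0), c(8, 12)),
               "empty")
})
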