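test_that("zero crossings and slope sign changes match hand-worked cases", {
  expect_equal(zero_crossings(c(1, -1, 1, -1), 0.5), 3)
  expect_equal(zero_crossings(c(1, 1, 1), 0.5), 0)
  # a crossing whose amplitude change is below the threshold does not count
  expect_equal(zero_crossings(c(0.1, -0.1), 0.5), 0)
  # exact zeros never cross (strict inequalities)
  expect_equal(zero_crossings(c(0, 1, -1, 0), 0), 1)
  expect_equal(zero_crossings(c(0, 1, 0, -1), 0), 0)

  expect_equal(slope_sign_changes(c(0, 1, 0), 0.5), 1)
  expect_equal(slope_sign_changes(c(0, 1, 2, 3), 0), 0)
  expect_equal(slope_sign_changes(c(0, 1, 0), 2), 0)
})

test_that("amplitude features match hand-worked values and basic identities", {
  af <- amplitude_features(c(3, -4))
  expect_equal(af[["rms"]], sqrt(12.5))
  expect_equal(af[["mav"]], 3.5)
  expect_equal(af[["wl"]], 7)
  expect_equal(af[["mavs"]], 1)  # mav([-4]) - mav([3])

  af_const <- amplitude_features(rep(-2.5, 10))
  expect_equal(unname(af_const), c(2.5, 2.5, 0, 0))

  # positive scaling scales all four features linearly
  set.seed(1)
  x <- rnorm(50)
  a1 <- amplitude_features(x)
  a2 <- amplitude_features(3 * x)
  expect_equal(a2, 3 * a1)
})

test_that("all six features agree with the naive-loop oracle on random windows", {
  set.seed(42)
  for (len in c(20, 40, 200)) {
    for (rep_i in 1:40) {
      x <- rnorm(len, sd = sample(c(1e-6, 1e-3, 1), 1))
      T <- sample(c(0, 1e-8, 1e-4, 1e-2), 1)
      expect_identical(zero_crossings(x, T), oracle_zc(x, T))
      expect_identical(slope_sign_changes(x, T), oracle_ssc(x, T))
      af <- amplitude_features(x)
      expect_equal(af[["rms"]], oracle_rms(x))
      expect_equal(af[["mav"]], oracle_mav(x))
      expect_equal(af[["wl"]], oracle_wl(x))
      expect_equal(af[["mavs"]], oracle_mavs(x))
    }
  }
})

test_that("zc and ssc are non-increasing in the threshold and vanish for huge T", {
  set.seed(7)
  grid <- c(0, 10^seq(-8, 0))
  for (i in 1:30) {
    x <- rnorm(60, sd = 10^runif(1, -4, 0))
    zc <- vapply(grid, function(T) zero_crossings(x, T), numeric(1))
    ssc <- vapply(grid, function(T) slope_sign_changes(x, T), numeric(1))
    expect_true(all(diff(zc) <= 0))
    expect_true(all(diff(ssc) <= 0))
    Tmax <- max(abs(diff(x))) * 1.01
    expect_equal(zero_crossings(x, Tmax), 0)
    expect_equal(slope_sign_changes(x, Tmax), 0)
  }
})

test_that("zc and ssc are invariant under joint positive scaling of x and T", {
  set.seed(8)
  x <- rnorm(100)
  for (a in c(0.01, 1, 250)) {
    expect_identical(zero_crossings(a * x, a * 0.3), zero_crossings(x, 0.3))
    expect_identical(slope_sign_changes(a * x, a * 0.3), slope_sign_changes(x, 0.3))
  }
})

test_that("extract_features builds the 6-per-channel table aligned with windows", {
  rec <- tiny_recording()
  ws <- segment(rec, 200, 100)
  ft <- extract_features(ws, 1e-3)
  expect_s3_class(ft, "emg_features")
  expect_equal(ncol(ft$values), 12)
  expect_equal(nrow(ft$values), length(ws$labels))
  expect_identical(ft$labels, ws$labels)
  expect_equal(ft$threshold_used, 1e-3)
  expect_equal(colnames(ft$values)[1:6],
               c("rms_ch1", "mav_ch1", "mavs_ch1", "zc_ch1", "ssc_ch1", "wl_ch1"))

  # each cell equals the single-window operation applied independently
  for (i in sample(nrow(ft$values), 5)) {
    for (ch in 1:2) {
      x <- ws$windows[i, , ch]
      off <- (ch - 1) * 6
      expect_equal(unname(ft$values[i, off + 1]), oracle_rms(x))
      expect_equal(unname(ft$values[i, off + 4]), as.numeric(oracle_zc(x, 1e-3)))
      expect_equal(unname(ft$values[i, off + 5]), as.numeric(oracle_ssc(x, 1e-3)))
      expect_equal(unname(ft$values[i, off + 6]), oracle_wl(x))
    }
  }
})

test_that("an all-zero signal produces an all-zero feature table", {
  rec <- emg_recording(matrix(0, 400, 2), 200, rep(0L, 400), rep(0L, 400))
  ft <- extract_features(segment(rec, 100, 100), 0.01)
  expect_true(all(ft$values == 0))
})

test_that("standardizer centres and scales with training statistics only", {
  v <- cbind(a = c(1, 2, 3), b = c(10, 10, 10))
  tab <- feature_table(v, c(0L, 1L, 1L), c(1L, 1L, 2L))
  std <- fit_standardizer(tab)
  expect_equal(unname(std$mean), c(2, 10))
  # population estimator: divide by n
  expect_equal(unname(std$sd[1]), sqrt(2 / 3))
  expect_true(std$zero_var[["b"]])

  z <- apply_standardizer(std, tab)
  expect_lt(max(abs(colMeans(z$values))), 1e-9)
  expect_equal(unname(sqrt(mean((z$values[, 1] - mean(z$values[, 1]))^2))), 1,
               tolerance = 1e-6)

  # test-table transform uses train statistics, not its own
  test_tab <- feature_table(cbind(a = c(5, 6), b = c(1, 2)),
                            c(0L, 1L), c(2L, 2L))
  zt <- apply_standardizer(std, test_tab)
  expect_gt(abs(mean(zt$values[, 1])), 1)

  # inverse transform round-trips
  back <- apply_standardizer(std, z, inverse = TRUE)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
})

test_that("feature preconditions raise structured input errors", {
  expect_error(zero_crossings(1, 0), class = "emg_input_error")
  expect_error(slope_sign_changes(c(1, 2), 0), class = "emg_input_error")
  expect_error(amplitude_features(numeric(0)), class = "emg_input_error")
  expect_error(fit_standardizer(feature_table(cbind(a = 1), 0L, 1L)),
               class = "emg_input_error")
})

test_that("per-dataset default thresholds are exposed", {
  expect_equal(default_threshold("DB5"), 0.01)
  expect_equal(default_threshold("DB7"), 1e-8)
  expect_equal(default_threshold("DB7-amputee"), 1e-6)
  expect_error(default_threshold("DB1"), class = "emg_config_error")
})
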