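test_that("recording MAT round-trip is the identity", {
  rec <- tiny_recording()
  path <- withr::local_tempfile(fileext = ".mat")
  write_recording_mat(rec, path)
  back <- read_ninapro_mat(path, source_tag = "synthetic")
  expect_identical(back$emg, rec$emg)
  expect_identical(back$stimulus, rec$stimulus)
  expect_identical(back$repetition, rec$repetition)
  expect_identical(back$fs, rec$fs)
})

test_that("reader rejects malformed inputs with structured errors", {
  path <- withr::local_tempfile(fileext = ".mat")
  # missing stimulus
  emgmotion:::write_mat5(list(emg = matrix(1:8 / 2, 4, 2)), path)
  expect_error(read_ninapro_mat(path, fs = 200), class = "emg_format_error")

  # label length mismatch
  emgmotion:::write_mat5(list(emg = matrix(1:8 / 2, 4, 2),
                              stimulus = matrix(0, 3, 1),
                              repetition = matrix(0, 3, 1)), path)
  expect_error(read_ninapro_mat(path, fs = 200), class = "emg_alignment_error")

  # non-finite samples
  emgmotion:::write_mat5(list(emg = matrix(c(1, NaN, 3, 4), 2, 2),
                              stimulus = matrix(0, 2, 1),
                              repetition = matrix(0, 2, 1)), path)
  expect_error(read_ninapro_mat(path, fs = 200), class = "emg_data_error")

  expect_error(read_ninapro_mat(tempfile()), class = "emg_format_error")

  # zero-sample recording refused at write time
  rec <- tiny_recording()
  rec$emg <- rec$emg[0, , drop = FALSE]
  rec$stimulus <- integer(0); rec$repetition <- integer(0)
  expect_error(write_recording_mat(rec, path), class = "emg_format_error")
})

test_that("field_map overrides names and records the label dialect", {
  path <- withr::local_tempfile(fileext = ".mat")
  emgmotion:::write_mat5(list(EMG = matrix(rnorm(8), 4, 2),
                              glove = matrix(c(0, 1, 1, 0), 4, 1),
                              rep_idx = matrix(c(0, 1, 1, 0), 4, 1)), path)
  rec <- read_ninapro_mat(path, field_map = list(emg = "EMG",
                                                 stimulus = "glove",
                                                 repetition = "rep_idx",
                                                 fs = 200))
  expect_equal(nrow(rec$emg), 4)
  expect_equal(rec$stimulus, c(0L, 1L, 1L, 0L))
  expect_equal(rec$label_source, "stimulus")
})

test_that("refined labels are preferred over the raw dialect when present", {
  path <- withr::local_tempfile(fileext = ".mat")
  emgmotion:::write_mat5(list(emg = matrix(rnorm(8), 4, 2),
                              stimulus = matrix(c(0, 1, 1, 1), 4, 1),
                              restimulus = matrix(c(0, 0, 1, 1), 4, 1),
                              repetition = matrix(c(0, 1, 1, 1), 4, 1),
                              rerepetition = matrix(c(0, 0, 1, 1), 4, 1)), path)
  rec <- read_ninapro_mat(path, fs = 200)
  expect_equal(rec$label_source, "restimulus")
  expect_equal(rec$stimulus, c(0L, 0L, 1L, 1L))
})

test_that("files written by scipy.io (v5, plain and compressed) are read correctly", {
  py <- find_python()
  expect_true(nzchar(py))  # the reference interpreter is part of the toolchain
  dir <- withr::local_tempdir()
  script <- file.path(dir, "make.py")
  writeLines(c(
    "import sys, numpy as np, scipy.io as sio",
    "rng = np.random.default_rng(0)",
    "emg = rng.normal(size=(60, 3))",
    "np.savetxt(sys.argv[1] + '/emg_ref.txt', emg)",
    "stim = (np.arange(60) % 4).astype(np.uint8).reshape(-1, 1)",
    "rep = np.ones((60, 1), dtype=np.int16)",
    "sio.savemat(sys.argv[1] + '/plain.mat', {'emg': emg, 'restimulus': stim,",
    "            'rerepetition': rep, 'frequency': np.array([[200.0]])})",
    "sio.savemat(sys.argv[1] + '/comp.mat', {'emg': emg.astype(np.float32),",
    "            'stimulus': stim.astype(np.int32), 'repetition': rep.astype(np.float64)},",
    "            do_compression=True)"), script)
  res <- system2(py, c(script, dir), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "plain.mat")), info = paste(res, collapse = "\n"))

  ref <- as.matrix(read.table(file.path(dir, "emg_ref.txt")))
  dimnames(ref) <- NULL

  r1 <- read_ninapro_mat(file.path(dir, "plain.mat"))
  expect_equal(r1$fs, 200)
  expect_equal(r1$label_source, "restimulus")
  expect_equal(r1$emg, ref, tolerance = 1e-12)
  expect_equal(r1$stimulus, as.integer(0:59 %% 4))

  r2 <- read_ninapro_mat(file.path(dir, "comp.mat"), fs = 200)
  expect_equal(r2$emg, ref, tolerance = 1e-6)  # float32 storage
  expect_equal(r2$stimulus, as.integer(0:59 %% 4))
})

test_that("MAT files written by the package are readable by scipy.io", {
  py <- find_python()
  expect_true(nzchar(py))
  dir <- withr::local_tempdir()
  rec <- tiny_recording()
  write_recording_mat(rec, file.path(dir, "ours.mat"))
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import sys, numpy as np, scipy.io as sio",
    "d = sio.loadmat(sys.argv[1] + '/ours.mat')",
    "np.savetxt(sys.argv[1] + '/emg_back.txt', d['emg'])",
    "np.savetxt(sys.argv[1] + '/stim_back.txt', d['stimulus'].ravel())",
    "print(float(d['fs'].ravel()[0]))"), script)
  out <- system2(py, c(script, dir), stdout = TRUE, stderr = TRUE)
  expect_equal(as.numeric(tail(out, 1)), rec$fs)
  back <- as.matrix(read.table(file.path(dir, "emg_back.txt")))
  dimnames(back) <- NULL
  expect_equal(back, rec$emg, tolerance = 1e-12)
  expect_equal(scan(file.path(dir, "stim_back.txt"), quiet = TRUE),
               as.numeric(rec$stimulus))
})

test_that("HDF5-backed (v7.3) MAT files are read with MATLAB dimension order", {
  py <- find_python()
  expect_true(nzchar(py))
  dir <- withr::local_tempdir()
  script <- file.path(dir, "make73.py")
  writeLines(c(
    "import sys, numpy as np, h5py",
    "rng = np.random.default_rng(1)",
    "emg = rng.normal(size=(40, 4))  # MATLAB shape 40 x 4",
    "np.savetxt(sys.argv[1] + '/emg_ref.txt', emg)",
    "with h5py.File(sys.argv[1] + '/v73.mat', 'w', userblock_size=512) as f:",
    "    f.create_dataset('emg', data=emg.T)  # HDF5 stores the transpose",
    "    f.create_dataset('stimulus', data=(np.arange(40.0) % 3).reshape(1, 40))",
    "    f.create_dataset('repetition', data=np.ones((1, 40)))",
    "    f.create_dataset('fs', data=np.array([[2000.0]]))",
    "with open(sys.argv[1] + '/v73.mat', 'r+b') as f:",
    "    f.write(b'MATLAB 7.3 MAT-file' + b' ' * 97 + bytes([0, 2, 73, 77]))"),
    script)
  res <- system2(py, c(script, dir), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "v73.mat")),
              info = paste(res, collapse = "\n"))
  ref <- as.matrix(read.table(file.path(dir, "emg_ref.txt")))
  dimnames(ref) <- NULL
  rec <- read_ninapro_mat(file.path(dir, "v73.mat"))
  expect_equal(rec$fs, 2000)
  expect_equal(rec$emg, ref, tolerance = 1e-12)
  expect_equal(rec$stimulus, as.integer(0:39 %% 3))
})

test_that("feature tables round-trip through CSV", {
  tabs <- tiny_split_features()
  tab <- tabs$train
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_equal(hdr, c(colnames(tab$values), "label", "repetition"))

  back <- read_feature_table(path)
  expect_identical(back$labels, tab$labels)
  expect_identical(back$repetitions, tab$repetitions)
  expect_equal(dim(back$values), dim(tab$values))
  rel <- abs(back$values - tab$values) /
    pmax(abs(tab$values), .Machine$double.eps)
  expect_lt(max(rel[tab$values != 0]), 1e-12)

  # empty table: header-only CSV
  empty <- feature_table(tab$values[0, , drop = FALSE], integer(0), integer(0))
  write_feature_table(empty, path)
  expect_equal(length(readLines(path)), 1)
  back0 <- read_feature_table(path)
  expect_equal(nrow(back0$values), 0)

  # duplicate columns rejected
  bad <- tab
  colnames(bad$values)[2] <- colnames(bad$values)[1]
  expect_error(write_feature_table(bad, path), class = "emg_format_error")
})
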