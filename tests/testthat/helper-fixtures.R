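# Small synthetic fixtures shared across test files. Heavy fixtures are
# memoised so several tests can reuse one trained model.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

tiny_config <- function(...) {
  synthetic_config(n_channels = 2, fs = 200, movement_classes = 1:3,
                   movement_s = 1, rest_s = 0.5, seed = 99,
                   activation = rbind(c(4, 0.5), c(0.5, 4), c(3, 3)), ...)
}

tiny_recording <- function() memo("tiny_recording", generate_recording(tiny_config()))

# A small separable classification problem: 3 classes, short blocks.
tiny_split_features <- function() memo("tiny_split_features", {
  rec <- tiny_recording()
  ws <- segment(rec, 200, 100)
  sp <- split_by_repetition(ws)
  list(train = extract_features(sp$train, 1e-3),
       test = extract_features(sp$test, 1e-3))
})

tiny_model <- function() memo("tiny_model", {
  tabs <- tiny_split_features()
  emg_dnn(tabs$train, epochs = 60, batch_size = 64, seed = 4)
})

# The study-protocol recovery problem: 8 channels @ 200 Hz, 10 movement
# classes + rest, 6 repetitions, 5 s activity / 3 s rest. Trained once and
# reused by the recovery, usage-simulation and determinism tests.
recovery_fixture <- function(seed = 101) memo(paste0("recovery_", seed), {
  cfg <- synthetic_config(n_channels = 8, fs = 200, movement_classes = 1:10,
                          n_repetitions = 6, movement_s = 5, rest_s = 3,
                          seed = seed)
  rec <- generate_recording(cfg)
  ws <- segment(rec, 200, 100)
  sp <- split_by_repetition(ws, c(1, 3, 4, 6), c(2, 5))
  train <- extract_features(sp$train, 1e-3)
  test <- extract_features(sp$test, 1e-3)
  model <- emg_dnn(train, epochs = 25, seed = seed + 1)
  list(config = cfg, recording = rec, train = train, test = test,
       model = model, report = evaluate(model, test))
})

find_python <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  p
}
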