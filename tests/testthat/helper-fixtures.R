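# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# A small but complete synthetic dataset on disk (8 events, 8 days,
# 5-minute sampling keeps the climate stream light).
tiny_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    cfg <- sim_config(n_events = 8L, days_per_event = 8L,
                      env_sample_interval = 5L, images_per_day = 3L,
                      image_size = 64L, seed = 7L)
    .fixtures$ds <- generate_dataset(cfg, file.path(tempdir(), "gw_tiny_ds"))
  }
  .fixtures$ds
}

tiny_aligned <- function() {
  if (is.null(.fixtures$al)) {
    .fixtures$al <- align_dataset(tiny_dataset())
  }
  .fixtures$al
}

tiny_sequences <- function() {
  if (is.null(.fixtures$seqs)) {
    .fixtures$seqs <- build_sequences(tiny_aligned(), 6L)
  }
  .fixtures$seqs
}

desk_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- build_model(model_config("desk", T = 6L, seed = 100L))
  }
  .fixtures$model
}

# Central-difference numerical gradient of f (scalar) w.r.t. matrix X.
num_grad <- function(f, X, eps = 1e-6) {
  G <- X * 0
  for (i in seq_along(X)) {
    X1 <- X; X2 <- X
    X1[i] <- X1[i] + eps
    X2[i] <- X2[i] - eps
    G[i] <- (f(X1) - f(X2)) / (2 * eps)
  }
  G
}

random_image <- function(size = 64L) {
  array(runif(size * size * 3L), dim = c(size, size, 3L))
}

# A fake sequence sample with random images and env rows.
random_sequence <- function(model, Tn = 6L, stage = "early") {
  size <- model$config$image_size
  structure(list(event_id = "evX",
                 timestamps = as.POSIXct("2024-03-01", tz = "UTC") + (1:Tn) * 3600,
                 env = matrix(rnorm(Tn * 4L), Tn, 4L),
                 images = replicate(Tn, random_image(size), simplify = FALSE),
                 stage = stage,
                 stages = rep(stage, Tn),
                 lesion_fracs = rep(0.03, Tn)),
            class = "sequence_sample")
}
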