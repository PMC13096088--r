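make_env <- function(ts, vals) {
  data.table::data.table(timestamp = ts,
                         temp_c = vals[, 1L], rh_pct = vals[, 2L],
                         vpd_kpa = vals[, 3L], co2_ppm = vals[, 4L])
}

t0 <- as.POSIXct("2024-03-01 12:00:00", tz = "UTC")

test_that("aggregate_window is the closed-interval window mean", {
  # constant series -> the constant
  env <- make_env(t0 + (0:99) * 60, matrix(rep(c(20, 60, 1, 400), each = 100), ncol = 4L))
  expect_equal(unname(aggregate_window(env, t0 + 50 * 60, 30)), c(20, 60, 1, 400))

  # two-point window mean
  env2 <- make_env(t0 + c(0, 60), rbind(c(20, 60, 1.0, 400), c(22, 64, 1.2, 420)))
  expect_equal(unname(aggregate_window(env2, t0 + 30, 30)), c(21, 62, 1.1, 410))

  # boundary instants are included (closed interval)
  expect_equal(unname(aggregate_window(env2, t0 + 60 + 30 * 60, 30)),
               c(22, 64, 1.2, 420))
})

test_that("aggregate_window matches a brute-force scan on random series and centres", {
  set.seed(101)
  n <- 500L
  ts <- t0 + sort(sample.int(100000L, n))
  vals <- matrix(rnorm(n * 4L), n, 4L)
  env <- make_env(ts, vals)
  for (rep in 1:1000) {
    tau <- t0 + runif(1, 0, 100000)
    hw <- runif(1, 5, 60)
    sel <- abs(as.numeric(ts) - as.numeric(tau)) <= hw * 60 + 1e-9
    got <- tryCatch(aggregate_window(env, tau, hw), gw_empty_window = function(e) NULL)
    if (!any(sel)) {
      # brute force says empty: either the nearest-fallback error fired or
      # nothing -- strict mode must have errored
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_lt(max(abs(got - colMeans(vals[sel, , drop = FALSE]))), 1e-9)
    }
  }
})

test_that("empty windows raise a typed error and the nearest fallback works", {
  env <- make_env(t0 + c(0, 7200), rbind(c(20, 60, 1, 400), c(22, 64, 1.2, 420)))
  err <- tryCatch(aggregate_window(env, t0 + 3600, 10), gw_empty_window = function(e) e)
  expect_s3_class(err, "gw_empty_window")
  expect_equal(err$tau, t0 + 3600)
  # nearest observation within 2*half_window
  near <- aggregate_window(env, t0 + 900, 10, fallback = "nearest")
  expect_equal(unname(near), c(20, 60, 1, 400))
  # nearest beyond 2*half_window still errors
  expect_error(aggregate_window(env, t0 + 3600, 10, fallback = "nearest"),
               class = "gw_empty_window")
})

test_that("ewma_smooth implements the stated recurrence", {
  expect_equal(ewma_smooth(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))  # alpha=1 identity
  expect_equal(ewma_smooth(rep(2.5, 10), 0.3), rep(2.5, 10))        # fixed point
  # frozen unroll of the recurrence with s(t0)=x(t0), alpha=0.2 on [0,0,1,1]
  expect_equal(ewma_smooth(c(0, 0, 1, 1), 0.2), c(0, 0, 0.2, 0.36), tolerance = 1e-12)
  expect_error(ewma_smooth(numeric(0), 0.2), "empty")
  expect_error(ewma_smooth(1:3, 0), "alpha")

  # convex-combination bound and matrix form
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  S <- ewma_smooth(X, 0.2)
  expect_equal(dim(S), dim(X))
  for (k in 1:3) {
    expect_true(all(S[, k] >= min(X[, k]) - 1e-12 & S[, k] <= max(X[, k]) + 1e-12))
  }
})

test_that("normalisation stats use the population convention and round-trip", {
  s <- fit_norm_stats(matrix(c(0, 2), ncol = 1L))
  expect_equal(unname(s$mu), 1)
  expect_equal(unname(s$sigma), 1)  # population sd of {0, 2}

  set.seed(6)
  X <- matrix(rnorm(200, 5, 3), 50, 4)
  colnames(X) <- c("temp_c", "rh_pct", "vpd_kpa", "co2_ppm")
  st <- fit_norm_stats(X)
  # two-pass oracle
  expect_equal(unname(st$mu), unname(colMeans(X)), tolerance = 1e-12)
  expect_equal(unname(st$sigma),
               unname(sqrt(colMeans(sweep(X, 2, colMeans(X))^2))), tolerance = 1e-12)

  Z <- normalize_env(X, st)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(sweep(Z, 2, colMeans(Z))^2)) - 1)), 1e-9)
  expect_lt(max(abs(denormalize_env(Z, st) - X)), 1e-12)

  expect_equal(unname(normalize_env(st$mu, st)), rep(0, 4))
  expect_equal(unname(normalize_env(st$mu + st$sigma, st)), rep(1, 4))

  expect_error(fit_norm_stats(matrix(1, 1, 4)), "at least 2")
  bad <- list(mu = rep(0, 4), sigma = c(1, 0, 1, 1))
  expect_error(normalize_env(X, bad), "degenerate")
})

test_that("augmentation is bounded, identity-capable and deterministic under a fixed seed", {
  img <- random_image(32L)
  idc <- augment_config(brightness_range = 0, contrast_range = 0, min_crop_area = 1)
  expect_identical(augment_image(img, idc), img)

  set.seed(9)
  a1 <- augment_image(img, augment_config())
  set.seed(9)
  a2 <- augment_image(img, augment_config())
  expect_identical(a1, a2)
  expect_equal(dim(a1), dim(img))
  expect_true(all(a1 >= 0 & a1 <= 1))
})

test_that("align_dataset yields one sample per frame in pipeline order", {
  ds <- tiny_dataset()
  al <- tiny_aligned()
  expect_equal(nrow(al$manifest), nrow(ds$manifest))
  expect_equal(nrow(al$env), nrow(ds$manifest))
  expect_true(all(is.finite(al$env)))
  expect_length(al$images, nrow(ds$manifest))
  expect_true(all(vapply(al$images, function(im) all(im >= 0 & im <= 1), logical(1L))))

  # smoothing reduces total variation relative to alpha = 1
  a1 <- align_dataset(ds, alignment_config(smoothing_alpha = 1))
  tv <- function(m) sum(abs(diff(m)))
  expect_lt(tv(al$env_raw), tv(a1$env_raw))
})

test_that("build_sequences windows never span events and label by final frame", {
  al <- tiny_aligned()
  seqs <- build_sequences(al, 6L)
  man <- al$manifest
  per_event <- table(man$event_id)
  expect_length(seqs, sum(pmax(0L, per_event - 6L + 1L)))
  for (s in seqs[seq(1, length(seqs), by = 7L)]) {
    expect_length(s$images, 6L)
    expect_false(is.unsorted(s$timestamps, strictly = TRUE))
    expect_equal(s$stage, s$stages[6L])
    rows <- man[man$event_id == s$event_id, ]
    expect_true(all(s$timestamps %in% rows$timestamp))
  }
  # an event shorter than T is skipped with a warning
  al2 <- al
  al2$manifest <- al$manifest[1:3, ]
  al2$env <- al$env[1:3, , drop = FALSE]
  al2$images <- al$images[1:3]
  expect_warning(s2 <- build_sequences(al2, 6L), "fewer than")
  expect_length(s2, 0L)

  # two events of exactly T frames give exactly two windows
  ids <- unique(man$event_id)[1:2]
  keep <- unlist(lapply(ids, function(i) which(man$event_id == i)[1:6]))
  al3 <- al
  al3$manifest <- al$manifest[keep, ]
  al3$env <- al$env[keep, , drop = FALSE]
  al3$images <- al$images[keep]
  s3 <- build_sequences(al3, 6L)
  expect_length(s3, 2L)
  expect_equal(sort(vapply(s3, `[[`, character(1L), "event_id")), sort(ids))
})

test_that("normalisation statistics can be fitted on a training subset only", {
  ds <- tiny_dataset()
  ids <- unique(ds$manifest$event_id)
  al <- align_dataset(ds, fit_events = ids[1:4], load_images = FALSE)
  fit_rows <- al$manifest$event_id %in% ids[1:4]
  agg <- al$env_raw[fit_rows, , drop = FALSE]
  expect_equal(unname(al$stats$mu), unname(colMeans(agg)), tolerance = 1e-12)
  # held-out rows are normalised with training stats, not their own
  expect_gt(max(abs(colMeans(al$env[!fit_rows, , drop = FALSE]))), 1e-6)
})
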