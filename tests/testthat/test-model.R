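# A reduced-width model used for the loop oracles (stage-1 width 8 so the
# oracle tensors stay small).
micro_model <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- build_model(model_config("desk", stage_channels = c(8L, 16L, 32L),
                                        backbone_heads = 2L, d_model = 16L,
                                        n_heads = 2L, env_embed_dim = 8L,
                                        align_dim = 16L, T = 2L, seed = 5L))
    }
    memo
  }
})

test_that("backbone stage outputs follow the 1/8, 1/16, 1/32 resolution scheme", {
  mp <- build_model(model_config("paper", seed = 1L))
  img <- random_image(64L)
  fb <- visual_backbone(mp, img)
  expect_equal(dim(fb[[1L]]), c(8L, 8L, 96L))
  expect_equal(dim(fb[[2L]]), c(4L, 4L, 192L))
  expect_equal(dim(fb[[3L]]), c(2L, 2L, 384L))

  # deterministic and input-sensitive
  fb2 <- visual_backbone(mp, img)
  expect_identical(fb, fb2)
  fb3 <- visual_backbone(mp, random_image(64L))
  expect_gt(max(abs(fb3[[1L]] - fb[[1L]])), 1e-6)

  expect_error(visual_backbone(mp, random_image(32L)), "image size")
  expect_error(model_config("paper", image_size = 60L), "divisible")
  expect_error(model_config("paper", d_model = 250L), "divisible")
})

test_that("environmental embedding dimensions match the stage channel widths", {
  m <- desk_model()
  eb <- embed_environment(m, c(0.1, -0.5, 1.2, 0.3))
  expect_length(eb$s, m$config$env_embed_dim)
  for (l in 1:3) {
    expect_length(eb$hierarchy[[l]], m$config$stage_channels[l])
  }
  # zero input with zero-initialised biases gives a zero base embedding
  e0 <- embed_environment(m, rep(0, 4))
  expect_equal(e0$s, rep(0, m$config$env_embed_dim))
  # deterministic
  expect_identical(eb, embed_environment(m, c(0.1, -0.5, 1.2, 0.3)))
})

test_that("environment-guided channel modulation matches a triple-loop oracle", {
  m <- micro_model()
  set.seed(71)
  for (rep in 1:3) {
    F <- array(rnorm(4 * 4 * 8), dim = c(4L, 4L, 8L))
    s <- rnorm(8)
    got <- env_guided_attention(m, F, s, stage = 1L)

    # independent loop computation of a_c, m_c and the channel modulation
    Ft <- matrix(0, 16L, 8L)
    for (y in 1:4) for (x in 1:4) Ft[(y - 1) * 4 + x, ] <- F[y, x, ]
    favg <- numeric(8); fmax <- numeric(8)
    for (c in 1:8) { favg[c] <- mean(Ft[, c]); fmax[c] <- max(Ft[, c]) }
    W <- m$params[["eg1.ca.W"]]; b <- m$params[["eg1.ca.b"]]
    a <- 1 / (1 + exp(-(c(favg, fmax) %*% W + b)))
    Wg <- m$params[["eg1.gate.W"]]; bg <- m$params[["eg1.gate.b"]]
    mm <- 1 / (1 + exp(-(s %*% Wg + bg)))
    pre <- matrix(0, 16L, 8L)
    for (i in 1:16) for (c in 1:8) pre[i, c] <- Ft[i, c] * a[c] * mm[c]

    expect_lt(max(abs(got$pre_residual - pre)), 1e-6)
    expect_lt(max(abs(got$a_channel - a)), 1e-9)
    expect_lt(max(abs(got$m_env - mm)), 1e-9)
    # gating bound: product of two sigmoids shrinks every entry
    expect_true(all(abs(got$pre_residual) <= abs(Ft) + 1e-12))
    expect_true(all(got$a_channel > 0 & got$a_channel < 1))
    expect_true(all(got$m_env > 0 & got$m_env < 1))
  }
})

test_that("environment-guided attention degenerate cases", {
  m <- micro_model()
  # all-zero features: modulated branch zero, zero-bias residual keeps zero
  z <- env_guided_attention(m, matrix(0, 16L, 8L), rnorm(8), stage = 1L)
  expect_equal(max(abs(z$pre_residual)), 0)
  expect_equal(max(abs(z$output)), 0)

  # zero environmental mapping -> m_c = sigmoid(0) = 0.5 everywhere
  m2 <- micro_model()
  m2$params[["eg1.gate.W"]][] <- 0
  m2$params[["eg1.gate.b"]][] <- 0
  F <- matrix(rnorm(16 * 8), 16L, 8L)
  g2 <- env_guided_attention(m2, F, rnorm(8), stage = 1L)
  expect_equal(g2$m_env, rep(0.5, 8L))
  expect_lt(max(abs(g2$pre_residual -
                      sweep(F, 2L, 0.5 * g2$a_channel, "*"))), 1e-9)

  expect_error(env_guided_attention(m, matrix(0, 16L, 4L), rnorm(8), 1L), "channels")
  expect_error(env_guided_attention(m, matrix(0, 16L, 8L), rnorm(3), 1L), "mismatch")
})

test_that("spatial saliency reweighting matches a direct loop implementation", {
  m <- micro_model()
  set.seed(72)
  F <- array(rnorm(6 * 6 * 8), dim = c(6L, 6L, 8L))
  got <- spatial_attention(m, F, stage = 1L)
  expect_true(all(got$A > 0 & got$A < 1))

  W <- m$params[["sa1.conv.W"]]; b <- m$params[["sa1.conv.b"]]
  A <- matrix(0, 6L, 6L)
  for (y in 1:6) for (x in 1:6) {
    acc <- 0; o <- 0L
    for (dy in -1:1) for (dx in -1:1) {
      o <- o + 1L
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= 6 && xx >= 1 && xx <= 6) {
        acc <- acc + mean(F[yy, xx, ]) * W[2 * (o - 1) + 1, 1] +
          max(F[yy, xx, ]) * W[2 * (o - 1) + 2, 1]
      }
    }
    A[y, x] <- 1 / (1 + exp(-(acc + b[1, 1])))
  }
  S <- array(0, dim = dim(F))
  for (y in 1:6) for (x in 1:6) for (c in 1:8) S[y, x, c] <- F[y, x, c] * A[y, x]

  # token row (y-1)*6 + x
  A_tok <- as.numeric(t(A))
  expect_lt(max(abs(got$A - A_tok)), 1e-6)
  St <- matrix(0, 36L, 8L)
  for (y in 1:6) for (x in 1:6) St[(y - 1) * 6 + x, ] <- S[y, x, ]
  expect_lt(max(abs(got$S - St)), 1e-6)
})

test_that("zeroed spatial convolution yields the A = 0.5 closed form", {
  m2 <- micro_model()
  m2$params[["sa1.conv.W"]][] <- 0
  m2$params[["sa1.conv.b"]][] <- 0
  F <- matrix(rnorm(16 * 8), 16L, 8L)
  got <- spatial_attention(m2, F, stage = 1L)
  expect_equal(got$A, rep(0.5, 16L))
  expect_lt(max(abs(got$S - 0.5 * F)), 1e-12)
})

test_that("the temporal attention core matches an explicit-loop softmax oracle", {
  # single head, identity output projection, FFN bypass via raw MHSA call
  d <- 8L
  set.seed(73)
  p <- list()
  p <- getFromNamespace("nn_init_mhsa", "greenwarn")(p, "tmp", d)
  p[["tmp.o.W"]] <- diag(d)
  p[["tmp.o.b"]] <- matrix(0, 1L, d)
  Z <- matrix(rnorm(4 * d), 4L, d)
  ctx <- getFromNamespace("ag_ctx", "greenwarn")()
  P <- getFromNamespace("nn_pgetter", "greenwarn")(ctx, p)
  res <- getFromNamespace("nn_mhsa", "greenwarn")(ctx, P, "tmp",
                                                  getFromNamespace("ag_const", "greenwarn")(ctx, Z),
                                                  n_heads = 1L)
  # loop oracle for h_t = sum_tau softmax(Q_t K_tau / sqrt(d)) V_tau
  Q <- Z %*% p[["tmp.q.W"]] + matrix(p[["tmp.q.b"]], 4L, d, byrow = TRUE)
  K <- Z %*% p[["tmp.k.W"]] + matrix(p[["tmp.k.b"]], 4L, d, byrow = TRUE)
  V <- Z %*% p[["tmp.v.W"]] + matrix(p[["tmp.v.b"]], 4L, d, byrow = TRUE)
  H <- matrix(0, 4L, d)
  Wm <- matrix(0, 4L, 4L)
  for (t in 1:4) {
    logits <- numeric(4L)
    for (tau in 1:4) logits[tau] <- sum(Q[t, ] * K[tau, ]) / sqrt(d)
    w <- exp(logits) / sum(exp(logits))
    Wm[t, ] <- w
    for (tau in 1:4) H[t, ] <- H[t, ] + w[tau] * V[tau, ]
  }
  expect_lt(max(abs(res$out$value - H)), 1e-6)
  expect_lt(max(abs(res$attn$value - Wm)), 1e-6)
  # attention rows are a probability distribution
  expect_lt(max(abs(rowSums(res$attn$value) - 1)), 1e-6)
})

test_that("temporal attention degenerates correctly for T = 1 and identical steps", {
  d <- 8L
  set.seed(74)
  p <- list()
  p <- getFromNamespace("nn_init_mhsa", "greenwarn")(p, "tmp", d)
  p[["tmp.o.W"]] <- diag(d)
  p[["tmp.o.b"]] <- matrix(0, 1L, d)
  ag_ctx <- getFromNamespace("ag_ctx", "greenwarn")
  ag_const <- getFromNamespace("ag_const", "greenwarn")
  nn_mhsa <- getFromNamespace("nn_mhsa", "greenwarn")
  nn_pgetter <- getFromNamespace("nn_pgetter", "greenwarn")

  z1 <- matrix(rnorm(d), 1L, d)
  ctx <- ag_ctx()
  r1 <- nn_mhsa(ctx, nn_pgetter(ctx, p), "tmp", ag_const(ctx, z1), 1L)
  expect_equal(r1$attn$value, matrix(1, 1L, 1L))
  V1 <- z1 %*% p[["tmp.v.W"]] + p[["tmp.v.b"]]
  expect_lt(max(abs(r1$out$value - V1)), 1e-9)

  zrep <- matrix(rep(rnorm(d), each = 5L), 5L, d)
  ctx <- ag_ctx()
  rr <- nn_mhsa(ctx, nn_pgetter(ctx, p), "tmp", ag_const(ctx, zrep), 1L)
  expect_lt(max(abs(rr$attn$value - 1 / 5)), 1e-9)
})

test_that("temporal_attention encoder runs bidirectionally and errors on empty input", {
  m <- desk_model()
  Z <- matrix(rnorm(6 * m$config$d_model), 6L)
  ta <- temporal_attention(m, Z)
  expect_equal(dim(ta$H), c(6L, m$config$d_model))
  expect_lt(max(abs(rowSums(ta$attn) - 1)), 1e-6)
  expect_error(temporal_attention(m, Z[0, , drop = FALSE]), "T >= 1")
})

test_that("model_forward produces a proper probability simplex and is deterministic", {
  m <- desk_model()
  set.seed(80)
  s <- random_sequence(m, Tn = 6L)
  o1 <- model_forward(m, s)
  expect_equal(sum(o1$stage_probs), 1, tolerance = 1e-6)
  expect_true(all(o1$stage_probs >= 0))
  for (a in o1$aux) expect_equal(sum(a), 1, tolerance = 1e-6)
  expect_length(o1$z_env, m$config$align_dim)
  expect_length(o1$z_vis, m$config$align_dim)
  expect_true(all(o1$A_spatial > 0 & o1$A_spatial < 1))
  expect_identical(model_forward(m, s)$stage_probs, o1$stage_probs)
})

test_that("the environmental guidance path is live and the ablation severs it", {
  cfgv <- model_config("desk", T = 4L, seed = 33L)
  m_full <- build_model(cfgv)
  cfg0 <- model_config("desk", T = 4L, seed = 33L, env_guidance = FALSE)
  m_abl <- build_model(cfg0)
  set.seed(81)
  s <- random_sequence(m_full, Tn = 4L)
  s2 <- s
  s2$env <- s$env + 1
  expect_gt(max(abs(model_forward(m_full, s2)$stage_probs -
                      model_forward(m_full, s)$stage_probs)), 0)
  expect_equal(model_forward(m_abl, s2)$stage_probs,
               model_forward(m_abl, s)$stage_probs)
  expect_null(model_forward(m_abl, s)$m_env)
})

test_that("checkpoints round-trip through disk", {
  m <- desk_model()
  pth <- tempfile(fileext = ".rds")
  save_checkpoint(m, pth)
  m2 <- load_checkpoint(pth)
  expect_equal(m2$params, m$params)
  set.seed(82)
  s <- random_sequence(m, Tn = 6L)
  expect_identical(model_forward(m, s)$stage_probs,
                   model_forward(m2, s)$stage_probs)
})

test_that("the temporal encoder carries the configured depth, heads and FFN width", {
  cfg <- model_config("paper")
  expect_equal(cfg$n_temporal_blocks, 6L)
  expect_equal(cfg$n_heads, 8L)
  expect_equal(cfg$d_model, 256L)
  expect_equal(cfg$ffn_mult, 4L)
  mp <- build_model(cfg)
  for (b in 1:6) {
    for (dir in c("tf", "tb")) {
      expect_equal(dim(mp$params[[paste0(dir, b, ".attn.q.W")]]), c(256L, 256L))
      expect_equal(dim(mp$params[[paste0(dir, b, ".ffn.fc1.W")]]), c(256L, 1024L))
    }
  }
  expect_null(mp$params[["tf7.attn.q.W"]])
})
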