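# Neural-network building blocks on top of the autodiff tape: parameter
# initialisation, linear layers, layer normalisation, multi-head attention,
# feed-forward blocks, and index machinery for patch embedding, patch
# merging, window partitioning and small convolutions on token grids.
#
# Token grids are stored row-major with x fastest: token index
# i = (y-1)*W + x for pixel (x, y) on an H x W grid, one row per token.

xavier_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Declare a linear layer's parameters into a plain list store.
nn_init_linear <- function(store, name, d_in, d_out, bias = TRUE) {
  store[[paste0(name, ".W")]] <- xavier_uniform(d_in, d_out)
  if (bias) store[[paste0(name, ".b")]] <- matrix(0, 1L, d_out)
  store
}

nn_init_layernorm <- function(store, name, d) {
  store[[paste0(name, ".g")]] <- matrix(1, 1L, d)
  store[[paste0(name, ".b")]] <- matrix(0, 1L, d)
  store
}

# Parameter getter bound to a context and a value store.
nn_pgetter <- function(ctx, params) {
  function(name) {
    v <- params[[name]]
    if (is.null(v)) stop("unknown parameter: ", name)
    ag_param(ctx, v, name)
  }
}

nn_linear <- function(ctx, P, name, x) {
  out <- ag_matmul(ctx, x, P(paste0(name, ".W")))
  bn <- paste0(name, ".b")
  out <- ag_add(ctx, out, P(bn))
  out
}

nn_layernorm <- function(ctx, P, name, x) {
  xn <- ag_rownorm(ctx, x)
  ag_add(ctx, ag_mul(ctx, xn, P(paste0(name, ".g"))), P(paste0(name, ".b")))
}

nn_init_mhsa <- function(store, name, d) {
  store <- nn_init_linear(store, paste0(name, ".q"), d, d)
  store <- nn_init_linear(store, paste0(name, ".k"), d, d)
  store <- nn_init_linear(store, paste0(name, ".v"), d, d)
  store <- nn_init_linear(store, paste0(name, ".o"), d, d)
  store
}

# Multi-head self-attention over N tokens of width d. `mask` (N x N, 0 or
# -1e9) restricts attention, e.g. to windows; NULL means global attention.
# Returns list(out, attn) where attn is the last head's weight matrix (kept
# for diagnostics).
nn_mhsa <- function(ctx, P, name, x, n_heads, mask = NULL) {
  d <- ncol(x$value)
  stopifnot(d %% n_heads == 0L)
  dh <- d %/% n_heads
  Q <- nn_linear(ctx, P, paste0(name, ".q"), x)
  K <- nn_linear(ctx, P, paste0(name, ".k"), x)
  V <- nn_linear(ctx, P, paste0(name, ".v"), x)
  mask_node <- if (!is.null(mask)) ag_const(ctx, mask)
  heads <- vector("list", n_heads)
  attn <- NULL
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- ag_gather_cols(ctx, Q, cols)
    Kh <- ag_gather_cols(ctx, K, cols)
    Vh <- ag_gather_cols(ctx, V, cols)
    S <- ag_scale(ctx, ag_matmul(ctx, Qh, ag_transpose(ctx, Kh)), 1 / sqrt(dh))
    if (!is.null(mask_node)) S <- ag_add(ctx, S, mask_node)
    A <- ag_softmax_rows(ctx, S)
    attn <- A
    heads[[h]] <- ag_matmul(ctx, A, Vh)
  }
  cat_h <- if (n_heads == 1L) heads[[1L]] else ag_cbind(ctx, heads)
  list(out = nn_linear(ctx, P, paste0(name, ".o"), cat_h), attn = attn)
}

nn_init_ffn <- function(store, name, d, mult) {
  store <- nn_init_linear(store, paste0(name, ".fc1"), d, d * mult)
  store <- nn_init_linear(store, paste0(name, ".fc2"), d * mult, d)
  store
}

nn_ffn <- function(ctx, P, name, x) {
  h <- ag_relu(ctx, nn_linear(ctx, P, paste0(name, ".fc1"), x))
  nn_linear(ctx, P, paste0(name, ".fc2"), h)
}

nn_init_block <- function(store, name, d, n_heads, ffn_mult) {
  store <- nn_init_mhsa(store, paste0(name, ".attn"), d)
  store <- nn_init_layernorm(store, paste0(name, ".ln1"), d)
  store <- nn_init_ffn(store, paste0(name, ".ffn"), d, ffn_mult)
  store <- nn_init_layernorm(store, paste0(name, ".ln2"), d)
  # LayerScale: residual branches start small so the untrained encoder is
  # near-identity and input statistics survive the stack (essential for
  # learnability at the small sample sizes this package trains on)
  store[[paste0(name, ".g1")]] <- matrix(0.1, 1L, d)
  store[[paste0(name, ".g2")]] <- matrix(0.1, 1L, d)
  store
}

# Pre-norm transformer block (the Swin/ViT convention, which keeps an
# identity residual stream) with LayerScale:
#   x = x + g1 * MSA(LN(x)); x = x + g2 * FFN(LN(x)).
nn_block <- function(ctx, P, name, x, n_heads, mask = NULL) {
  at <- nn_mhsa(ctx, P, paste0(name, ".attn"),
                nn_layernorm(ctx, P, paste0(name, ".ln1"), x), n_heads, mask)
  x <- ag_add(ctx, x, ag_mul(ctx, at$out, P(paste0(name, ".g1"))))
  f <- nn_ffn(ctx, P, paste0(name, ".ffn"),
              nn_layernorm(ctx, P, paste0(name, ".ln2"), x))
  x <- ag_add(ctx, x, ag_mul(ctx, f, P(paste0(name, ".g2"))))
  list(out = x, attn = at$attn)
}

# --- token-grid index machinery -----------------------------------------

grid_index <- function(x, y, W) (y - 1L) * W + x

# Additive attention mask confining attention to ws x ws windows of an
# H x W token grid. Entries 0 within a window, -1e9 across windows.
window_mask <- function(H, W, ws) {
  ws <- min(ws, H, W)
  stopifnot(H %% ws == 0L, W %% ws == 0L)
  n <- H * W
  xs <- rep(seq_len(W), times = H)
  ys <- rep(seq_len(H), each = W)
  wid <- ((ys - 1L) %/% ws) * (W %/% ws) + ((xs - 1L) %/% ws)
  M <- matrix(-1e9, n, n)
  same <- outer(wid, wid, "==")
  M[same] <- 0
  M
}

# Index matrix for 2x2 patch merging on an H x W grid: output token rows
# gather the 4 source tokens (x,y),(x+1,y),(x,y+1),(x+1,y+1).
merge_index <- function(H, W) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  xs <- rep(seq_len(Wo), times = Ho) * 2L - 1L
  ys <- rep(seq_len(Ho), each = Wo) * 2L - 1L
  cbind(grid_index(xs, ys, W), grid_index(xs + 1L, ys, W),
        grid_index(xs, ys + 1L, W), grid_index(xs + 1L, ys + 1L, W))
}

# im2col index for a k x k convolution with zero padding (stride 1): one row
# per output pixel, one column per kernel offset, 0 marks out-of-bounds.
conv_index <- function(H, W, k) {
  stopifnot(k %% 2L == 1L)
  r <- (k - 1L) %/% 2L
  xs <- rep(seq_len(W), times = H)
  ys <- rep(seq_len(H), each = W)
  idx <- matrix(0L, H * W, k * k)
  col <- 0L
  for (dy in -r:r) for (dx in -r:r) {
    col <- col + 1L
    xn <- xs + dx; yn <- ys + dy
    ok <- xn >= 1L & xn <= W & yn >= 1L & yn <= H
    v <- integer(H * W)
    v[ok] <- grid_index(xn[ok], yn[ok], W)
    idx[, col] <- v
  }
  idx
}

nn_init_conv <- function(store, name, k, c_in, c_out) {
  nn_init_linear(store, name, k * k * c_in, c_out)
}

# k x k conv over a token grid: gather k^2 shifted copies, concat channels,
# apply as a linear layer. idx from conv_index(H, W, k).
nn_conv <- function(ctx, P, name, x, idx) {
  taps <- lapply(seq_len(ncol(idx)), function(o) ag_gather_rows(ctx, x, idx[, o]))
  patches <- if (length(taps) == 1L) taps[[1L]] else ag_cbind(ctx, taps)
  nn_linear(ctx, P, name, patches)
}

# Rearrange an H x W x 3 image array into patch tokens:
# (H/p * W/p) x (p*p*3), channel-last within a patch, x fastest.
image_to_patches <- function(img, p) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  stopifnot(H %% p == 0L, W %% p == 0L)
  Hp <- H %/% p; Wp <- W %/% p
  out <- matrix(0, Hp * Wp, p * p * 3L)
  for (py in seq_len(Hp)) {
    for (px in seq_len(Wp)) {
      block <- img[((py - 1L) * p + 1L):(py * p),
                   ((px - 1L) * p + 1L):(px * p), , drop = FALSE]
      out[grid_index(px, py, Wp), ] <- as.numeric(block)
    }
  }
  out
}
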