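# The dual-branch early-disease perception network.
#
# Visual branch: patch embedding, then a hierarchical windowed-attention
# encoder with patch merging producing three stages at 1/8, 1/16 and 1/32
# of the input resolution with (96, 192, 384) channels in the reference
# profile. Sensor branch: a linear environmental embedding refined by a
# per-stage linear+ReLU hierarchy. After every backbone stage the
# environmental representation gates the visual channels
# (F~_c = F_c * a_c * m_c, both gates sigmoid), a 1x1-conv spatial map
# reweights the gated features, and the result is injected back residually.
# A spatial saliency map (channel mean/max -> 3x3 conv -> sigmoid) then
# reweights each frame; pooled per-frame descriptors feed a bidirectional
# temporal attention encoder whose fused final step, concatenated with the
# final frame's high-level visual semantics, yields the stage probabilities.
#
# Feature maps are token matrices (HW x C, x fastest); helpers convert to
# H x W x C arrays at the public boundary.

#' Model configuration
#'
#' The `"paper"` profile carries the reference dimensions: stage channels
#' (96, 192, 384) at 1/8, 1/16, 1/32 resolution, a 256-dimensional temporal
#' embedding with 8 heads, six stacked temporal attention blocks and
#' feed-forward width 4d. The `"desk"` profile shrinks widths and depth for
#' CPU-scale training while keeping every equation identical.
#'
#' @param profile `"paper"` or `"desk"`.
#' @param image_size square input side (must be divisible by 32).
#' @param patch_size patch embedding size (stage downsample factors are
#'   `patch_size * c(2, 4, 8)`).
#' @param stage_channels integer 3-vector of per-stage channel widths.
#' @param window_size attention window (tokens) in the visual backbone.
#' @param env_dim environmental input dimension (4).
#' @param env_embed_dim base environmental embedding width.
#' @param d_model temporal embedding dimension d.
#' @param n_heads temporal attention heads (d must be divisible).
#' @param backbone_heads attention heads in the visual backbone.
#' @param n_temporal_blocks stacked temporal attention blocks per direction.
#' @param ffn_mult feed-forward hidden width as a multiple of d.
#' @param n_classes number of disease stages (3).
#' @param T sequence length (frames per sample).
#' @param aux_scales backbone stages receiving auxiliary deep-supervision
#'   heads (subset of 1:3).
#' @param align_dim shared dimension D of the alignment embeddings
#'   z_env/z_vis.
#' @param env_guidance FALSE removes the environmental gate m_c (vision-only
#'   ablation; the predicted probabilities then carry zero gradient with
#'   respect to the environmental input).
#' @param spatial_head emit a per-pixel lesion probability map at stage 1.
#' @param seed initialisation seed (Xavier uniform weights).
#' @return a `gw_model_config` list.
#' @export
model_config <- function(profile = c("paper", "desk"),
                         image_size = NULL, patch_size = 4L,
                         stage_channels = NULL, window_size = 4L,
                         env_dim = 4L, env_embed_dim = NULL,
                         d_model = NULL, n_heads = NULL,
                         backbone_heads = NULL, n_temporal_blocks = NULL,
                         ffn_mult = 4L, n_classes = 3L, T = 6L,
                         aux_scales = c(1L, 2L), align_dim = NULL,
                         env_guidance = TRUE, spatial_head = FALSE,
                         seed = 1L) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") {
    list(image_size = 64L, patch_size = 4L,
         stage_channels = c(96L, 192L, 384L),
         env_embed_dim = 64L, d_model = 256L, n_heads = 8L,
         backbone_heads = 8L, n_temporal_blocks = 6L, align_dim = 128L)
  } else {
    list(image_size = 64L, patch_size = 8L,
         stage_channels = c(16L, 32L, 64L),
         env_embed_dim = 16L, d_model = 64L, n_heads = 2L,
         backbone_heads = 2L, n_temporal_blocks = 2L, align_dim = 32L)
  }
  pick <- function(x, d) if (is.null(x)) d else x
  if (missing(patch_size)) patch_size <- def$patch_size
  cfg <- list(profile = profile,
              image_size = as.integer(pick(image_size, def$image_size)),
              patch_size = as.integer(patch_size),
              stage_channels = as.integer(pick(stage_channels, def$stage_channels)),
              stage_downsamples = as.integer(patch_size) * c(2L, 4L, 8L),
              window_size = as.integer(window_size),
              env_dim = as.integer(env_dim),
              env_embed_dim = as.integer(pick(env_embed_dim, def$env_embed_dim)),
              d_model = as.integer(pick(d_model, def$d_model)),
              n_heads = as.integer(pick(n_heads, def$n_heads)),
              backbone_heads = as.integer(pick(backbone_heads, def$backbone_heads)),
              n_temporal_blocks = as.integer(pick(n_temporal_blocks, def$n_temporal_blocks)),
              ffn_mult = as.integer(ffn_mult),
              n_classes = as.integer(n_classes),
              T = as.integer(T),
              aux_scales = as.integer(aux_scales),
              align_dim = as.integer(pick(align_dim, def$align_dim)),
              env_guidance = isTRUE(env_guidance),
              spatial_head = isTRUE(spatial_head),
              seed = as.integer(seed))
  validate_model_config(cfg)
  class(cfg) <- "gw_model_config"
  cfg
}

validate_model_config <- function(cfg) {
  if (length(cfg$stage_channels) != length(cfg$stage_downsamples)) {
    stop("stage_channels and stage_downsamples must have equal length")
  }
  if (cfg$image_size %% max(cfg$stage_downsamples) != 0L) {
    stop("image_size must be divisible by the largest stage downsample (",
         max(cfg$stage_downsamples), ")")
  }
  if (cfg$d_model %% cfg$n_heads != 0L) {
    stop("d_model must be divisible by n_heads")
  }
  c0 <- cfg$stage_channels[1L] %/% 2L
  for (ch in c(c0, cfg$stage_channels)) {
    if (ch %% cfg$backbone_heads != 0L) {
      stop("stage channel width ", ch,
           " is not divisible by backbone_heads = ", cfg$backbone_heads)
    }
  }
  if (!all(cfg$aux_scales %in% seq_along(cfg$stage_channels))) {
    stop("aux_scales must index backbone stages")
  }
  invisible(cfg)
}

# Grid side lengths: pre-merge token grid, then the three stages.
model_grids <- function(cfg) {
  g0 <- cfg$image_size %/% cfg$patch_size
  c(g0, cfg$image_size %/% cfg$stage_downsamples)
}

#' Build a model with Xavier-uniform initialised parameters
#'
#' @param config a [model_config()].
#' @return a `gw_model` list with `params` (named matrices), `config`, and
#'   cached index structures.
#' @export
build_model <- function(config) {
  validate_model_config(config)
  set.seed(config$seed)
  cfg <- config
  g <- model_grids(cfg)
  c0 <- cfg$stage_channels[1L] %/% 2L
  chans <- c(c0, cfg$stage_channels)
  p <- list()

  p <- nn_init_linear(p, "patch_embed", cfg$patch_size^2 * 3L, c0)
  for (l in 0:3) {
    ch <- chans[l + 1L]
    p <- nn_init_block(p, paste0("bb", l), ch, cfg$backbone_heads, cfg$ffn_mult)
    if (l > 0L) {
      p <- nn_init_linear(p, paste0("merge", l), 4L * chans[l], ch)
    }
  }
  # sensor branch
  p <- nn_init_linear(p, "env_proj", cfg$env_dim, cfg$env_embed_dim)
  prev <- cfg$env_embed_dim
  for (l in 1:3) {
    p <- nn_init_linear(p, paste0("env_stage", l), prev, cfg$stage_channels[l])
    prev <- cfg$stage_channels[l]
  }
  # environment-guided attention + spatial attention per stage
  for (l in 1:3) {
    C <- cfg$stage_channels[l]
    p <- nn_init_linear(p, paste0("eg", l, ".ca"), 2L * C, C)
    p <- nn_init_linear(p, paste0("eg", l, ".gate"), C, C)
    p <- nn_init_linear(p, paste0("eg", l, ".sp"), C, 1L)
    p <- nn_init_linear(p, paste0("eg", l, ".res"), C, C)
    p <- nn_init_conv(p, paste0("sa", l, ".conv"), 3L, 2L, 1L)
  }
  # temporal encoder
  p <- nn_init_linear(p, "tproj", cfg$stage_channels[3L], cfg$d_model)
  for (b in seq_len(cfg$n_temporal_blocks)) {
    p <- nn_init_block(p, paste0("tf", b), cfg$d_model, cfg$n_heads, cfg$ffn_mult)
    p <- nn_init_block(p, paste0("tb", b), cfg$d_model, cfg$n_heads, cfg$ffn_mult)
  }
  p <- nn_init_linear(p, "tfuse", 2L * cfg$d_model, cfg$d_model)
  # heads
  p <- nn_init_linear(p, "head", cfg$d_model + cfg$stage_channels[3L],
                      cfg$n_classes)
  for (l in cfg$aux_scales) {
    p <- nn_init_linear(p, paste0("aux", l), cfg$stage_channels[l], cfg$n_classes)
  }
  p <- nn_init_linear(p, "zvis", cfg$stage_channels[3L], cfg$align_dim)
  p <- nn_init_linear(p, "zenv", cfg$stage_channels[3L], cfg$align_dim)
  if (cfg$spatial_head) {
    p <- nn_init_linear(p, "sphead", cfg$stage_channels[1L], 1L)
  }

  cache <- list(
    masks = lapply(g, function(s) window_mask(s, s, cfg$window_size)),
    merges = lapply(g[1:3], function(s) merge_index(s, s)),
    convs = lapply(g[2:4], function(s) conv_index(s, s, 3L)),
    grids = g,
    memo = new.env(parent = emptyenv()))
  structure(list(params = p, config = cfg, cache = cache),
            class = "gw_model")
}

# --- frame-stacking machinery -------------------------------------------
#
# All T frames of a sequence are pushed through the backbone as one token
# matrix (frame-major row blocks); window masks become block-diagonal, and
# per-frame pooling becomes a constant-matrix product. This keeps the tape
# short and the matrix ops BLAS-sized.

stack_mask <- function(mask, Tn) {
  if (Tn == 1L) return(mask)
  n <- nrow(mask)
  M <- matrix(-1e9, n * Tn, n * Tn)
  for (t in seq_len(Tn)) {
    ix <- ((t - 1L) * n + 1L):(t * n)
    M[ix, ix] <- mask
  }
  M
}

stack_index <- function(idx, Tn, n_src) {
  if (Tn == 1L) return(idx)
  do.call(rbind, lapply(seq_len(Tn), function(t) {
    out <- idx + (t - 1L) * n_src
    out[idx == 0L] <- 0L
    out
  }))
}

frame_pool_matrix <- function(Tn, n_tok) {
  P <- matrix(0, Tn, Tn * n_tok)
  for (t in seq_len(Tn)) {
    P[t, ((t - 1L) * n_tok + 1L):(t * n_tok)] <- 1 / n_tok
  }
  P
}

stacked_cache <- function(model, Tn) {
  key <- paste0("T", Tn)
  memo <- model$cache$memo
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  g <- model$cache$grids
  sc <- list(
    masks = lapply(seq_along(g), function(i) {
      stack_mask(model$cache$masks[[i]], Tn)
    }),
    merges = lapply(1:3, function(l) {
      stack_index(model$cache$merges[[l]], Tn, g[l]^2)
    }),
    convs = lapply(1:3, function(l) {
      stack_index(model$cache$convs[[l]], Tn, g[l + 1L]^2)
    }),
    pools = lapply(1:3, function(l) frame_pool_matrix(Tn, g[l + 1L]^2)),
    n_tok = g^2)
  memo[[key]] <- sc
  sc
}

#' Number of trainable parameters
#' @param model a `gw_model`.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1L)))
}

#' @export
print.gw_model <- function(x, ...) {
  cfg <- x$config
  cat("<gw_model> profile=", cfg$profile,
      " stages=(", paste(cfg$stage_channels, collapse = ","), ")",
      " d=", cfg$d_model, " heads=", cfg$n_heads,
      " blocks=", cfg$n_temporal_blocks,
      " params=", count_params(x),
      if (!cfg$env_guidance) " [no-env-guidance]", "\n", sep = "")
  invisible(x)
}

tokens_to_array <- function(m, side) {
  # token row i = (y-1)*side + x  ->  array[y, x, c]
  a <- array(0, dim = c(side, side, ncol(m)))
  for (c in seq_len(ncol(m))) a[, , c] <- matrix(m[, c], side, side, byrow = TRUE)
  a
}

array_to_tokens <- function(a) {
  if (is.matrix(a)) return(a)
  side_y <- dim(a)[1L]; side_x <- dim(a)[2L]; C <- dim(a)[3L]
  m <- matrix(0, side_y * side_x, C)
  for (c in seq_len(C)) m[, c] <- as.numeric(t(a[, , c]))
  m
}

# --- graph-building components ------------------------------------------

# Environmental hierarchy: s = relu(W e~), S^(l) = relu(W_l S^(l-1)).
# Rows = frames (row-wise, so all frames are processed in one pass).
env_branch_graph <- function(ctx, P, env_rows) {
  s <- ag_relu(ctx, nn_linear(ctx, P, "env_proj", env_rows))
  S <- vector("list", 3L)
  prev <- s
  for (l in 1:3) {
    prev <- ag_relu(ctx, nn_linear(ctx, P, paste0("env_stage", l), prev))
    S[[l]] <- prev
  }
  list(s = s, S = S)
}

# Backbone over Tn stacked frames: returns per-stage token-matrix nodes
# (frame-major row blocks).
backbone_graph <- function(ctx, P, model, patches, sc) {
  cfg <- model$config
  x <- nn_linear(ctx, P, "patch_embed", patches)
  x <- nn_block(ctx, P, "bb0", x, cfg$backbone_heads, sc$masks[[1L]])$out
  feats <- vector("list", 3L)
  for (l in 1:3) {
    mi <- sc$merges[[l]]
    merged <- ag_cbind(ctx, lapply(seq_len(4L), function(o) {
      ag_gather_rows(ctx, x, mi[, o])
    }))
    x <- nn_linear(ctx, P, paste0("merge", l), merged)
    x <- nn_block(ctx, P, paste0("bb", l), x, cfg$backbone_heads,
                  sc$masks[[l + 1L]])$out
    feats[[l]] <- x
  }
  feats
}

# Environment-guided visual attention at stage l (channel gating plus the 1x1-conv
# spatial refinement and residual injection). F holds Tn stacked frames;
# S_l is the Tn x C environmental hierarchy slice.
egva_graph <- function(ctx, P, model, F, S_l, l, Tn, n_tok) {
  desc <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    ft <- if (Tn == 1L) F else {
      ag_gather_rows(ctx, F, ((t - 1L) * n_tok + 1L):(t * n_tok))
    }
    desc[[t]] <- ag_cbind(ctx, list(ag_mean_rows(ctx, ft),
                                    ag_max_rows(ctx, ft)))
  }
  dmat <- if (Tn == 1L) desc[[1L]] else ag_rbind(ctx, desc)
  a <- ag_sigmoid(ctx, nn_linear(ctx, P, paste0("eg", l, ".ca"), dmat))
  m <- NULL
  gate <- a
  if (model$config$env_guidance) {
    m <- ag_sigmoid(ctx, nn_linear(ctx, P, paste0("eg", l, ".gate"), S_l))
    gate <- ag_mul(ctx, a, m)
  }
  gate_full <- if (Tn == 1L) gate else {
    ag_gather_rows(ctx, gate, rep(seq_len(Tn), each = n_tok))
  }
  Fm <- ag_mul(ctx, F, gate_full)
  As <- ag_sigmoid(ctx, nn_linear(ctx, P, paste0("eg", l, ".sp"), Fm))
  Fsp <- ag_mul(ctx, Fm, As)
  out <- ag_add(ctx, F, nn_linear(ctx, P, paste0("eg", l, ".res"), Fsp))
  list(out = out, pre_residual = Fm, a = a, m = m, As = As)
}

# Spatial saliency reweighting at stage l; row-wise, so it applies
# unchanged to stacked frames (the conv index is frame-block-diagonal).
spatial_graph <- function(ctx, P, model, F, l, sc) {
  avg <- ag_rowmeans(ctx, F)
  mx <- ag_rowmax(ctx, F)
  A <- ag_sigmoid(ctx, nn_conv(ctx, P, paste0("sa", l, ".conv"),
                               ag_cbind(ctx, list(avg, mx)),
                               sc$convs[[l]]))
  list(out = ag_mul(ctx, F, A), A = A)
}

# Bidirectional temporal encoder over a T x d_model step matrix.
temporal_graph <- function(ctx, P, model, Z) {
  cfg <- model$config
  Tn <- nrow(Z$value)
  xf <- Z
  xb <- if (Tn > 1L) ag_gather_rows(ctx, Z, rev(seq_len(Tn))) else Z
  attn <- NULL
  for (b in seq_len(cfg$n_temporal_blocks)) {
    rf <- nn_block(ctx, P, paste0("tf", b), xf, cfg$n_heads)
    xf <- rf$out
    attn <- rf$attn
    xb <- nn_block(ctx, P, paste0("tb", b), xb, cfg$n_heads)$out
  }
  if (Tn > 1L) xb <- ag_gather_rows(ctx, xb, rev(seq_len(Tn)))
  H <- nn_linear(ctx, P, "tfuse", ag_cbind(ctx, list(xf, xb)))
  list(H = H, attn = attn)
}

# Full forward graph for one sequence sample. `patches` holds the Tn
# frames' patch matrices stacked row-wise. Returns nodes.
forward_graph <- function(ctx, model, seq_env, patches, Tn) {
  cfg <- model$config
  P <- nn_pgetter(ctx, model$params)
  sc <- stacked_cache(model, Tn)
  eb <- env_branch_graph(ctx, P, ag_const(ctx, seq_env))
  feats <- backbone_graph(ctx, P, model, ag_const(ctx, patches), sc)
  stage_out <- vector("list", 3L)
  for (l in 1:3) {
    eg <- egva_graph(ctx, P, model, feats[[l]], eb$S[[l]], l, Tn,
                     sc$n_tok[l + 1L])
    sp <- spatial_graph(ctx, P, model, eg$out, l, sc)
    stage_out[[l]] <- list(eg = eg, sp = sp)
  }
  eg3 <- stage_out[[3L]]$eg
  sp3 <- stage_out[[3L]]$sp

  pooled <- ag_matmul(ctx, ag_const(ctx, sc$pools[[3L]]), sp3$out)  # Tn x C3
  Z <- nn_linear(ctx, P, "tproj", pooled)
  tg <- temporal_graph(ctx, P, model, Z)
  hT <- if (Tn == 1L) tg$H else ag_gather_rows(ctx, tg$H, Tn)
  sem <- if (Tn == 1L) pooled else ag_gather_rows(ctx, pooled, Tn)
  logits <- nn_linear(ctx, P, "head", ag_cbind(ctx, list(hT, sem)))
  probs <- ag_softmax_rows(ctx, logits)

  aux <- list()
  for (l in cfg$aux_scales) {
    pl <- ag_matmul(ctx, ag_const(ctx, sc$pools[[l]]),
                    stage_out[[l]]$sp$out)
    plT <- if (Tn == 1L) pl else ag_gather_rows(ctx, pl, Tn)
    aux[[as.character(l)]] <- ag_softmax_rows(
      ctx, nn_linear(ctx, P, paste0("aux", l), plT))
  }
  pooled_eg3 <- ag_matmul(ctx, ag_const(ctx, sc$pools[[3L]]), eg3$out)
  vis_final <- if (Tn == 1L) pooled_eg3 else ag_gather_rows(ctx, pooled_eg3, Tn)
  zvis <- nn_linear(ctx, P, "zvis", vis_final)
  env_final <- if (Tn == 1L) eb$S[[3L]] else ag_gather_rows(ctx, eb$S[[3L]], Tn)
  zenv <- nn_linear(ctx, P, "zenv", env_final)
  pmap <- NULL
  if (cfg$spatial_head) {
    n1 <- sc$n_tok[2L]
    sp1_final <- if (Tn == 1L) stage_out[[1L]]$sp$out else {
      ag_gather_rows(ctx, stage_out[[1L]]$sp$out,
                     ((Tn - 1L) * n1 + 1L):(Tn * n1))
    }
    pmap <- ag_sigmoid(ctx, nn_linear(ctx, P, "sphead", sp1_final))
  }
  n3 <- sc$n_tok[4L]
  A3_final_rows <- ((Tn - 1L) * n3 + 1L):(Tn * n3)
  list(probs = probs, aux = aux, zvis = zvis, zenv = zenv, pmap = pmap,
       attn_temporal = tg$attn,
       A_spatial = sp3$A$value[A3_final_rows, , drop = FALSE],
       a_channel = eg3$a$value[Tn, , drop = FALSE],
       m_env = if (!is.null(eg3$m)) eg3$m$value[Tn, , drop = FALSE])
}

seq_to_patches <- function(model, sequence) {
  do.call(rbind, lapply(sequence$images, image_to_patches,
                        p = model$config$patch_size))
}

#' Run the model on one sequence sample
#'
#' @param model a `gw_model`.
#' @param sequence a `sequence_sample` from [build_sequences()], or a list
#'   with `images` (list of H x W x 3 arrays) and `env` (T x 4 matrix).
#' @return a `model_outputs` list: `stage_probs` (named probability
#'   vector), `aux` (per-scale probability vectors), `z_env`, `z_vis`,
#'   `spatial_map` (or NULL), and diagnostic attention maps
#'   `attn_temporal`, `A_spatial`, `a_channel`, `m_env`.
#' @export
model_forward <- function(model, sequence) {
  stopifnot(inherits(model, "gw_model"))
  patches <- seq_to_patches(model, sequence)
  Tn <- length(sequence$images)
  ctx <- ag_ctx()
  fg <- forward_graph(ctx, model, sequence$env, patches, Tn)
  g1 <- model$cache$grids[2L]
  structure(list(
    stage_probs = stats::setNames(as.numeric(fg$probs$value),
                                  STAGE_LEVELS[seq_len(model$config$n_classes)]),
    aux = lapply(fg$aux, function(n) as.numeric(n$value)),
    z_env = as.numeric(fg$zenv$value),
    z_vis = as.numeric(fg$zvis$value),
    spatial_map = if (!is.null(fg$pmap)) matrix(fg$pmap$value, g1, g1, byrow = TRUE),
    attn_temporal = fg$attn_temporal$value,
    A_spatial = as.numeric(fg$A_spatial),
    a_channel = as.numeric(fg$a_channel),
    m_env = if (!is.null(fg$m_env)) as.numeric(fg$m_env)),
    class = "model_outputs")
}

#' Environmental embedding and per-stage hierarchy
#'
#' Linear projection of the aligned environmental 4-vector followed by
#' stacked linear+ReLU layers, one per backbone stage, dimensioned to the
#' stage channel widths (so the stage-l gate can map them channel-wise).
#'
#' @param model a `gw_model`.
#' @param env_vector numeric 4-vector (aligned, normalised).
#' @return list with `s` (base embedding) and `hierarchy` (list of
#'   per-stage vectors).
#' @export
embed_environment <- function(model, env_vector) {
  stopifnot(is.finite(env_vector), length(env_vector) == model$config$env_dim)
  ctx <- ag_ctx()
  P <- nn_pgetter(ctx, model$params)
  eb <- env_branch_graph(ctx, P, ag_const(ctx, matrix(env_vector, 1L)))
  list(s = as.numeric(eb$s$value),
       hierarchy = lapply(eb$S, function(n) as.numeric(n$value)))
}

#' Hierarchical visual backbone features for one image
#'
#' @param model a `gw_model`.
#' @param image H x W x 3 array in [0, 1] of the configured size.
#' @return list of three H' x W' x C arrays at 1/8, 1/16, 1/32 resolution.
#' @export
visual_backbone <- function(model, image) {
  if (!all(dim(image)[1:2] == model$config$image_size)) {
    stop("image size must be ", model$config$image_size)
  }
  ctx <- ag_ctx()
  P <- nn_pgetter(ctx, model$params)
  feats <- backbone_graph(ctx, P, model,
                          ag_const(ctx, image_to_patches(image, model$config$patch_size)),
                          stacked_cache(model, 1L))
  lapply(seq_len(3L), function(l) {
    tokens_to_array(feats[[l]]$value, model$cache$grids[l + 1L])
  })
}

#' Environment-guided visual attention (standalone)
#'
#' Applies the channel gates a_c and m_c, the 1x1-convolution spatial map,
#' and the residual injection to a single stage feature map.
#'
#' @param model a `gw_model`.
#' @param F feature map: H' x W' x C array or HW x C token matrix for
#'   stage `stage`.
#' @param s_stage environmental hierarchy vector for that stage (from
#'   [embed_environment()]`$hierarchy[[stage]]`).
#' @param stage backbone stage index (1-3).
#' @return list with `output`, `pre_residual` (token matrices), `a_channel`,
#'   `m_env`, `A_s`.
#' @export
env_guided_attention <- function(model, F, s_stage, stage) {
  Fm <- array_to_tokens(F)
  C <- model$config$stage_channels[stage]
  if (ncol(Fm) != C) {
    stop("feature map has ", ncol(Fm), " channels; stage ", stage,
         " expects ", C)
  }
  if (length(s_stage) != C) stop("environmental vector/channel mismatch")
  ctx <- ag_ctx()
  P <- nn_pgetter(ctx, model$params)
  eg <- egva_graph(ctx, P, model, ag_const(ctx, Fm),
                   ag_const(ctx, matrix(s_stage, 1L)), stage,
                   Tn = 1L, n_tok = nrow(Fm))
  list(output = eg$out$value, pre_residual = eg$pre_residual$value,
       a_channel = as.numeric(eg$a$value),
       m_env = if (!is.null(eg$m)) as.numeric(eg$m$value),
       A_s = as.numeric(eg$As$value))
}

#' Spatial saliency attention (standalone)
#'
#' Channel-wise mean and max maps, concatenated, 3x3 convolution, sigmoid;
#' the resulting map A_t reweights the features.
#'
#' @param model a `gw_model`.
#' @param F stage feature map (array or token matrix).
#' @param stage backbone stage index (1-3).
#' @return list with `S` (reweighted token matrix) and `A` (saliency
#'   vector, one entry per token).
#' @export
spatial_attention <- function(model, F, stage) {
  Fm <- array_to_tokens(F)
  idx <- if (is.matrix(F)) {
    side <- as.integer(round(sqrt(nrow(Fm))))
    if (side^2 != nrow(Fm)) stop("token matrix is not a square grid")
    conv_index(side, side, 3L)
  } else {
    conv_index(dim(F)[1L], dim(F)[2L], 3L)
  }
  ctx <- ag_ctx()
  P <- nn_pgetter(ctx, model$params)
  sp <- spatial_graph(ctx, P, model, ag_const(ctx, Fm), stage,
                      list(convs = list(idx, idx, idx)))
  list(S = sp$out$value, A = as.numeric(sp$A$value))
}

#' Bidirectional temporal attention encoder (standalone)
#'
#' @param model a `gw_model`.
#' @param Z T x d_model matrix of per-step embeddings (pooled frame
#'   descriptors after projection).
#' @return list with `H` (T x d_model joint representation) and `attn`
#'   (the last forward block's attention weights, rows summing to 1).
#' @export
temporal_attention <- function(model, Z) {
  if (nrow(Z) < 1L) stop("temporal input must have T >= 1 steps")
  stopifnot(ncol(Z) == model$config$d_model)
  ctx <- ag_ctx()
  P <- nn_pgetter(ctx, model$params)
  tg <- temporal_graph(ctx, P, model, ag_const(ctx, Z))
  list(H = tg$H$value, attn = tg$attn$value)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single RDS file holding the parameter list and the
#' full model configuration.
#'
#' @param model a `gw_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(params = model$params, config = unclass(model$config)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- obj$config
  class(cfg) <- "gw_model_config"
  m <- build_model(cfg)
  m$params <- obj$params
  m
}
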