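# The four-term joint training objective:
#   L = L_sup + lambda_early * L_early + lambda_align * L_align
#             + lambda_ds * L_ds
# with L_sup the (optionally mask-augmented) cross-entropy, L_early the
# stage-weighted cross-entropy upweighting early samples, L_align the
# cosine misalignment between the environmental and visual embeddings, and
# L_ds the deep-supervision sum over auxiliary scales. All terms are
# non-negative and the alignment term lies in [0, 2], so the total is
# bounded below by zero for non-negative weights.
#
# Public functions operate on plain numeric arrays (these are what the
# oracle tests check); graph twins used during training live alongside and
# are asserted equal to the numeric route in the test suite.

#' Loss configuration
#'
#' @param lambda_early weight of the early-stage term (reference value 0.5).
#' @param lambda_align weight of the alignment term (reference value 0.1).
#' @param lambda_ds weight of the deep-supervision term (reference 0.3).
#' @param beta weight of the optional spatial (mask) loss inside L_sup;
#'   unstated in the reference setup, 0.5 here.
#' @param gamma early-sample upweight increment (w = 1 + gamma for early
#'   samples); unstated in the reference setup, 1.0 here.
#' @param alpha_per_scale named numeric vector of per-scale weights for the
#'   deep-supervision term; NULL = uniform 1/|Omega| at use time.
#' @param spatial_loss `"bce"` (default) or `"dice"` for the mask term.
#' @param epsilon clamp for logarithms and the alignment denominator.
#' @return a `loss_config` list.
#' @export
loss_config <- function(lambda_early = 0.5, lambda_align = 0.1,
                        lambda_ds = 0.3, beta = 0.5, gamma = 1.0,
                        alpha_per_scale = NULL,
                        spatial_loss = c("bce", "dice"),
                        epsilon = 1e-8) {
  if (lambda_early < 0 || lambda_align < 0 || lambda_ds < 0) {
    stop("loss weights must be >= 0 (required for the lower-bound property)")
  }
  if (gamma < 0) stop("gamma must be >= 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(lambda_early = lambda_early, lambda_align = lambda_align,
                 lambda_ds = lambda_ds, beta = beta, gamma = gamma,
                 alpha_per_scale = alpha_per_scale,
                 spatial_loss = match.arg(spatial_loss),
                 epsilon = epsilon),
            class = "loss_config")
}

as_prob_matrix <- function(y_hat) {
  if (!is.matrix(y_hat)) y_hat <- matrix(y_hat, nrow = 1L)
  y_hat
}

one_hot <- function(stages, levels = STAGE_LEVELS) {
  idx <- match(stages, levels)
  if (anyNA(idx)) stop("unknown stage label: ",
                       paste(unique(stages[is.na(idx)]), collapse = ", "))
  Y <- matrix(0, length(idx), length(levels))
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

ce_rows <- function(y_hat, y, eps) {
  -rowSums(y * log(pmax(y_hat, eps)))
}

#' Main supervised loss (cross-entropy, optional mask term)
#'
#' Mean over the batch of the per-sample cross-entropy, plus `beta` times
#' the pixel-averaged binary cross-entropy (or Dice loss) between predicted
#' and reference lesion maps when both are supplied.
#'
#' @param y_hat n x C matrix of predicted stage probabilities (rows sum
#'   to 1).
#' @param y n x C one-hot matrix (or a character vector of stage labels).
#' @param p_hat,p optional predicted and reference spatial maps (equal
#'   shape, values in [0, 1]).
#' @param beta spatial-term weight.
#' @param spatial_loss `"bce"` or `"dice"`.
#' @param eps log clamp.
#' @return scalar loss.
#' @export
supervised_loss <- function(y_hat, y, p_hat = NULL, p = NULL, beta = 0.5,
                            spatial_loss = "bce", eps = 1e-8) {
  y_hat <- as_prob_matrix(y_hat)
  if (is.character(y)) y <- one_hot(y)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  if (!all(dim(y_hat) == dim(y))) stop("y_hat / y shape mismatch")
  loss <- mean(ce_rows(y_hat, y, eps))
  if (!is.null(p_hat) && !is.null(p)) {
    if (!all(dim(p_hat) == dim(p))) stop("p_hat / p shape mismatch")
    sp <- if (spatial_loss == "dice") {
      1 - (2 * sum(p_hat * p) + eps) / (sum(p_hat) + sum(p) + eps)
    } else {
      -mean(p * log(pmax(p_hat, eps)) + (1 - p) * log(pmax(1 - p_hat, eps)))
    }
    loss <- loss + beta * sp
  }
  loss
}

#' Early-stage weighted cross-entropy
#'
#' Per-sample weights `w_j = 1 + gamma * 1(g_j = "early")` upweight the
#' early stage, countering the optimisation bias toward visually strong
#' symptomatic samples.
#'
#' @inheritParams supervised_loss
#' @param stages character vector of per-sample stage labels g_j.
#' @param gamma early upweight increment (>= 0).
#' @return scalar loss.
#' @export
early_weighted_loss <- function(y_hat, y, stages, gamma = 1.0, eps = 1e-8) {
  y_hat <- as_prob_matrix(y_hat)
  if (is.character(y)) y <- one_hot(y)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  if (!all(stages %in% STAGE_LEVELS)) {
    stop("unknown stage label: ",
         paste(setdiff(unique(stages), STAGE_LEVELS), collapse = ", "))
  }
  w <- 1 + gamma * (stages == "early")
  mean(w * ce_rows(y_hat, y, eps))
}

#' Cross-modal cosine alignment loss
#'
#' Mean over the batch of `1 - <z_env, z_vis> / (|z_env| |z_vis| + eps)`;
#' bounded in [0, 2] (up to the epsilon guard).
#'
#' @param z_env,z_vis n x D matrices (or single D-vectors) of environmental
#'   and visual embeddings.
#' @param eps denominator guard.
#' @return scalar loss.
#' @export
alignment_loss <- function(z_env, z_vis, eps = 1e-8) {
  if (!is.matrix(z_env)) z_env <- matrix(z_env, nrow = 1L)
  if (!is.matrix(z_vis)) z_vis <- matrix(z_vis, nrow = 1L)
  if (!all(dim(z_env) == dim(z_vis))) stop("z_env / z_vis shape mismatch")
  dots <- rowSums(z_env * z_vis)
  nrm <- sqrt(rowSums(z_env^2)) * sqrt(rowSums(z_vis^2))
  mean(1 - dots / (nrm + eps))
}

#' Deep-supervision loss over auxiliary scales
#'
#' `sum_l alpha_l * supervised_loss(aux_l, y)`; an empty scale set gives 0.
#'
#' @param aux named list of auxiliary probability matrices, one per scale.
#' @param y one-hot matrix or stage labels.
#' @param alpha_per_scale named weights; NULL = uniform `1/|Omega|`.
#' @param eps log clamp.
#' @return scalar loss.
#' @export
deep_supervision_loss <- function(aux, y, alpha_per_scale = NULL, eps = 1e-8) {
  if (length(aux) == 0L) return(0)
  if (is.null(alpha_per_scale)) {
    alpha_per_scale <- stats::setNames(rep(1 / length(aux), length(aux)),
                                       names(aux))
  }
  missing <- setdiff(names(aux), names(alpha_per_scale))
  if (length(missing)) {
    stop("missing alpha for supervised scale(s): ",
         paste(missing, collapse = ", "))
  }
  tot <- 0
  for (nm in names(aux)) {
    tot <- tot + alpha_per_scale[[nm]] * supervised_loss(aux[[nm]], y, eps = eps)
  }
  tot
}

#' Compose the joint loss and return its breakdown
#'
#' @param outputs list with `probs` (n x C), optionally `aux` (list),
#'   `z_env`, `z_vis` (n x D), `p_hat`; a batch assembled from
#'   [model_forward()] outputs.
#' @param targets list with `y` (one-hot or labels), `stages`, optionally
#'   `p` (reference masks).
#' @param config a [loss_config()].
#' @return a `loss_breakdown` list: `total`, `sup`, `early`, `align`, `ds`,
#'   satisfying `total = sup + le*early + la*align + ld*ds`.
#' @export
joint_loss <- function(outputs, targets, config = loss_config()) {
  y <- targets$y
  if (is.character(y)) y <- one_hot(y)
  sup <- supervised_loss(outputs$probs, y, outputs$p_hat, targets$p,
                         beta = config$beta,
                         spatial_loss = config$spatial_loss,
                         eps = config$epsilon)
  early <- early_weighted_loss(outputs$probs, y, targets$stages,
                               gamma = config$gamma, eps = config$epsilon)
  align <- if (!is.null(outputs$z_env) && !is.null(outputs$z_vis)) {
    alignment_loss(outputs$z_env, outputs$z_vis, eps = config$epsilon)
  } else 0
  ds <- deep_supervision_loss(outputs$aux %||% list(), y,
                              config$alpha_per_scale, eps = config$epsilon)
  total <- sup + config$lambda_early * early + config$lambda_align * align +
    config$lambda_ds * ds
  structure(list(total = total, sup = sup, early = early, align = align,
                 ds = ds),
            class = "loss_breakdown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- graph twins (used by the trainer; numerically equal to the above) ---

ce_graph <- function(ctx, probs, y_onehot, eps) {
  ag_scale(ctx, ag_sum(ctx, ag_mul(ctx, ag_logclamp(ctx, probs, eps),
                                   ag_const(ctx, matrix(y_onehot, 1L)))), -1)
}

# Joint loss graph for a single sequence's forward nodes.
joint_loss_graph <- function(ctx, fg, target, lcfg) {
  eps <- lcfg$epsilon
  y <- as.numeric(one_hot(target$stage))
  sup <- ce_graph(ctx, fg$probs, y, eps)
  if (!is.null(fg$pmap) && !is.null(target$p)) {
    pm <- fg$pmap
    pc <- ag_const(ctx, matrix(as.numeric(target$p), ncol = 1L))
    pos <- ag_mul(ctx, pc, ag_logclamp(ctx, pm, eps))
    neg <- ag_mul(ctx, ag_cadd(ctx, ag_scale(ctx, pc, -1), 1),
                  ag_logclamp(ctx, ag_cadd(ctx, ag_scale(ctx, pm, -1), 1), eps))
    bce <- ag_scale(ctx, ag_mean_all(ctx, ag_add(ctx, pos, neg)), -1)
    sup <- ag_add(ctx, sup, ag_scale(ctx, bce, lcfg$beta))
  }
  w <- 1 + lcfg$gamma * (target$stage == "early")
  early <- ag_scale(ctx, ce_graph(ctx, fg$probs, y, eps), w)
  dot <- ag_sum(ctx, ag_mul(ctx, fg$zenv, fg$zvis))
  na <- ag_sqrt(ctx, ag_sum(ctx, ag_mul(ctx, fg$zenv, fg$zenv)))
  nb <- ag_sqrt(ctx, ag_sum(ctx, ag_mul(ctx, fg$zvis, fg$zvis)))
  denom <- ag_cadd(ctx, ag_mul(ctx, na, nb), eps)
  align <- ag_cadd(ctx, ag_scale(ctx, ag_div(ctx, dot, denom), -1), 1)
  ds <- NULL
  if (length(fg$aux)) {
    alpha <- lcfg$alpha_per_scale
    if (is.null(alpha)) {
      alpha <- stats::setNames(rep(1 / length(fg$aux), length(fg$aux)),
                               names(fg$aux))
    }
    for (nm in names(fg$aux)) {
      term <- ag_scale(ctx, ce_graph(ctx, fg$aux[[nm]], y, eps), alpha[[nm]])
      ds <- if (is.null(ds)) term else ag_add(ctx, ds, term)
    }
  } else {
    ds <- ag_const(ctx, 0)
  }
  total <- ag_add(ctx, sup, ag_scale(ctx, early, lcfg$lambda_early))
  total <- ag_add(ctx, total, ag_scale(ctx, align, lcfg$lambda_align))
  total <- ag_add(ctx, total, ag_scale(ctx, ds, lcfg$lambda_ds))
  list(total = total,
       breakdown = structure(list(total = total$value[1L],
                                  sup = sup$value[1L],
                                  early = early$value[1L],
                                  align = align$value[1L],
                                  ds = ds$value[1L]),
                             class = "loss_breakdown"))
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss total=%.5f sup=%.5f early=%.5f align=%.5f ds=%.5f\n",
              x$total, x$sup, x$early, x$align, x$ds))
  invisible(x)
}
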