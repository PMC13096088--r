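# End-to-end training: AdamW with cosine-annealed learning rate, gradient
# accumulation over mini-batches of sequence samples, per-epoch loss
# breakdown logging, and event-level cross-validation orchestration.

#' Training configuration
#'
#' The `"paper"` profile carries the reference hyperparameters (AdamW,
#' weight decay 1e-4, initial learning rate 1e-4, cosine annealing, batch
#' 16). The `"desk"` profile uses a larger learning rate and smaller batch
#' suited to the reduced-width CPU model.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param lr initial learning rate.
#' @param weight_decay decoupled weight decay.
#' @param batch_size sequences per optimisation step.
#' @param epochs training epochs.
#' @param lr_min floor of the cosine schedule.
#' @param shuffle reshuffle training sequences every epoch.
#' @param seed seed controlling shuffling (model init has its own seed).
#' @return a `train_config` list.
#' @export
train_config <- function(profile = c("desk", "paper"), lr = NULL,
                         weight_decay = 1e-4, batch_size = NULL,
                         epochs = NULL, lr_min = NULL, shuffle = TRUE,
                         seed = 1L) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") {
    list(lr = 1e-4, batch_size = 16L, epochs = 30L, lr_min = 1e-6)
  } else {
    list(lr = 2e-3, batch_size = 8L, epochs = 4L, lr_min = 1e-4)
  }
  pick <- function(x, d) if (is.null(x)) d else x
  cfg <- list(profile = profile, lr = pick(lr, def$lr),
              weight_decay = weight_decay,
              batch_size = as.integer(pick(batch_size, def$batch_size)),
              epochs = as.integer(pick(epochs, def$epochs)),
              lr_min = pick(lr_min, def$lr_min), shuffle = isTRUE(shuffle),
              seed = as.integer(seed))
  if (cfg$lr <= 0) stop("lr must be > 0")
  if (cfg$batch_size < 1L) stop("batch_size must be >= 1")
  class(cfg) <- "train_config"
  cfg
}

#' Cosine-annealed learning rate
#' @param epoch 1-based epoch index.
#' @param total total epochs.
#' @param lr0 initial rate.
#' @param lr_min floor.
#' @return learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, total, lr0, lr_min = 1e-6) {
  if (total <= 1L) return(lr0)
  frac <- (epoch - 1) / (total - 1)
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * frac))
}

adamw_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

# Forward + backward for one sequence; returns grads, loss breakdown.
# `patches` allows callers to reuse precomputed patch matrices.
sequence_grads <- function(model, s, lcfg, patches = NULL) {
  if (is.null(patches)) patches <- seq_to_patches(model, s)
  ctx <- ag_ctx()
  fg <- forward_graph(ctx, model, s$env, patches, length(s$images))
  jl <- joint_loss_graph(ctx, fg, list(stage = s$stage, p = s$mask), lcfg)
  ag_backward(ctx, jl$total)
  list(grads = ag_grads(ctx), breakdown = jl$breakdown)
}

#' Train a model on sequence samples
#'
#' Accumulates joint-loss gradients over mini-batches and applies AdamW
#' updates under a cosine-annealed learning rate. Deterministic for a fixed
#' (model seed, train seed, data) triple.
#'
#' @param model a `gw_model` (freshly built or a checkpoint).
#' @param sequences training `sequence_sample`s.
#' @param tcfg a [train_config()].
#' @param lcfg a [loss_config()].
#' @param val_sequences optional validation sequences; per-epoch mean
#'   validation total loss is logged.
#' @param verbose print one line per epoch.
#' @return list with `model` (trained), `log` (data.table: epoch, lr,
#'   total, sup, early, align, ds, val_total).
#' @export
train_model <- function(model, sequences, tcfg = train_config(),
                        lcfg = loss_config(), val_sequences = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "gw_model"), length(sequences) >= 1L)
  set.seed(tcfg$seed)
  patch_cache <- lapply(sequences, seq_to_patches, model = model)
  state <- adamw_state(model$params)
  log_rows <- list()
  for (epoch in seq_len(tcfg$epochs)) {
    lr <- cosine_lr(epoch, tcfg$epochs, tcfg$lr, tcfg$lr_min)
    ord <- if (tcfg$shuffle) sample.int(length(sequences)) else seq_along(sequences)
    sums <- c(total = 0, sup = 0, early = 0, align = 0, ds = 0)
    nb <- 0L
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + tcfg$batch_size - 1L, length(ord))]
      acc <- NULL
      for (bi in batch) {
        sg <- sequence_grads(model, sequences[[bi]], lcfg, patch_cache[[bi]])
        acc <- if (is.null(acc)) sg$grads else {
          Map(`+`, acc, sg$grads[names(acc)])
        }
        for (nm in names(sums)) sums[nm] <- sums[nm] + sg$breakdown[[nm]]
        nb <- nb + 1L
      }
      acc <- lapply(acc, `/`, length(batch))
      st <- adamw_step(model$params, acc, state, lr, tcfg$weight_decay)
      model$params <- st$params
      state <- st$state
      i <- i + tcfg$batch_size
    }
    row <- as.list(sums / nb)
    row$epoch <- epoch
    row$lr <- lr
    row$val_total <- NA_real_
    if (!is.null(val_sequences)) {
      vt <- vapply(val_sequences, function(s) {
        ctx <- ag_ctx()
        fg <- forward_graph(ctx, model, s$env, seq_to_patches(model, s),
                            length(s$images))
        joint_loss_graph(ctx, fg, list(stage = s$stage, p = s$mask),
                         lcfg)$breakdown$total
      }, numeric(1L))
      row$val_total <- mean(vt)
    }
    log_rows[[epoch]] <- data.table::as.data.table(
      row[c("epoch", "lr", "total", "sup", "early", "align", "ds", "val_total")])
    if (verbose) {
      message(sprintf("epoch %d lr=%.2e total=%.4f val=%.4f",
                      epoch, lr, row$total, row$val_total))
    }
  }
  list(model = model, log = data.table::rbindlist(log_rows))
}

#' Event-level K-fold cross-validation
#'
#' For each fold: normalisation statistics and the model are fitted on the
#' training events only, then the held-out fold is evaluated — the split
#' plan guarantees no event's frames cross the boundary.
#'
#' @param dataset a `synthetic_dataset`.
#' @param K folds.
#' @param acfg an [alignment_config()] (its `norm_stats` are refitted per
#'   fold on training events).
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param lcfg a [loss_config()].
#' @param T sequence length.
#' @param seed split/seed base.
#' @param verbose print per-fold progress.
#' @return list with `per_fold` (list of `eval_report`s), `summary`
#'   (data.table of per-fold metrics plus mean and sd rows), `plan`.
#' @export
crossval <- function(dataset, K = 5L, acfg = alignment_config(),
                     mcfg = model_config("desk"), tcfg = train_config(),
                     lcfg = loss_config(), T = 6L, seed = 1L,
                     verbose = FALSE) {
  plan <- event_based_split(dataset, K, seed)
  reports <- vector("list", K)
  metric_rows <- list()
  for (fold in seq_len(K)) {
    train_ids <- names(plan)[plan != fold]
    test_ids <- names(plan)[plan == fold]
    acfg_fold <- alignment_config(acfg$half_window, acfg$smoothing_alpha)
    aligned <- align_dataset(dataset, acfg_fold, fit_events = train_ids)
    seqs <- build_sequences(aligned, T)
    seq_ids <- vapply(seqs, `[[`, character(1L), "event_id")
    mcfg_fold <- mcfg
    mcfg_fold$seed <- mcfg$seed + fold
    tcfg_fold <- tcfg
    tcfg_fold$seed <- tcfg$seed + fold
    model <- build_model(mcfg_fold)
    fit <- train_model(model, seqs[seq_ids %in% train_ids], tcfg_fold, lcfg)
    ev_ids <- vapply(dataset$events, `[[`, character(1L), "event_id")
    rep <- evaluate_run(fit$model, seqs[seq_ids %in% test_ids],
                        dataset$events[ev_ids %in% test_ids])
    reports[[fold]] <- rep
    metric_rows[[fold]] <- data.table::data.table(
      fold = fold, seed = tcfg_fold$seed,
      accuracy = rep$accuracy, recall = rep$recall, f1 = rep$f1,
      early_recall = rep$early_recall, early_f1 = rep$early_f1,
      lead_time_days = rep$lead_time_days)
    if (verbose) message("fold ", fold, " accuracy=", round(rep$accuracy, 3))
  }
  per_fold <- data.table::rbindlist(metric_rows)
  num <- setdiff(names(per_fold), c("fold", "seed"))
  summ <- data.table::rbindlist(list(
    per_fold,
    data.table::data.table(fold = NA_integer_, seed = NA_integer_,
                           t(colMeans(per_fold[, num, with = FALSE], na.rm = TRUE))),
    data.table::data.table(fold = NA_integer_, seed = NA_integer_,
                           t(apply(per_fold[, num, with = FALSE], 2L,
                                   stats::sd, na.rm = TRUE)))),
    use.names = TRUE)
  summ$row <- c(paste0("fold", seq_len(K)), "mean", "sd")
  list(per_fold = reports, summary = summ, plan = plan)
}
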