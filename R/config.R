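# Single-YAML configuration with sim/align/model/loss/train/eval sections.

#' Default configuration tree
#'
#' @param profile `"desk"` (CPU-scale defaults, used by the tests) or
#'   `"paper"` (reference hyperparameters).
#' @return nested list with sections `sim`, `align`, `model`, `loss`,
#'   `train`, `eval`.
#' @export
default_config <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  list(
    profile = profile,
    sim = unclass(sim_config()),
    align = list(half_window = 30, smoothing_alpha = 0.2),
    model = unclass(model_config(profile)),
    loss = unclass(loss_config()),
    train = unclass(train_config(profile)),
    eval = list(threshold = 0.5, k = 3L, sequence_length = 6L, folds = 5L)
  )
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      merge_lists(base[[nm]], override[[nm]])
    } else override[[nm]]
  }
  base
}

#' Read a YAML configuration, merged over the profile defaults
#'
#' @param path YAML file path (NULL = pure defaults).
#' @param profile default profile used for unset fields.
#' @return nested configuration list.
#' @export
read_config <- function(path = NULL, profile = "desk") {
  user <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else list()
  if (!is.null(user$profile)) profile <- user$profile
  merge_lists(default_config(profile), user)
}

config_sim <- function(cfg) {
  do.call(sim_config, cfg$sim[setdiff(names(cfg$sim), character(0))])
}

config_model <- function(cfg, env_guidance = NULL, seed = NULL) {
  m <- cfg$model
  if (!is.null(env_guidance)) m$env_guidance <- env_guidance
  if (!is.null(seed)) m$seed <- seed
  keep <- setdiff(names(m), "stage_downsamples")
  do.call(model_config, c(list(profile = m$profile),
                          m[setdiff(keep, "profile")]))
}
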