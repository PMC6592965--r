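# Run configuration: structured text (YAML) with strict key validation and
# materialised defaults, so every run is reconstructible from its saved
# resolved config plus seed.

config_defaults <- function() {
  list(
    model = list(type = "mass"),
    inversion = list(max_iter = 64, tol_nats = 0.01, lm_init = 0.125,
                     fd_step = 1e-4),
    simulate = list(kind = "subject", n_subjects = 16, noise_sd = NULL,
                    freq_min = 4, freq_max = 100, freq_step = 1,
                    re_sd = 0.1),
    peb = list(design = NULL, params = NULL),
    seed = 1,
    output_dir = "."
  )
}

config_allowed_keys <- function() {
  list(top = c("model", "inversion", "simulate", "peb", "seed", "output_dir"),
       model = c("type", "kappa1", "kappa2", "kappa3", "kappa4",
                 MASS_GAIN_NAMES, FIELD_KERNEL_NAMES,
                 "alpha_u", "beta_u", "alpha_n", "beta_n"),
       inversion = c("max_iter", "tol_nats", "lm_init", "fd_step"),
       simulate = c("kind", "n_subjects", "noise_sd", "freq_min", "freq_max",
                    "freq_step", "re_sd"),
       peb = c("design", "params"))
}

#' Read and resolve a run configuration
#'
#' Parses a YAML run configuration, rejects unknown keys, and materialises
#' all defaults so the resolved configuration fully determines the run.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A list of class `run_config` with every setting filled in.
#' @export
read_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_dcm("config file not found: %s", path)
    yaml::read_yaml(path) %||% list()
  }
  allowed <- config_allowed_keys()
  unknown <- setdiff(names(cfg), allowed$top)
  if (length(unknown)) stop_dcm("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (section in intersect(names(cfg), c("model", "inversion", "simulate", "peb"))) {
    bad <- setdiff(names(cfg[[section]]), allowed[[section]])
    if (length(bad)) stop_dcm("unknown key(s) in [%s]: %s", section, paste(bad, collapse = ", "))
  }
  resolved <- modifyList(config_defaults(), cfg)
  if (!resolved$model$type %in% c("mass", "field")) {
    stop_dcm("model type must be 'mass' or 'field'")
  }
  structure(resolved, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Save a resolved configuration
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(yaml::as.yaml(unclass(cfg)), path)
  invisible(path)
}

## build the forward model a config describes
config_model <- function(cfg) {
  mv <- cfg$model
  theta_keys <- setdiff(names(mv), "type")
  base <- if (mv$type == "mass") mass_model() else field_model()
  if (!length(theta_keys)) return(base)
  ok <- intersect(theta_keys, free_param_names(base))
  bad <- setdiff(theta_keys, free_param_names(base))
  if (length(bad)) stop_dcm("config parameters not in the %s model: %s",
                            mv$type, paste(bad, collapse = ", "))
  apply_theta(base, setNames(as.numeric(mv[ok]), ok))
}

config_settings <- function(cfg) {
  dcm_settings(max_iter = cfg$inversion$max_iter,
               tol_nats = cfg$inversion$tol_nats,
               lm_init = cfg$inversion$lm_init,
               fd_step = cfg$inversion$fd_step,
               seed = cfg$seed)
}

config_freqs <- function(cfg) {
  seq(cfg$simulate$freq_min, cfg$simulate$freq_max, by = cfg$simulate$freq_step)
}
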