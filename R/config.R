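# Flat key-value configuration (Debian-control / DCF text format: one
# "key: value" per line). Unknown keys are rejected fail-fast.

.config_defaults <- function() {
  p <- model_parameters()
  c(unclass(p)[.param_names()],
    list(dialect = p$dialect,
         genotype = "wild_type",
         seed = 1L,
         # steady / fig4
         salt_min = 0, salt_max = 10, n_points = 101L,
         # simulate
         salt_before = 0, salt_after = 0.5, t_step = 0,
         t_end = 50, n_samples = 501L,
         # synth
         mode = "timecourse",
         s_ref = 0.5, time_scale = 2,
         noise_sd_log2 = 0.15, n_reps = 3L,
         # fit
         free_params = "s_ref", n_starts = 8L))
}

.config_numeric_keys <- function() {
  c(.param_names(), "seed", "salt_min", "salt_max", "n_points",
    "salt_before", "salt_after", "t_step", "t_end", "n_samples",
    "s_ref", "time_scale", "noise_sd_log2", "n_reps", "n_starts")
}

#' Load a run configuration
#'
#' Reads a flat `key: value` text file (DCF format) and merges it over the
#' built-in defaults. Keys are the model parameter symbols (`alphaCK` ...
#' `n`), `dialect`, `genotype`, `seed`, protocol and sweep settings
#' (`salt_min`, `salt_max`, `n_points`, `salt_before`, `salt_after`,
#' `t_step`, `t_end`, `n_samples`), synthetic-data settings (`mode`,
#' `s_ref`, `time_scale`, `noise_sd_log2`, `n_reps`) and fit settings
#' (`free_params`, comma-separated, and `n_starts`). Unknown keys raise an
#' error.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file (highest
#'   precedence; used for command-line flags).
#' @return Named list of resolved settings.
#' @examples
#' cfg <- load_config(NULL, overrides = list(genotype = "phb_1d"))
#' cfg$genotype
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- .config_defaults()
  file_vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config file not found: ", path, call. = FALSE)
    dcf <- read.dcf(path)
    if (nrow(dcf) != 1L)
      stop("config file must contain a single record", call. = FALSE)
    file_vals <- as.list(dcf[1, ])
  }
  for (vals in list(file_vals, overrides)) {
    if (!length(vals)) next
    bad <- setdiff(names(vals), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg[names(vals)] <- vals
  }
  for (k in .config_numeric_keys()) {
    v <- suppressWarnings(as.numeric(cfg[[k]]))
    if (is.na(v)) stop("config key '", k, "' must be numeric", call. = FALSE)
    cfg[[k]] <- v
  }
  for (k in c("seed", "n_points", "n_samples", "n_reps", "n_starts"))
    cfg[[k]] <- as.integer(cfg[[k]])
  if (!cfg$mode %in% c("timecourse", "dose_response"))
    stop("mode must be 'timecourse' or 'dose_response'", call. = FALSE)
  if (is.character(cfg$free_params) && length(cfg$free_params) == 1L)
    cfg$free_params <- trimws(strsplit(cfg$free_params, ",")[[1]])
  cfg
}

.config_params <- function(cfg) {
  do.call(model_parameters, c(cfg[.param_names()],
                              list(dialect = cfg$dialect)))
}
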