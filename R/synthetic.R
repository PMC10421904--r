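#' Map NaCl dose to model salt level
#'
#' The model's dimensionless salt variable is anchored to the experimental
#' treatment by a single point: 150 mM NaCl corresponds to salt = `s_ref`
#' (default 0.5, the published perturbation level). The map is linear
#' through the origin: `salt = s_ref * dose_mM / 150`.
#'
#' @param dose_mM nonnegative NaCl dose(s) in mM; vectorised.
#' @param s_ref model salt level equivalent to 150 mM (default 0.5).
#' @return Nonnegative salt level(s).
#' @examples
#' dose_to_salt(c(0, 100, 150, 200))
#' @export
dose_to_salt <- function(dose_mM, s_ref = 0.5) {
  if (any(!is.finite(dose_mM)) || any(dose_mM < 0))
    stop("dose_mM must be finite and nonnegative", call. = FALSE)
  if (!is.finite(s_ref) || s_ref < 0)
    stop("s_ref must be finite and nonnegative", call. = FALSE)
  s_ref * dose_mM / 150
}

#' Noise-free fold changes under salt treatment
#'
#' The model analogue of a 2^-ddCt measurement: the treated level of each
#' readout divided by its untreated (salt = 0 steady state) control level.
#' The treated trajectory starts at the control steady state with salt
#' stepped to `dose_to_salt(dose_mM, s_ref)` at time 0, and is read out at
#' `time_h * time_scale` model time units.
#'
#' @param params a `mirsalt_params` object.
#' @param genotype a `mirsalt_genotype` or genotype name.
#' @param dose_mM a single NaCl dose (mM).
#' @param time_h exposure time(s) in hours; vectorised.
#' @param s_ref dose-map anchor (see [dose_to_salt()]).
#' @param time_scale model time units per hour (> 0, default 2).
#' @return A data frame with columns `time_h`, `FC_miR166`, `FC_PHB`.
#' @examples
#' true_fold_change(model_parameters(), "wild_type", dose_mM = 150,
#'                  time_h = c(0.5, 4))
#' @export
true_fold_change <- function(params, genotype = "wild_type", dose_mM,
                             time_h, s_ref = 0.5, time_scale = 2) {
  stopifnot(inherits(params, "mirsalt_params"))
  g <- .as_genotype(genotype)
  if (!is.finite(time_scale) || time_scale <= 0)
    stop("time_scale must be positive", call. = FALSE)
  if (length(dose_mM) != 1L)
    stop("dose_mM must be a single dose", call. = FALSE)
  if (any(!is.finite(time_h)) || any(time_h < 0))
    stop("time_h must be finite and nonnegative", call. = FALSE)
  control <- find_steady_state(params, salt = 0, genotype = g)$state
  fc <- .fold_change_at(params, g, control, dose_mM, time_h, s_ref,
                        time_scale)
  data.frame(time_h = time_h, FC_miR166 = fc[, 1], FC_PHB = fc[, 2])
}

# Shared kernel: fold changes at several times for one dose, given the
# precomputed control steady state. Returns a matrix (miR166, PHB).
.fold_change_at <- function(params, g, control, dose_mM, time_h, s_ref,
                            time_scale) {
  salt <- dose_to_salt(dose_mM, s_ref)
  if (salt == 0 || all(time_h == 0)) {
    fc <- matrix(1, length(time_h), 2L)
    if (salt == 0) return(fc)
  }
  ord <- order(time_h)
  tt <- time_h[ord] * time_scale
  fc <- matrix(1, length(time_h), 2L)
  pos <- tt > 0
  if (any(pos)) {
    states <- .integrate_protocol(params, g, constant_salt(salt),
                                  times = c(0, tt[pos]),
                                  init = control)[-1, , drop = FALSE]
    fc[ord[pos], 1] <- states[, 3] / control[["miR166"]]
    fc[ord[pos], 2] <- states[, 2] / control[["PHB"]]
  }
  fc
}

# Run a body with a locally seeded RNG, restoring any pre-existing global
# RNG state afterwards (no hidden global side effects).
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite numeric seed is required", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.make_dataset <- function(records, params, g, s_ref, time_scale,
                          noise_sd_log2, n_reps, seed) {
  rownames(records) <- NULL
  structure(records,
            metadata = list(genotype = g$name,
                            dialect = params$dialect,
                            s_ref = s_ref, time_scale = time_scale,
                            noise_sd_log2 = noise_sd_log2,
                            n_reps = n_reps, seed = seed,
                            params = unclass(params)),
            class = c("mirsalt_dataset", "data.frame"))
}

.measure <- function(params, g, doses, times, s_ref, time_scale,
                     noise_sd_log2, n_reps, seed) {
  if (!is.finite(noise_sd_log2) || noise_sd_log2 < 0)
    stop("noise_sd_log2 must be nonnegative", call. = FALSE)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  control <- find_steady_state(params, salt = 0, genotype = g)$state
  grids <- lapply(doses, function(d)
    .fold_change_at(params, g, control, d, times, s_ref, time_scale))
  .with_seed(seed, {
    rec <- do.call(rbind, lapply(seq_along(doses), function(i) {
      do.call(rbind, lapply(seq_along(times), function(j) {
        true_fc <- grids[[i]][j, ]
        do.call(rbind, lapply(seq_len(n_reps), function(r) {
          eps <- stats::rnorm(2L, mean = 0, sd = noise_sd_log2)
          data.frame(gene = c("miR166", "PHB"),
                     dose_mM = doses[i], time_h = times[j],
                     replicate = r,
                     fold_change = true_fc * 2^eps)
        }))
      }))
    }))
    rec
  })
}

#' Generate a synthetic qRT-PCR time-course dataset
#'
#' Emulates the design of the salt time-course experiment: fold changes
#' (2^-ddCt relative to untreated control) of the pooled pre-miR165/166
#' readout and PHB, at one NaCl dose across several exposure times, with
#' multiplicative lognormal replicate noise: measured FC = true FC x
#' 2^eps, eps ~ Normal(0, `noise_sd_log2`), i.i.d. per replicate and gene.
#' Housekeeping-gene normalisation is assumed perfect.
#'
#' @inheritParams true_fold_change
#' @param timepoints_h exposure times in hours (default the published
#'   design: 0.5, 1, 1.5, 2, 3, 4).
#' @param dose_mM single NaCl dose (default 150).
#' @param n_reps biological replicates per condition (default 3).
#' @param noise_sd_log2 SD of the Gaussian noise on log2 fold change
#'   (default 0.15); 0 gives noiseless data.
#' @param seed required integer seed; identical seeds give bit-identical
#'   datasets and the caller's RNG state is left untouched.
#' @return A data frame of class `mirsalt_dataset` with columns `gene`,
#'   `dose_mM`, `time_h`, `replicate`, `fold_change`, and generation
#'   settings in `attr(, "metadata")`.
#' @examples
#' d <- generate_timecourse(model_parameters(), seed = 1)
#' head(d)
#' @export
generate_timecourse <- function(params = model_parameters(),
                                genotype = "wild_type",
                                timepoints_h = c(0.5, 1, 1.5, 2, 3, 4),
                                dose_mM = 150, n_reps = 3L,
                                noise_sd_log2 = 0.15,
                                s_ref = 0.5, time_scale = 2, seed) {
  stopifnot(inherits(params, "mirsalt_params"))
  g <- .as_genotype(genotype)
  rec <- .measure(params, g, doses = dose_mM, times = timepoints_h,
                  s_ref, time_scale, noise_sd_log2, n_reps, seed)
  .make_dataset(rec, params, g, s_ref, time_scale, noise_sd_log2, n_reps,
                seed)
}

#' Generate a synthetic qRT-PCR dose-response dataset
#'
#' Emulates the dose-response design: fold changes at a single exposure
#' time across several NaCl doses (default 0, 100, 150, 200 mM at 5 h).
#' Noise model and return value as in [generate_timecourse()].
#'
#' @inheritParams generate_timecourse
#' @param doses_mM NaCl doses in mM (default 0, 100, 150, 200).
#' @param time_h single exposure time in hours (default 5).
#' @return A `mirsalt_dataset` data frame.
#' @examples
#' d <- generate_dose_response(model_parameters(), seed = 2)
#' aggregate(fold_change ~ gene + dose_mM, d, mean)
#' @export
generate_dose_response <- function(params = model_parameters(),
                                   genotype = "wild_type",
                                   doses_mM = c(0, 100, 150, 200),
                                   time_h = 5, n_reps = 3L,
                                   noise_sd_log2 = 0.15,
                                   s_ref = 0.5, time_scale = 2, seed) {
  stopifnot(inherits(params, "mirsalt_params"))
  g <- .as_genotype(genotype)
  rec <- .measure(params, g, doses = doses_mM, times = time_h,
                  s_ref, time_scale, noise_sd_log2, n_reps, seed)
  .make_dataset(rec, params, g, s_ref, time_scale, noise_sd_log2, n_reps,
                seed)
}

#' Read and write synthetic datasets as TSV
#'
#' `write_dataset()` writes the records as a tab-separated table (full
#' `%.17g` precision, so the round trip is lossless) and the generation
#' metadata as a JSON sidecar (`<path>.meta.json`). `read_dataset()`
#' reverses it.
#'
#' @param dataset a `mirsalt_dataset`.
#' @param path TSV file path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `mirsalt_dataset`.
#' @examples
#' d <- generate_timecourse(seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' write_dataset(d, f)
#' identical(read_dataset(f)$fold_change, d$fold_change)
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "mirsalt_dataset"))
  out <- as.data.frame(dataset)
  out$fold_change <- sprintf("%.17g", out$fold_change)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- attr(dataset, "metadata")
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(gene = "character",
                                          dose_mM = "numeric",
                                          time_h = "numeric",
                                          replicate = "integer",
                                          fold_change = "character"))
  rec$fold_change <- as.numeric(rec$fold_change)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  structure(rec, metadata = meta,
            class = c("mirsalt_dataset", "data.frame"))
}
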