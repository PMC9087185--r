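#' Read and write observed series CSV files
#'
#' The on-disk schema is exactly the four columns `year`, `month`, `tier`
#' (`FLH`/`SLH`/`TLH`) and `visits_10k`, with `.` as decimal separator and
#' no thousands separators. Values are written at full double precision so
#' a write/read round trip is exact.
#'
#' @param path CSV file path.
#' @return `read_series_csv()` returns a validated series data frame;
#'   `write_series_csv()` returns `path` invisibly.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c("year", "month", "tier", "visits_10k"))
  if (length(extra))
    stop("unknown series column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  validate_series(df)
  df
}

#' @rdname read_series_csv
#' @param series A series data frame (see [validate_series()]).
#' @export
write_series_csv <- function(series, path) {
  validate_series(series)
  out <- series[c("year", "month", "tier", "visits_10k")]
  out$visits_10k <- format(out$visits_10k, digits = 17, trim = TRUE,
                           scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

pipeline_sections <- function() c("seed", "synth", "fit", "sweep")

read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  extra <- setdiff(names(cfg), pipeline_sections())
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (sec in c("synth", "fit"))
    if (is.null(cfg[[sec]]))
      stop("config is missing required section '", sec, "'", call. = FALSE)
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates, from a single JSON configuration, the stages: generate a
#' synthetic observed series, fit the twelve parameters to it, compute the
#' equilibria and their stability at the fitted values, and (optionally)
#' run a sensitivity sweep from the fitted values. Each stage validates its
#' inputs before any computation; a failure aborts the run with a
#' diagnostic. All artifacts are written under `out_dir` together with a
#' manifest (config snapshot, seed, package version, file list, timestamp)
#' sufficient to re-run the pipeline reproducibly.
#'
#' The config document has sections:
#' \describe{
#'   \item{`seed`}{integer; overrides the generator/fit seeds.}
#'   \item{`synth`}{fields of [generator_config()], with `params` as a
#'     twelve-field object and `initial` as a length-3 array.}
#'   \item{`fit`}{`init_guess` (twelve-field object) and optionally
#'     `n_starts`, `maxiter`.}
#'   \item{`sweep`}{optional: `parameter`, `values`, `t_end`.}
#' }
#' Unknown sections or parameter fields are errors, not warnings.
#'
#' @param config_path Path to the JSON configuration.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config_path, out_dir) {
  cfg <- read_pipeline_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 20220426L

  # -- synth ----------------------------------------------------------------
  syn <- cfg$synth
  known <- c("params", "initial", "years", "noise_sd", "seasonal_amp", "seed")
  extra <- setdiff(names(syn), known)
  if (length(extra))
    stop("unknown synth field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  gp <- as_visit_params(as.list(syn$params))
  gc <- generator_config(
    params = gp,
    initial = as.numeric(syn$initial),
    years = if (is.null(syn$years)) 8 else syn$years,
    noise_sd = if (is.null(syn$noise_sd)) 0.02 else syn$noise_sd,
    seasonal_amp = if (is.null(syn$seasonal_amp)) 0 else syn$seasonal_amp,
    seed = if (is.null(syn$seed)) seed else syn$seed)
  obs <- generate_series(gc)
  f_obs <- file.path(out_dir, "observed.csv")
  write_series_csv(obs, f_obs)
  outputs <- c(outputs, f_obs)

  # -- fit ------------------------------------------------------------------
  fcfg <- cfg$fit
  extra <- setdiff(names(fcfg), c("init_guess", "n_starts", "maxiter"))
  if (length(extra))
    stop("unknown fit field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  guess <- as_visit_params(as.list(fcfg$init_guess))
  fit <- fit_visits(obs, guess,
                    n_starts = if (is.null(fcfg$n_starts)) 8 else fcfg$n_starts,
                    seed = seed,
                    control = minpack.lm::nls.lm.control(
                      maxiter = if (is.null(fcfg$maxiter)) 200 else fcfg$maxiter))
  f_fit <- file.path(out_dir, "fit.json")
  jsonlite::write_json(
    list(params = fit$params[param_names()], sse = fit$sse,
         r_squared = fit$r_squared,
         per_tier_r2 = as.list(fit$per_tier_r2), n_obs = fit$n_obs,
         converged = fit$converged, initial_state = fit$initial_state,
         combos = as.list(fit$combos)),
    f_fit, auto_unbox = TRUE, digits = I(17))
  outputs <- c(outputs, f_fit)

  # -- equilibria & stability at the fitted parameters ----------------------
  eq <- all_equilibria(fit$params)
  f_eq <- file.path(out_dir, "equilibria.json")
  jsonlite::write_json(
    lapply(eq, function(e) list(label = e$label, exists = e$exists,
                                marginal = e$marginal,
                                point = if (e$exists) as.list(e$point) else NULL,
                                conditions = e$conditions)),
    f_eq, auto_unbox = TRUE, digits = I(17))
  outputs <- c(outputs, f_eq)

  st <- stability_summary(fit$params)
  message("Stability at fitted parameters: ",
          paste(vapply(st$reports, function(r)
            paste0(r$label, "=", r$classification), ""), collapse = ", "))
  f_st <- file.path(out_dir, "stability.json")
  jsonlite::write_json(
    list(stable = st$stable,
         reports = lapply(st$reports, function(r)
           list(label = r$label, eigenvalues = r$eigenvalues,
                classification = r$classification,
                conditions = r$conditions))),
    f_st, auto_unbox = TRUE, digits = I(17))
  outputs <- c(outputs, f_st)

  # -- sweep (optional) ------------------------------------------------------
  if (!is.null(cfg$sweep)) {
    scfg <- cfg$sweep
    extra <- setdiff(names(scfg), c("parameter", "values", "t_end"))
    if (length(extra))
      stop("unknown sweep field(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    t_end <- if (is.null(scfg$t_end)) 600 else scfg$t_end
    sw <- sweep_parameter(fit$params, scfg$parameter,
                          as.numeric(scfg$values), fit$initial_state,
                          times = seq(0, t_end, by = 1))
    for (i in seq_along(sw$values)) {
      f <- file.path(out_dir, sprintf("sweep_%s_%g.csv", sw$parameter,
                                      sw$values[i]))
      utils::write.csv(format(sw$trajectories[[i]], digits = 17, trim = TRUE),
                       f, row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, f)
    }
  }

  manifest <- list(command = "run_pipeline",
                   config = cfg,
                   seed = seed,
                   package_version = as.character(utils::packageVersion("tierdyn")),
                   outputs = c(basename(outputs), "manifest.json"),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  f_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = I(17))
  invisible(manifest)
}
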