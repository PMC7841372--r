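#' Write a trajectory to CSV
#'
#' One row per agent per snapshot with columns `step`, `agent_id`, `x`, `y`,
#' `theta`. Numbers are written in shortest round-trip form, so
#' [read_trajectory()] reconstructs every value exactly.
#'
#' @param traj A `pk_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- tibble::as_tibble(traj)[c("step", "agent_id", "x", "y", "theta")]
  readr::write_csv(fmt17(out), path, progress = FALSE)
  invisible(path)
}

# Serialize doubles with 17 significant digits so CSV round-trips are exact.
fmt17 <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                  ~ sprintf("%.17g", .x)))
}

#' Read a trajectory CSV
#'
#' @param path Path written by [write_trajectory()].
#' @param cfg Optional [pk_config()] to re-attach (enables [first_arrival()]
#'   and friends on the result).
#' @return A tibble (a `pk_trajectory` when `cfg` is given).
#' @export
read_trajectory <- function(path, cfg = NULL) {
  # base R parsing (strtod) reconstructs 17-digit decimals exactly
  out <- tibble::as_tibble(utils::read.csv(path, colClasses = c(
    step = "integer", agent_id = "integer",
    x = "numeric", y = "numeric", theta = "numeric"
  )))
  if (!is.null(cfg)) {
    out <- structure(out, config = validate_config(cfg),
                     class = c("pk_trajectory", class(out)))
  }
  out
}

#' Write sweep results to CSV
#'
#' One row per grid cell, sorted by grid coordinates
#' (`alpha`, `xi`, `p1`, `p2`), with the observable columns
#' `n_experiments`, `s`, `mean_tau`, `tau_norm`, `mean_va`, `coordinated`.
#' Re-running the same sweep with the same master seed produces a
#' byte-identical file.
#'
#' @param result A `pk_sweep` (or any data frame with those columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  out <- dplyr::arrange(tibble::as_tibble(result),
                        dplyr::across(dplyr::any_of(c("alpha", "xi", "p1", "p2"))))
  readr::write_csv(fmt17(out), path, progress = FALSE)
  invisible(path)
}

#' Read sweep results written by [write_results()]
#'
#' @param path CSV path.
#' @return A tibble with all numeric fields reconstructed exactly.
#' @export
read_results <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  dplyr::mutate(out, dplyr::across(
    dplyr::any_of(c("p1", "p2", "xi", "alpha", "beta", "s",
                    "mean_tau", "tau_norm", "mean_va")),
    as.numeric
  ))
}

#' Write a run manifest
#'
#' Records, before any results are written, everything needed to re-run an
#' experiment exactly: the fully resolved configuration, the master seed, the
#' package version, the planned output paths, and a timestamp.
#'
#' @param cfg A [pk_config()].
#' @param seed Master seed.
#' @param outputs Character vector of planned output paths.
#' @param path Manifest path (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, seed, outputs, path) {
  cfg <- validate_config(cfg)
  manifest <- list(
    config = Filter(Negate(is.null), unclass(cfg)),
    master_seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("skillflock")),
    outputs = as.list(outputs),
    written_at = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
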