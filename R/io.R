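## Configuration and result serialization. Config format is YAML with three
## top-level sections: `params` (whole-body model), `gsh_params` (glutathione
## surrogate) and `protocol` (dose events + horizon). All concentrations uM,
## times hr, volumes L, APAP amounts mg, NAC amounts mmol.

#' Save a model configuration to a YAML file
#'
#' Writes the full parameter sets and (optionally) a dosing protocol to a
#' human-readable YAML file that [load_config()] restores bit-identically.
#'
#' @param path output file path.
#' @param params an [apap_parameters()] object.
#' @param gsh_params a [gsh_parameters()] object.
#' @param protocol optional [dosing_protocol()].
#' @return `path`, invisibly.
#' @export
save_config <- function(path, params = apap_parameters(),
                        gsh_params = gsh_parameters(), protocol = NULL) {
  cfg <- list(params = unclass(params), gsh_params = unclass(gsh_params))
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "dosing_protocol"))
    cfg$protocol <- list(horizon = protocol$horizon,
                         events = protocol$events)
  }
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' Load a model configuration from a YAML file
#'
#' Reads a configuration written by [save_config()], or a partial file whose
#' `params` / `gsh_params` entries override the defaults. Unknown keys are
#' rejected with an error naming the key (via the parameter constructors).
#'
#' @param path YAML file path.
#' @return list with elements `params`, `gsh_params` and `protocol` (NULL if
#'   the file has no protocol section).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("params", "gsh_params", "protocol"))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  pp <- cfg$params
  if (!is.null(pp) && !is.null(pp$Vmax_ugt_liver))
    pp$Vmax_ugt_liver <- as.numeric(pp$Vmax_ugt_liver)
  if (!is.null(pp) && !is.null(pp$Vmax_ugt_tissue))
    pp$Vmax_ugt_tissue <- as.numeric(pp$Vmax_ugt_tissue)
  params <- do.call(apap_parameters, pp %||% list())
  gsh <- do.call(gsh_parameters, cfg$gsh_params %||% list())
  protocol <- NULL
  if (!is.null(cfg$protocol)) {
    ev <- cfg$protocol$events
    if (is.list(ev) && !is.data.frame(ev)) {
      # YAML represents a data.frame either as a named list of columns or
      # as a list of row records
      ev <- if (!is.null(names(ev)) && all(nzchar(names(ev))))
        as.data.frame(ev, stringsAsFactors = FALSE)
      else do.call(rbind, lapply(ev, as.data.frame))
    }
    protocol <- dosing_protocol(ev, horizon = cfg$protocol$horizon)
  }
  list(params = params, gsh_params = gsh, protocol = protocol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Reproducibility header written at the top of every CSV output.
output_header <- function(traj) {
  solver <- attr(traj, "solver")
  ver <- tryCatch(as.character(utils::packageVersion("apapsim")),
                  error = function(e) "dev")
  c(sprintf("# apapsim %s", ver),
    sprintf("# parameter_hash: %s", params_hash(attr(traj, "params"),
                                                attr(traj, "gsh_params"))),
    sprintf("# solver: %s rtol=%g atol=%g dt_out=%g hr", solver$method,
            solver$rtol, solver$atol, solver$dt_out))
}

## Stable short hash of the parameter sets (md5 of their serialized values).
params_hash <- function(params, gsh_params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(c(unclass(params), unclass(gsh_params))), tmp)
  unname(tools::md5sum(tmp))
}

#' Export a trajectory as CSV
#'
#' Writes a simulated trajectory with a reproducibility header (package
#' version, parameter hash, solver settings) in wide layout (one column per
#' variable) or tidy layout (`time`, `variable`, `value`).
#'
#' @param traj an `apap_trajectory` from [simulate_protocol()].
#' @param path output file path.
#' @param layout `"wide"` or `"tidy"`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, layout = c("wide", "tidy")) {
  layout <- match.arg(layout)
  stopifnot(inherits(traj, "apap_trajectory"))
  df <- as.data.frame(traj)
  if (layout == "tidy") {
    vars <- setdiff(names(df), "time")
    df <- data.frame(
      time = rep(df$time, times = length(vars)),
      variable = rep(vars, each = nrow(df)),
      value = unlist(df[vars], use.names = FALSE))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(traj), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Export an outcome summary as JSON
#'
#' @param summary an `outcome_summary` from [summarize_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "outcome_summary"))
  x <- unclass(summary)
  x$urinary_24h_mmol <- as.list(x$urinary_24h_mmol)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
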