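#' Assemble a run configuration
#'
#' A \code{run_config} bundles everything one simulation needs: growth
#' parameters, optional circuit parameters, initial conditions, solver
#' settings, the marker [spawn_policy()] and output resolution. Either build
#' it from parts or load a packaged regime preset by name (see
#' [list_presets()]).
#'
#' @param preset optional preset name; when given, all other arguments are
#'   ignored and the packaged configuration is loaded via [load_config()].
#' @param growth a [growth_params()] object.
#' @param circuit a [circuit_params()] object, or \code{NULL} for a
#'   growth-only configuration.
#' @param init list with \code{R0} (initial colony radius), \code{n0}
#'   (initial nutrient), \code{T0} (initial per-marker T7 RNAP),
#'   \code{n_markers} (initial marker count; markers start evenly spaced on
#'   [0, R0]) and optionally \code{marker_radii} (explicit initial radii,
#'   overriding \code{n_markers}).
#' @param solver list with \code{rtol}, \code{atol}, \code{t_end},
#'   \code{n_floor_frac} (nutrient-exhaustion floor as a fraction of
#'   \code{n0}), \code{n_quad} (quadrature nodes in the coupled right-hand
#'   side).
#' @param spawn a [spawn_policy()].
#' @param output list with \code{n_times} (output samples) and \code{n_dgrid}
#'   (kymograph distance-grid resolution).
#' @return An object of class \code{"run_config"}.
#' @examples
#' cfg <- run_config(growth = growth_params(), circuit = NULL)
#' cfg$init$R0
#' @export
run_config <- function(preset = NULL,
                       growth = growth_params(),
                       circuit = NULL,
                       init = list(),
                       solver = list(),
                       spawn = spawn_policy(),
                       output = list()) {
  if (!is.null(preset)) return(load_config(preset_path(preset)))
  stopifnot(inherits(growth, "growth_params"))
  if (!is.null(circuit)) stopifnot(inherits(circuit, "circuit_params"))
  stopifnot(inherits(spawn, "spawn_policy"))
  init <- fill_defaults(init, list(R0 = 0.05, n0 = 1, T0 = 0.1,
                                   n_markers = 15L, marker_radii = NULL),
                        "init")
  solver <- fill_defaults(solver, list(rtol = 1e-8, atol = 1e-8, t_end = 80,
                                       n_floor_frac = 1e-4, n_quad = 201L),
                          "solver")
  output <- fill_defaults(output, list(n_times = 201L, n_dgrid = 161L),
                          "output")
  if (init$R0 <= 0) stop("init$R0 must be positive", call. = FALSE)
  if (init$n0 < 0) stop("init$n0 must be non-negative", call. = FALSE)
  if (solver$t_end <= 0) stop("solver$t_end must be positive", call. = FALSE)
  structure(list(growth = growth, circuit = circuit, init = init,
                 solver = solver, spawn = spawn, output = output),
            class = "run_config")
}

fill_defaults <- function(given, defaults, what) {
  extra <- setdiff(names(given), names(defaults))
  if (length(extra))
    stop("unknown ", what, " field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (nm in names(given)) defaults[[nm]] <- given[[nm]]
  defaults
}

#' Modify parts of a run configuration
#'
#' Returns a copy of \code{config} with the named fields replaced, e.g.
#' \code{modify_config(cfg, circuit = list(A0 = 0.8))}. Unknown field names
#' are rejected.
#'
#' @param config a [run_config()].
#' @param growth,circuit,init,solver,spawn,output named lists of overrides.
#' @return The modified \code{"run_config"}.
#' @export
modify_config <- function(config, growth = list(), circuit = list(),
                          init = list(), solver = list(), spawn = list(),
                          output = list()) {
  stopifnot(inherits(config, "run_config"))
  patch_params <- function(obj, patch, ctor, what) {
    if (!length(patch)) return(obj)
    if (is.null(obj)) stop("config has no ", what, " section", call. = FALSE)
    args <- unclass(obj)
    extra <- setdiff(names(patch), names(args))
    if (length(extra))
      stop("unknown ", what, " field(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    args[names(patch)] <- patch
    do.call(ctor, args)
  }
  config$growth <- patch_params(config$growth, growth, growth_params,
                                "growth")
  config$circuit <- patch_params(config$circuit, circuit, circuit_params,
                                 "circuit")
  config$spawn <- patch_params(config$spawn, spawn, spawn_policy, "spawn")
  config$init <- fill_defaults(init, config$init, "init")
  config$solver <- fill_defaults(solver, config$solver, "solver")
  config$output <- fill_defaults(output, config$output, "output")
  run_config(growth = config$growth, circuit = config$circuit,
             init = config$init, solver = config$solver,
             spawn = config$spawn, output = config$output)
}

#' @export
print.run_config <- function(x, ...) {
  cat("colonyflow run configuration\n")
  cat(sprintf("  init: R0 = %g, n0 = %g, T0 = %g, %s markers\n",
              x$init$R0, x$init$n0, x$init$T0,
              if (is.null(x$init$marker_radii)) x$init$n_markers
              else length(x$init$marker_radii)))
  cat(sprintf("  solver: t_end = %g, rtol = %g, n_floor_frac = %g\n",
              x$solver$t_end, x$solver$rtol, x$solver$n_floor_frac))
  cat(if (is.null(x$circuit)) "  growth-only (no circuit)\n"
      else sprintf("  circuit: b = %g, R_domain = %g, A0 = %g\n",
                   x$circuit$b, x$circuit$R_domain, x$circuit$A0))
  invisible(x)
}

config_sections <- c("schema", "growth", "circuit", "init", "solver",
                     "spawn", "output")
CONFIG_SCHEMA <- "colonyflow-run/1"

#' Load a run configuration from YAML
#'
#' Parses and validates a YAML run configuration. Preset names (see
#' [list_presets()]) resolve to files shipped with the package. Unknown
#' sections or fields are rejected with an error naming the offender;
#' load/save round-trips are lossless.
#'
#' @param path path to a YAML file, or a packaged preset name.
#' @return A validated [run_config()].
#' @examples
#' cfg <- load_config("fig4_low_burden")
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    pp <- preset_path(path, must_exist = FALSE)
    if (!is.null(pp) && file.exists(pp)) path <- pp
    else stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw), config_sections)
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (!identical(raw$schema, CONFIG_SCHEMA))
    stop("config field 'schema' must be \"", CONFIG_SCHEMA, "\"",
         call. = FALSE)
  if (is.null(raw$growth)) stop("config section 'growth' is required",
                                call. = FALSE)
  gp <- do.call(growth_params, lapply(raw$growth, yaml_num))
  cpar <- if (!is.null(raw$circuit))
    do.call(circuit_params, lapply(raw$circuit, yaml_num)) else NULL
  sp <- if (!is.null(raw$spawn)) do.call(spawn_policy, raw$spawn)
        else spawn_policy()
  run_config(growth = gp, circuit = cpar,
             init = raw$init %||% list(),
             solver = raw$solver %||% list(),
             spawn = sp,
             output = raw$output %||% list())
}

yaml_num <- function(x) if (identical(x, ".inf") || identical(x, "Inf"))
  Inf else x

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration to YAML
#'
#' @param config a [run_config()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  init <- config$init
  init$n_markers <- as.integer(init$n_markers)
  if (is.null(init$marker_radii)) init$marker_radii <- NULL
  out <- list(schema = CONFIG_SCHEMA,
              growth = unclass(config$growth),
              circuit = if (!is.null(config$circuit))
                unclass(config$circuit),
              init = init,
              solver = config$solver,
              spawn = unclass(config$spawn),
              output = config$output)
  out <- Filter(Negate(is.null), out)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' List packaged regime presets
#'
#' Packaged configurations encode the named simulation regimes: the
#' growth-only default, the high-burden / sharp-capacity patterning regime
#' (base case plus the initial-AHL 0.3, initial-AHL 0.8 and doubled-domain
#' variants), the low-burden / gradual-capacity core-ring regime used for the
#' scale-invariance analysis, and the low-division-rate regime in which the
#' outer ring forms before the inner core.
#'
#' @return Character vector of preset names usable with [load_config()] and
#'   [run_config()].
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "colonyflow")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

preset_path <- function(name, must_exist = TRUE) {
  fn <- system.file("extdata", "presets", paste0(name, ".yaml"),
                    package = "colonyflow")
  if (fn == "") {
    if (must_exist)
      stop("unknown preset '", name, "'; available: ",
           paste(list_presets(), collapse = ", "), call. = FALSE)
    return(NULL)
  }
  fn
}
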