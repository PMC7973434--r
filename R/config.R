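# Run configuration: a YAML key-value file with strict key checking.
# Analysis constants default to the screen's standard choices: calling
# threshold alpha = 0.05, linkage window = 500 kb, enrichment FDR = 0.1,
# failed-control fraction = 0.1.

config_defaults <- function() {
  list(
    seed = 1,
    alpha = 0.05,
    linkage_window = 500000,
    enrichment_fdr = 0.1,
    min_fraction = 0.1,
    control = "ctrl",
    reference = "del",
    simulate = TRUE,
    sim = list(),
    inputs = list(plates = NULL, genome = NULL, layout = NULL,
                  gmt = NULL, slim = NULL)
  )
}

config_numeric_keys <- c("seed", "alpha", "linkage_window", "enrichment_fdr",
                         "min_fraction")

#' Resolve and validate a run configuration
#'
#' Unknown keys are rejected; all problems are reported at once. Missing
#' keys are filled with defaults. `sim` entries are forwarded to
#' [sim_config()] (and validated there at simulation time).
#'
#' @param x a named list (e.g. parsed YAML), possibly partial.
#' @return the fully resolved configuration list, class `sga_config`.
#' @export
resolve_config <- function(x = list()) {
  if (is.null(x)) x <- list()
  if (!is.list(x)) stopf("sga_config_error", "configuration must be a mapping")
  defs <- config_defaults()
  problems <- character()
  unknown <- setdiff(names(x), names(defs))
  if (length(unknown)) {
    problems <- c(problems, sprintf("unknown key '%s'", unknown))
  }
  if (!is.null(x$inputs)) {
    bad_in <- setdiff(names(x$inputs), names(defs$inputs))
    if (length(bad_in)) {
      problems <- c(problems, sprintf("unknown key 'inputs.%s'", bad_in))
    }
  }
  if (!is.null(x$sim)) {
    bad_sim <- setdiff(names(x$sim), names(formals(sim_config)))
    if (length(bad_sim)) {
      problems <- c(problems, sprintf("unknown key 'sim.%s'", bad_sim))
    }
  }
  cfg <- utils::modifyList(defs, x[setdiff(names(x), unknown)])
  for (k in config_numeric_keys) {
    if (!is_number(cfg[[k]])) {
      problems <- c(problems, sprintf("'%s' must be a single number", k))
    } else {
      cfg[[k]] <- as.numeric(cfg[[k]])
    }
  }
  if (is_number(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 1)) {
    problems <- c(problems, "'alpha' must be in (0, 1)")
  }
  if (!is.logical(cfg$simulate) || length(cfg$simulate) != 1L) {
    problems <- c(problems, "'simulate' must be TRUE or FALSE")
  }
  for (k in c("control", "reference")) {
    if (!is.character(cfg[[k]]) || length(cfg[[k]]) != 1L) {
      problems <- c(problems, sprintf("'%s' must be a single strain name", k))
    }
  }
  if (length(problems)) {
    stopf("sga_config_error", "invalid configuration:\n%s",
          paste0("  - ", problems, collapse = "\n"))
  }
  if (!length(cfg$sim)) cfg$sim <- list()  # canonical empty mapping
  # canonical inputs shape (YAML serializers drop NULL-valued keys)
  ins <- defs$inputs
  for (k in names(ins)) if (!is.null(x$inputs[[k]])) ins[[k]] <- x$inputs[[k]]
  cfg$inputs <- ins
  class(cfg) <- c("sga_config", "list")
  cfg
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file path.
#' @return resolved configuration list (see [resolve_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("sga_config_error", "no such file: %s", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stopf("sga_config_error",
                                            "cannot parse %s: %s", path,
                                            conditionMessage(e)))
  resolve_config(raw)
}

#' Write a resolved configuration back to YAML
#'
#' Round-trip safe: `load_config(write_config(cfg, f))` equals `cfg`.
#'
#' @param config resolved configuration.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
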