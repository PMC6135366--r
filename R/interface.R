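#' Load and validate a run configuration
#'
#' Reads a flat YAML run configuration, validates it field by field
#' against the published schema (`inst/schema/config-schema.json`
#' documents the same contract), fills documented defaults, and rejects
#' unknown keys. The normalized form round-trips through
#' [write_config()].
#'
#' @param path Path to a YAML configuration file.
#' @return An object of class `run_config`: the validated, normalized
#'   configuration.
#' @export
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c("n_women: 100", "age: {type: uniform, min: 25, max: 34}"),
#'            cfg_file)
#' load_config(cfg_file)
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config parse error in ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  normalize_config(raw, src = path)
}

config_defaults <- function() {
  list(duration_days = 365,
       scenario = "population_mix",
       schedule = list(type = "periodic", interval_days = 91),
       timing_policy = "random",
       assay = "serum_quantitative",
       mode = "mc",
       n_reps = 200,
       seed = 1,
       parameter_table = "bundled-default",
       out_dir = ".")
}

known_config_keys <- function() {
  c("n_women", "age", "duration_days", "scenario", "schedule",
    "timing_policy", "assay", "assays", "mode", "n_reps", "seed",
    "parameter_table", "out_dir")
}

# Validate a raw config list and fill defaults.
normalize_config <- function(raw, src = "config") {
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(raw), known_config_keys())
  if (length(unknown)) {
    stop("unknown config key(s) in ", src, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (req in c("n_women", "age")) {
    if (is.null(raw[[req]])) {
      stop("config field '", req, "' is required (", src, ")", call. = FALSE)
    }
  }
  cfg <- utils::modifyList(config_defaults(), raw)
  if (!is.numeric(cfg$n_women) || cfg$n_women < 0) {
    stop("config field 'n_women' must be a non-negative number", call. = FALSE)
  }
  if (!is.list(cfg$age) || is.null(cfg$age$type)) {
    stop("config field 'age' must be a mapping with a 'type'", call. = FALSE)
  }
  if (!cfg$scenario %in% c("none", "population_mix", "highly_effective_only")) {
    stop("config field 'scenario' must be one of none, population_mix, ",
         "highly_effective_only", call. = FALSE)
  }
  if (!cfg$mode %in% c("mc", "expected")) {
    stop("config field 'mode' must be 'mc' or 'expected'", call. = FALSE)
  }
  if (cfg$mode == "mc" && (is.null(cfg$seed) || !is.numeric(cfg$seed))) {
    stop("config field 'seed' is required for mc mode", call. = FALSE)
  }
  if (!is.null(cfg$assays)) {
    if (is.null(names(cfg$assays))) {
      stop("config field 'assays' must be a named mapping", call. = FALSE)
    }
    cfg$assays <- lapply(cfg$assays, function(a) {
      do.call(assay_spec, c(list(name = a$name %||% "custom"),
                            a[setdiff(names(a), "name")]))
    })
  }
  structure(cfg, class = "run_config")
}

#' Write a normalized run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$assays <- lapply(out$assays, function(a) unclass(a))
  yaml::write_yaml(out, path)
  invisible(path)
}

# Resolve the assay named in a config (custom block first, then bundled).
resolve_assay <- function(cfg) {
  if (inherits(cfg$assay, "assay_spec")) return(cfg$assay)
  if (!is.null(cfg$assays) && cfg$assay %in% names(cfg$assays)) {
    return(cfg$assays[[cfg$assay]])
  }
  defaults <- default_assays()
  if (cfg$assay %in% names(defaults)) return(defaults[[cfg$assay]])
  stop("config references undefined assay '", cfg$assay, "'", call. = FALSE)
}

config_to_design <- function(cfg, assay = NULL) {
  trial_design(n_women = cfg$n_women, age_spec = cfg$age,
               duration = cfg$duration_days, scenario = cfg$scenario,
               schedule = cfg$schedule, timing_policy = cfg$timing_policy,
               assay = assay %||% resolve_assay(cfg))
}

config_params <- function(cfg) {
  if (identical(cfg$parameter_table, "bundled-default")) {
    default_parameters()
  } else {
    load_parameters(cfg$parameter_table)
  }
}

#' Write an outcome tally to CSV and JSON
#'
#' Reports use per-10,000-women rates; each file embeds the seed, a hash
#' of the configuration, and the parameter-table version for audit
#' reproducibility.
#'
#' @param tally An `outcome_tally`.
#' @param out_dir Output directory (created if missing).
#' @param meta Named list of audit fields (seed, config hash, parameter
#'   table version).
#' @return Paths of the written files, invisibly.
#' @export
write_tally <- function(tally, out_dir, meta = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(category = names(tally$counts),
                   count = as.numeric(tally$counts),
                   per_10k_women = as.numeric(tally$rates))
  if (!is.null(tally$ci)) {
    df$lower <- tally$ci["lower", ]
    df$upper <- tally$ci["upper", ]
  }
  csv <- file.path(out_dir, "outcome_tally.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  js <- file.path(out_dir, "outcome_tally.json")
  payload <- c(list(categories = df, n_tests = tally$n_tests,
                    n_pregnancies = tally$n_pregnancies,
                    n_exposures = tally$n_exposures,
                    n_women = tally$n_women, mode = tally$mode,
                    n_reps = tally$n_reps), meta)
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(csv = csv, json = js))
}

run_meta <- function(cfg, params) {
  cfg_txt <- paste(utils::capture.output(utils::str(unclass(cfg))),
                   collapse = "\n")
  list(seed = cfg$seed,
       config_hash = sprintf("%08x", sum(utf8ToInt(cfg_txt) *
                                           (seq_along(utf8ToInt(cfg_txt)) %% 251 + 1)) %%
                               .Machine$integer.max),
       parameter_table_version = params$version)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (Monte Carlo run), `expect` (deterministic
#' expectation), `compare` (paired two-assay comparison; flags
#' `--assay-a`, `--assay-b`), `timing` (false-negative rates by timing
#' policy). Common flags: `--config <file>` (required), `--seed`,
#' `--reps`, `--out`. Writes `outcome_tally.csv` / `outcome_tally.json`
#' (or `comparison.csv` / `timing.csv`) and `run_log.txt` into the
#' output directory.
#'
#' @param argv Character vector of command-line arguments (defaults to
#'   the process arguments when run via `Rscript`).
#' @return Integer exit status, invisibly: 0 on success, 1 on usage or
#'   configuration errors.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pregsim <simulate|expect|compare|timing> --config FILE",
    "  [--seed N] [--reps N] [--out DIR] [--assay-a NAME --assay-b NAME]",
    sep = "\n")
  if (length(argv) < 1 ||
      !argv[1] %in% c("simulate", "expect", "compare", "timing")) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- argv[1]
  flags <- parse_flags(argv[-1])
  if (is.null(flags$config)) {
    message("--config is required\n", usage)
    return(invisible(1L))
  }
  status <- tryCatch({
    cfg <- load_config(flags$config)
    if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
    if (!is.null(flags$reps)) cfg$n_reps <- as.integer(flags$reps)
    if (!is.null(flags$out)) cfg$out_dir <- flags$out
    params <- config_params(cfg)
    meta <- run_meta(cfg, params)
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    log_lines <- c(paste("pregsim", cmd), paste("seed:", cfg$seed),
                   paste("config hash:", meta$config_hash),
                   paste("parameter table:", params$version))
    if (cmd == "simulate" || cmd == "expect") {
      design <- config_to_design(cfg)
      tally <- if (cmd == "simulate") {
        run_monte_carlo(design, params, n_reps = cfg$n_reps, seed = cfg$seed)
      } else {
        expected_outcomes(design, params)
      }
      write_tally(tally, cfg$out_dir, meta)
      summary_txt <- utils::capture.output(print(tally))
    } else if (cmd == "compare") {
      nameA <- flags[["assay-a"]] %||% cfg$assay
      nameB <- flags[["assay-b"]] %||% cfg$assay
      lookup <- function(nm) {
        c2 <- cfg; c2$assay <- nm; resolve_assay(c2)
      }
      design <- config_to_design(cfg, assay = lookup(nameA))
      cmpdf <- compare_specs(design, lookup(nameA), lookup(nameB), params,
                             mode = cfg$mode, n_reps = cfg$n_reps,
                             seed = cfg$seed)
      utils::write.csv(cmpdf, file.path(cfg$out_dir, "comparison.csv"),
                       row.names = FALSE)
      summary_txt <- utils::capture.output(print(cmpdf))
    } else {
      design <- config_to_design(cfg)
      tdf <- timing_effect(design, params, n_reps = cfg$n_reps,
                           seed = cfg$seed)
      utils::write.csv(tdf, file.path(cfg$out_dir, "timing.csv"),
                       row.names = FALSE)
      summary_txt <- utils::capture.output(print(tdf))
    }
    writeLines(c(log_lines, "", summary_txt),
               file.path(cfg$out_dir, "run_log.txt"))
    message(paste(summary_txt, collapse = "\n"))
    0L
  }, error = function(e) {
    message("pregsim error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        flags[[key]] <- args[i + 1]
        i <- i + 2
      } else {
        flags[[key]] <- TRUE
        i <- i + 1
      }
    } else {
      i <- i + 1
    }
  }
  flags
}
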