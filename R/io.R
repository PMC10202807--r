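# Configuration, orchestration and on-disk artifacts. CSV is the only
# tabular interchange format; JSON for structured objects; everything is
# reproducible from the manifest (config + seeds).

.config_defaults <- function() {
  list(mode = "simulate", out_dir = "out",
       n_countries = 3L, n_agents = 500L, persons_per_agent = 1,
       years = list(start = 1985L, end = 2020L, report_from = 1990L,
                    project_to = NULL),
       seeds = list(world = 1L, anneal = 2L, first_order = 3L),
       iterations = 4L,
       targets = list(reps = 2L, noise_sd = 1, cut_year = NULL),
       calibrate = list(steps = 200L, k = 50L, ppc_iterations = 50L),
       trace = FALSE)
}

#' Load and validate a run configuration
#'
#' YAML configuration with the documented keys only; unknown keys are
#' rejected with a message, missing keys take documented defaults.
#'
#' @param path YAML file path.
#' @return Validated config list (class `run_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  def <- .config_defaults()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(def, raw)
  cfg$mode <- match.arg(cfg$mode,
                        c("synth", "simulate", "calibrate", "ppc", "project"))
  with(cfg$years, {
    if (!(start < report_from && report_from <= end)) {
      stop("years must satisfy start < report_from <= end", call. = FALSE)
    }
  })
  for (s in names(cfg$seeds)) {
    if (!.is_count(cfg$seeds[[s]])) stop("seeds must be integers",
                                         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Write / read the long-form indicator table
#'
#' Schema: scope, scope_id, year, indicator, mean, ui_lo, ui_hi. Reads are
#' validated against the schema so files round-trip.
#'
#' @param df indicator data.frame as from [indicator_table()].
#' @param path CSV path.
#' @return `read_indicators()` returns the validated data.frame.
#' @export
write_indicators <- function(df, path) {
  need <- c("scope", "scope_id", "year", "indicator", "mean", "ui_lo",
            "ui_hi")
  stopifnot(all(need %in% names(df)))
  utils::write.csv(df[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indicators
#' @export
read_indicators <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scope", "scope_id", "year", "indicator", "mean", "ui_lo",
            "ui_hi")
  if (!identical(names(df), need)) {
    stop("indicator file does not match schema", call. = FALSE)
  }
  if (any(df$ui_lo > df$mean + 1e-9) || any(df$ui_hi < df$mean - 1e-9)) {
    stop("indicator file violates ui_lo <= mean <= ui_hi", call. = FALSE)
  }
  df
}

#' Write / read a calibration target table
#' @param targets targets data.frame (see [generate_synthetic_targets()]).
#' @param path CSV path.
#' @return `read_targets()` returns the validated data.frame.
#' @export
write_targets <- function(targets, path) {
  need <- c("country", "year", "indicator", "cause", "value", "source",
            "weight", "split")
  stopifnot(all(need %in% names(targets)))
  utils::write.csv(targets[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "year", "indicator", "cause", "value", "source",
            "weight", "split")
  if (!identical(names(df), need)) {
    stop("target file does not match schema", call. = FALSE)
  }
  if (any(df$weight < 0) || any(df$value < 0)) {
    stop("target file has negative values or weights", call. = FALSE)
  }
  df
}

.write_archive <- function(archive, path, keep = 200L) {
  n <- min(keep, length(archive$scores))
  jsonlite::write_json(
    list(scores = archive$scores[seq_len(n)],
         params = as.data.frame(archive$params[seq_len(n), , drop = FALSE]),
         best_trace = archive$best_trace, t0 = archive$t0,
         n_failed = archive$n_failed),
    path, digits = NA)
  invisible(path)
}

.deaths_by_cause_df <- function(tallies) {
  t0 <- tallies[[1L]]
  rows <- list()
  for (ci in seq_along(t0$countries)) for (yi in seq_along(t0$years)) {
    for (k in seq_along(maternal_causes)) {
      v <- vapply(tallies, function(tl) tl$deaths_cause[ci, yi, k],
                  numeric(1))
      u <- uncertainty(v)
      rows[[length(rows) + 1L]] <- data.frame(
        country = t0$countries[ci], year = t0$years[yi],
        cause = maternal_causes[k], mean = u[["mean"]],
        ui_lo = u[["ui_lo"]], ui_hi = u[["ui_hi"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Execute a configured run
#'
#' Modes: `synth` writes the synthetic world (truth, lifetables, subgroup
#' shares, entry schedule) and its calibration targets; `simulate` runs the
#' engine for several iterations under the truth and writes indicator and
#' deaths-by-cause tables (reported years only -- the burn-in years before
#' `report_from` are simulated but never reported); `calibrate` runs the
#' annealer against generated targets and writes the archive; `ppc` adds a
#' posterior predictive check; `project` simulates through
#' `years$project_to` under the truth (trend damping carries parameters
#' forward). A manifest with the config, seeds and an md5 of the config
#' makes any run reproducible.
#'
#' @param config a `run_config` from [load_config()], or a path to one.
#' @return Invisible list of artifact paths.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  paths <- character(0)

  yrs <- config$years
  gen <- generate_synthetic_world(
    config$n_countries, seed = config$seeds$world,
    years = yrs$start:max(yrs$end, yrs$project_to %||% yrs$end),
    report_from = yrs$report_from, n_agents = config$n_agents,
    persons_per_agent = config$persons_per_agent)
  world <- gen$world; truth <- gen$truth
  report_years <- yrs$report_from:yrs$end

  if (config$mode == "synth") {
    jsonlite::write_json(jsonlite::serializeJSON(truth), outp("truth.json"))
    lt <- as.data.frame.table(world$lifetable, stringsAsFactors = FALSE)
    names(lt) <- c("country", "age", "year", "q_annual")
    utils::write.csv(lt, outp("lifetable.csv"), row.names = FALSE)
    sg <- as.data.frame.table(world$subgroup_shares,
                              stringsAsFactors = FALSE)
    names(sg) <- c("country", "subgroup", "share")
    utils::write.csv(sg, outp("subgroup_shares.csv"), row.names = FALSE)
    es <- as.data.frame.table(world$entry_schedule, stringsAsFactors = FALSE)
    names(es) <- c("country", "year", "new_entrants")
    utils::write.csv(es, outp("entry_schedule.csv"), row.names = FALSE)
    tg <- generate_synthetic_targets(
      world, truth, reps = config$targets$reps,
      noise_sd = config$targets$noise_sd, seed = config$seeds$first_order,
      cut_year = config$targets$cut_year %||%
        max(yrs$report_from, yrs$end - 5L))
    write_targets(tg, outp("targets.csv"))
    paths <- c(outp("truth.json"), outp("lifetable.csv"),
               outp("subgroup_shares.csv"), outp("entry_schedule.csv"),
               outp("targets.csv"))
  } else if (config$mode %in% c("simulate", "project")) {
    sim_years <- world$years
    keep_years <- if (config$mode == "project") {
      yrs$report_from:(yrs$project_to %||% yrs$end)
    } else report_years
    tallies <- lapply(seq_len(config$iterations), function(i) {
      restrict_tally(
        simulate_world(world, truth, seed = config$seeds$first_order + i,
                       years = sim_years),
        keep_years)
    })
    ind <- rbind(indicator_table(tallies, "country"),
                 indicator_table(tallies, "global"))
    write_indicators(ind, outp("indicators.csv"))
    utils::write.csv(.deaths_by_cause_df(tallies),
                     outp("deaths_by_cause.csv"), row.names = FALSE)
    paths <- c(outp("indicators.csv"), outp("deaths_by_cause.csv"))
  } else { # calibrate / ppc
    tg <- generate_synthetic_targets(
      world, truth, reps = config$targets$reps,
      noise_sd = config$targets$noise_sd, seed = config$seeds$first_order,
      cut_year = config$targets$cut_year %||%
        max(yrs$report_from, yrs$end - 5L))
    write_targets(tg, outp("targets.csv"))
    train <- tg[tg$split == "train", ]
    free <- free_parameters(world)
    arch <- anneal(
      make_prior_sampler(free), make_simulator(world, truth, train), train,
      anneal_config(steps = config$calibrate$steps,
                    proposal_scale = free$prior_sd * 0.25,
                    seed = config$seeds$anneal))
    .write_archive(arch, outp("archive.json"))
    paths <- c(outp("targets.csv"), outp("archive.json"))
    if (config$mode == "ppc") {
      pw <- ppc_world(world, truth, arch, tg,
                      k = min(config$calibrate$k, length(arch$scores)),
                      n = config$calibrate$ppc_iterations,
                      seed = config$seeds$first_order,
                      noise_sd = config$targets$noise_sd)
      jsonlite::write_json(pw$report, outp("ppc_report.json"), digits = NA)
      paths <- c(paths, outp("ppc_report.json"))
    }
  }

  manifest <- list(mode = config$mode, seeds = config$seeds,
                   n_countries = config$n_countries,
                   n_agents = config$n_agents, years = config$years,
                   config_md5 = .config_md5(config), artifacts = paths)
  jsonlite::write_json(manifest, outp("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, outp("run_manifest.json")))
}

.config_md5 <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
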