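#' Assemble and validate a pipeline configuration
#'
#' A configuration names the data source — exactly one of `simulation`
#' (arguments for [sim_config()]) or `input` (paths for [read_panel()]) —
#' the stages to run, and per-stage settings. Can be given as a list or as a
#' path to a YAML file with the same structure.
#'
#' @param config list or path to a YAML file.
#' @return validated config list of class `analysis_config`.
#' @export
analysis_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    stages = c("clean", "sc", "placebo", "did", "sensitivity"),
    seed = 1L,
    out_dir = ".",
    sc = list(),
    did = list(),
    clean = list()
  )
  for (nm in names(defaults)) {
    config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  }
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input) {
    abort("config must name exactly one of 'simulation' or 'input'",
          "vaxpolicy_config_error")
  }
  known <- c("clean", "sc", "placebo", "did", "sensitivity")
  bad <- setdiff(config$stages, known)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
          "vaxpolicy_config_error")
  }
  if ("placebo" %in% config$stages && !"sc" %in% config$stages) {
    abort("stage 'placebo' requires stage 'sc'", "vaxpolicy_config_error")
  }
  config$sc$outcomes <- config$sc$outcomes %||%
    c(coverage = "increase", nonmedical = "decrease", medical = "increase")
  config$sc$predictors <- config$sc$predictors %||% character(0)
  config$did$outcome <- config$did$outcome %||% "overall"
  config$did$covariates <- config$did$covariates %||% character(0)
  config$clean$min_population <- config$clean$min_population %||% 65000
  config$clean$max_missing_fraction <- config$clean$max_missing_fraction %||% 0.2
  structure(config, class = c("analysis_config", "list"))
}

load_pipeline_panels <- function(config) {
  if (!is.null(config$simulation)) {
    args <- config$simulation
    args$seed <- args$seed %||% config$seed
    cfg <- do.call(sim_config, args)
    list(state = simulate_state_panel(cfg), county = simulate_county_panel(cfg))
  } else {
    inp <- config$input
    out <- list()
    if (!is.null(inp$state)) {
      out$state <- do.call(read_panel, c(inp$state, list(level = "state")))
    }
    if (!is.null(inp$county)) {
      out$county <- do.call(read_panel, c(inp$county, list(level = "county")))
    }
    out
  }
}

#' Run the full evaluation pipeline
#'
#' Executes the requested stages in dependency order — load/simulate, clean,
#' synthetic control (+ placebo tests), county DiD, sensitivity — writing
#' every stage result as JSON, plot-ready CSV tables via [write_report()],
#' and a run manifest (seed, package version, per-stage status, file list).
#' Reruns with the same config and seed are byte-identical up to file
#' timestamps.
#'
#' @param config an [analysis_config()] (list or YAML path).
#' @return the run manifest, invisibly; results are attached as the
#'   `"results"` attribute.
#' @export
run_pipeline <- function(config) {
  config <- analysis_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  status <- list()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), vaxpolicy_error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- paste0("failed: ", conditionMessage(res))
      FALSE
    } else {
      results[[name]] <<- res
      status[[name]] <<- "ok"
      TRUE
    }
  }

  panels <- load_pipeline_panels(config)
  status[["load"]] <- "ok"

  if ("clean" %in% config$stages && !is.null(panels$county)) {
    ok <- run_stage("clean", function() {
      f <- apply_county_filters(panels$county,
                                min_population = config$clean$min_population)
      m <- handle_missing(f$panel, config$did$outcome,
                          config$clean$max_missing_fraction)
      list(panel = m$panel, report = merge_reports(f$report, m$report))
    })
    if (ok) panels$county <- results$clean$panel
  }

  if ("sc" %in% config$stages && !is.null(panels$state)) {
    run_stage("sc", function() {
      lapply(stats::setNames(nm = names(config$sc$outcomes)), function(oc) {
        preds <- config$sc$predictors
        if (isTRUE(config$sc$select_predictors)) {
          preds <- select_predictors_stepwise(
            panels$state, oc, candidates = config$sc$candidates,
            treated = panels$state$treated_units[1])
        }
        fit_synthetic_control(panels$state, oc, preds,
                              treated = panels$state$treated_units[1])
      })
    })
  }
  if ("placebo" %in% config$stages && !is.null(results$sc)) {
    run_stage("placebo", function() {
      lapply(stats::setNames(nm = names(results$sc)), function(oc) {
        fit <- results$sc[[oc]]
        run_placebo_tests(panels$state, oc, fit$predictors,
                          treated = fit$treated_id,
                          direction = config$sc$outcomes[[oc]],
                          sc_fit = fit)
      })
    })
  }
  if ("did" %in% config$stages && !is.null(panels$county)) {
    run_stage("did", function() {
      list(
        fit = fit_did(panels$county, config$did$outcome,
                      config$did$covariates),
        parallel_trends = parallel_trends_check(panels$county,
                                                config$did$outcome),
        county_changes = county_change_table(panels$county,
                                             config$did$outcome)
      )
    })
  }
  if ("sensitivity" %in% config$stages) {
    run_stage("sensitivity", function() {
      out <- list()
      if (!is.null(results$sc)) {
        oc <- names(config$sc$outcomes)[1]
        out$sc_loo <- leave_one_out(
          panels$state, "sc", oc,
          predictors = results$sc[[oc]]$predictors,
          treated = results$sc[[oc]]$treated_id)
      }
      if (!is.null(results$did)) {
        out$did_loo <- leave_one_out(panels$county, "did",
                                     config$did$outcome,
                                     covariates = config$did$covariates)
        if (!is.null(results$clean) &&
            nrow(results$clean$report$proxy_substitutions)) {
          out$overall_only <- overall_only_subanalysis(
            panels$county, results$clean$report,
            covariates = config$did$covariates,
            outcome = config$did$outcome)
        }
      }
      out
    })
  }

  files <- write_report(results, config$out_dir)
  manifest <- list(
    package = "vaxpolicy",
    version = as.character(utils::packageVersion("vaxpolicy")),
    seed = config$seed,
    stages = status,
    outputs = basename(files)
  )
  write_json_file(manifest, file.path(config$out_dir, "manifest.json"))
  failed <- any(vapply(status, function(s) startsWith(s, "failed"),
                       logical(1)))
  attr(manifest, "results") <- results
  attr(manifest, "failed") <- failed
  invisible(manifest)
}

# Per-county pre/post change table (choropleth-ready): outcome in the last
# prepolicy year vs the last observed year.
county_change_table <- function(panel, outcome) {
  d <- panel$data
  pre_year <- max(d$year[d$year < panel$policy_year])
  post_year <- max(d$year)
  pre <- d[d$year == pre_year, c("unit_id", "parent_state", outcome)]
  post <- d[d$year == post_year, c("unit_id", outcome)]
  names(pre)[3] <- "pre_value"
  names(post)[2] <- "post_value"
  out <- dplyr::inner_join(pre, post, by = "unit_id")
  out$change <- out$post_value - out$pre_value
  out$pre_year <- pre_year
  out$post_year <- post_year
  out$treated <- out$unit_id %in% panel$treated_units
  out
}

sensitivity_to_csv <- function(tab) {
  aux <- vapply(tab$rows$auxiliary, function(a)
    jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA), character(1))
  tibble::tibble(
    analysis = tab$analysis,
    label = tab$rows$label,
    effect_size = tab$rows$effect_size,
    failed = tab$rows$failed,
    auxiliary = aux
  )
}

#' Write plot-ready tables and stage JSONs from pipeline results
#'
#' A pure function of the stage results: emits trajectory, weight, placebo,
#' county-change, DiD and sensitivity tables as CSV, plus one JSON per stage,
#' into `out_dir`.
#'
#' @param results named list of stage results (as produced by
#'   [run_pipeline()]): any of `sc`, `placebo`, `did`, `clean`,
#'   `sensitivity`.
#' @param out_dir output directory (created if needed).
#' @return character vector of files written.
#' @export
write_report <- function(results, out_dir) {
  if (!length(results)) {
    abort("no stage results to report", "vaxpolicy_parameter_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    files <<- c(files, path)
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    write_json_file(x, path)
    files <<- c(files, path)
  }

  if (!is.null(results$sc)) {
    for (oc in names(results$sc)) {
      fit <- results$sc[[oc]]
      emit_csv(tibble::tibble(
        year = as.integer(names(fit$gaps)),
        treated = as.numeric(fit$treated_path),
        synthetic = as.numeric(fit$synthetic_path),
        gap = as.numeric(fit$gaps)
      ), sprintf("sc_trajectory_%s.csv", oc))
      emit_csv(tibble::tibble(
        donor = names(fit$donor_contributions),
        weight = as.numeric(fit$donor_contributions)
      ), sprintf("sc_weights_%s.csv", oc))
      emit_json(list(
        outcome = oc, treated = fit$treated_id,
        effect_size = fit$effect_size, pre_mspe = fit$pre_mspe,
        predictors = as.list(fit$predictors),
        V = as.list(fit$weights$V),
        weights = as.list(fit$donor_contributions),
        gaps = as.list(fit$gaps)
      ), sprintf("sc_result_%s.json", oc))
    }
  }
  if (!is.null(results$placebo)) {
    for (oc in names(results$placebo)) {
      pl <- results$placebo[[oc]]
      emit_csv(tibble::tibble(
        unit_id = c(pl$treated_id, names(pl$effects)),
        effect_size = c(pl$treated_effect, as.numeric(pl$effects)),
        is_treated = c(TRUE, rep(FALSE, length(pl$effects)))
      ), sprintf("placebo_effects_%s.csv", oc))
      traj <- dplyr::bind_rows(lapply(names(pl$gap_trajectories), function(u)
        tibble::tibble(unit_id = u,
                       year = as.integer(names(pl$gap_trajectories[[u]])),
                       gap = as.numeric(pl$gap_trajectories[[u]]))))
      emit_csv(traj, sprintf("placebo_gaps_%s.csv", oc))
      emit_json(list(
        outcome = oc, treated = pl$treated_id, direction = pl$direction,
        treated_effect = pl$treated_effect, rank = pl$rank,
        n_evaluated = pl$n_evaluated, percentile = pl$percentile,
        meaningful = pl$meaningful, effects = as.list(pl$effects)
      ), sprintf("placebo_result_%s.json", oc))
    }
  }
  if (!is.null(results$did)) {
    fit <- results$did$fit %||% results$did
    emit_csv(fit$table, "did_table.csv")
    emit_json(list(
      outcome = fit$outcome, effect_size = fit$effect_size,
      n_obs = fit$n_obs, n_clusters = fit$n_clusters,
      coefficients = as.list(fit$coefficients),
      table = fit$table
    ), "did_result.json")
    if (!is.null(results$did$parallel_trends)) {
      emit_csv(results$did$parallel_trends$table, "parallel_trends.csv")
    }
    if (!is.null(results$did$county_changes)) {
      emit_csv(results$did$county_changes, "county_changes.csv")
    }
  }
  if (!is.null(results$clean)) {
    rep <- results$clean$report
    emit_json(list(
      excluded_units = rep$excluded_units,
      imputed_cells = rep$imputed_cells,
      proxy_substitutions = rep$proxy_substitutions
    ), "cleaning_report.json")
  }
  if (!is.null(results$sensitivity)) {
    for (nm in names(results$sensitivity)) {
      obj <- results$sensitivity[[nm]]
      if (inherits(obj, "sensitivity_table")) {
        emit_csv(sensitivity_to_csv(obj), sprintf("sensitivity_%s.csv", nm))
      } else if (inherits(obj, "did_result")) {
        emit_csv(obj$table, sprintf("sensitivity_%s.csv", nm))
      }
    }
  }
  files
}
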