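## End-to-end pipeline: assign -> estimate -> equilibrium -> sensitivity
## (-> disparity when two groups are requested), with a machine-readable
## run manifest.

#' Run configuration
#'
#' @param panel path to a panel CSV (columns person_id, wave, age, sex,
#'   race, offended, arrested), or a data.frame.
#' @param out_dir output directory (created if missing).
#' @param subgroups character vector of subgroup labels to analyze, e.g.
#'   `c("Black men", "White men")`; `NULL` analyzes the pooled panel.
#'   When exactly two subgroups are given, a disparity report is added.
#' @param estimation `"empirical"` (cell counts) or `"random-intercept"`
#'   (regression-based subgroup predictions).
#' @param seed integer seed (all pipeline randomness flows from it).
#' @param max_steps,tol equilibrium iteration protocol.
#' @param force overwrite existing outputs?
#' @param verbose print progress?
#' @return A validated `run_config` list.
#' @export
run_config <- function(panel, out_dir, subgroups = NULL,
                       estimation = c("empirical", "random-intercept"),
                       seed = 1L, max_steps = 300L, tol = 1e-12,
                       force = FALSE, verbose = TRUE) {
  estimation <- match.arg(estimation)
  if (is.character(panel) && !file.exists(panel))
    stop("panel file does not exist: ", panel, call. = FALSE)
  structure(list(panel = panel, out_dir = out_dir, subgroups = subgroups,
                 estimation = estimation, seed = as.integer(seed),
                 max_steps = max_steps, tol = tol, force = force,
                 verbose = verbose),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Stages: (1) state assignment, (2) transition estimation per requested
#' subgroup, (3) equilibrium, (4) sensitivity report, (5) disparity report
#' when exactly two subgroups are given.  Each stage writes a CSV; a JSON
#' manifest records inputs, seed, package version, per-stage status and
#' all warnings.  Any stage failure aborts with the stage name and cause.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "crimedyn",
    version = as.character(packageVersion("crimedyn")),
    seed = config$seed,
    estimation = config$estimation,
    input = if (is.character(config$panel)) config$panel else "<data.frame>",
    stages = list(), warnings = character())
  say <- function(...) if (config$verbose) message(...)
  warnings_log <- character()
  run_stage <- function(name, expr) {
    say("stage: ", name)
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- "completed"
    res
  }

  panel <- if (is.character(config$panel))
    read.csv(config$panel, stringsAsFactors = FALSE) else config$panel

  states <- run_stage("assign", assign_states(panel))
  write_table_csv(states[c("person_id", "wave", "state", "ever_arrested",
                           "inactive_streak")],
                  file.path(config$out_dir, "states.csv"),
                  force = config$force)
  transitions <- run_stage("transitions", build_transitions(states))

  groups <- config$subgroups
  if (is.null(groups)) groups <- "pooled"
  param_sets <- run_stage("estimate", {
    if (config$estimation == "empirical") {
      lapply(setNames(groups, groups), function(g) {
        if (g == "pooled") em <- empirical_matrix(transitions)
        else {
          parts <- strsplit(g, " ")[[1]]
          em <- empirical_matrix(transitions, race = parts[1],
                                 sex = ifelse(parts[2] == "men", "man",
                                              "woman"))
        }
        if (is.null(em$params))
          stop("empirical matrix for '", g, "' has undefined row(s): ",
               paste(em$undefined_rows, collapse = ", "))
        attr(em$params, "label") <- g
        em$params
      })
    } else {
      fits <- lapply(setNames(ARROW_KEYS, ARROW_KEYS), function(a)
        fit_transition_logit(transitions, a))
      tab <- subgroup_table(fits, panel, seed = config$seed)
      write_table_csv(tab, file.path(config$out_dir,
                                     "subgroup_predictions.csv"),
                      force = config$force)
      lapply(setNames(groups, groups), function(g)
        params_from_subgroup_table(tab, g))
    }
  })
  for (g in names(param_sets))
    save_params(param_sets[[g]],
                file.path(config$out_dir,
                          paste0("params_", gsub(" ", "_", g), ".json")))

  eqs <- run_stage("equilibrium", lapply(param_sets, function(p)
    equilibrium_iterate(p, max_steps = config$max_steps, tol = config$tol)))
  eq_df <- do.call(rbind, lapply(names(eqs), function(g) {
    e <- eqs[[g]]
    data.frame(group = g, t(as.numeric(e$state_star)), x_star = e$x_star,
               crime_rate = e$crime_rate, n_steps = e$n_steps_to_converge)
  }))
  names(eq_df)[2:6] <- STATE_NAMES
  write_table_csv(eq_df, file.path(config$out_dir, "equilibrium.csv"),
                  force = config$force)

  sens <- run_stage("sensitivity", do.call(rbind, lapply(names(param_sets),
    function(g) cbind(group = g,
                      as.data.frame(sensitivity_report(param_sets[[g]]))))))
  write_table_csv(sens, file.path(config$out_dir, "sensitivity.csv"),
                  force = config$force)

  if (length(param_sets) == 2) {
    disp <- run_stage("disparity",
      disparity_report(param_sets[[1]], param_sets[[2]]))
    write_table_csv(as.data.frame(disp),
                    file.path(config$out_dir, "disparity.csv"),
                    force = config$force)
  }

  diag_assign <- attr(states, "diagnostics")
  diag_tr <- attr(transitions, "diagnostics")
  manifest$diagnostics <- c(diag_assign, diag_tr)
  manifest$warnings <- warnings_log
  manifest$groups <- names(param_sets)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
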