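## File formats: JSON for parameter sets and state distributions, CSV for
## panels, transition tables and full printed matrices.

ARROW_KEYS <- unname(PARAM_ARROWS)

#' Path to a packaged fixture
#'
#' Packaged parameter and state files under `inst/extdata`: the printed
#' per-group transition-rate tables (`table5_black_men.json`,
#' `table5_white_men.json`), the full-sample average transition rates
#' (`table2_full_sample.json`, with the printed full matrix in
#' `table2_full_sample_matrix.csv`), and the initial state distributions
#' (`table4_initial_black_men.json`, `table4_initial_white_men.json`,
#' `table1_round1_full_sample.json`).
#'
#' @param name file name; with no argument, lists available fixtures.
#' @return Full path to the file.
#' @export
crimedyn_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "crimedyn")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path))
    stop("no packaged fixture '", name, "'; available: ",
         paste(list.files(dir), collapse = ", "), call. = FALSE)
  path
}

#' Load transition parameters from JSON
#'
#' The file must contain the 11 arrow keys (`"X->C1"`, `"X->A"`, `"C1->X"`,
#' `"C1->A"`, `"A->C2"`, `"A->R"`, `"C2->A"`, `"C2->R"`, `"R->C2"`,
#' `"R->A"`, `"R->X"`) with values in `[0, 1]`; an optional `"label"`.
#' Stay probabilities are never stored — always derived.
#'
#' @param path JSON file path.
#' @return A [transition_params] object.
#' @export
load_params <- function(path) {
  obj <- jsonlite::read_json(path)
  miss <- setdiff(ARROW_KEYS, names(obj))
  if (length(miss))
    stop("parameter file '", path, "' missing key(s): ",
         paste0('"', miss, '"', collapse = ", "), call. = FALSE)
  vals <- vapply(obj[ARROW_KEYS], function(v) {
    if (!is.numeric(v) || length(v) != 1) NA_real_ else as.numeric(v)
  }, 0)
  bad <- ARROW_KEYS[is.na(vals) | vals < 0 | vals > 1]
  if (length(bad))
    stop("parameter file '", path, "': value(s) for ",
         paste0('"', bad, '"', collapse = ", "),
         " missing, non-numeric or outside [0, 1]", call. = FALSE)
  args <- as.list(setNames(vals, names(PARAM_ARROWS)[
    match(ARROW_KEYS, PARAM_ARROWS)]))
  args$label <- if (!is.null(obj$label)) as.character(obj$label) else NULL
  do.call(transition_params, args)
}

#' Save transition parameters to JSON
#'
#' @param params a [transition_params] object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
save_params <- function(params, path) {
  stopifnot(inherits(params, "transition_params"))
  obj <- as.list(setNames(as.numeric(unclass(params)[names(PARAM_ARROWS)]),
                          ARROW_KEYS))
  if (!is.null(attr(params, "label"))) obj$label <- attr(params, "label")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a state distribution (JSON object or one-row CSV)
#'
#' Keys/columns `X`, `C1`, `A`, `R`, `C2`; normalized on construction.
#'
#' @param path file path (`.json` or `.csv`).
#' @return A [state_vector].
#' @export
load_state <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path)
  } else {
    obj <- as.list(read.csv(path)[1, ])
  }
  miss <- setdiff(STATE_NAMES, names(obj))
  if (length(miss))
    stop("state file '", path, "' missing component(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  state_vector(as.numeric(unlist(obj[STATE_NAMES])))
}

#' Load a printed full transition matrix from CSV
#'
#' A 5x5 table with a `state` column naming the source rows, columns
#' X, C1, A, R, C2, and stay probabilities included (as printed tables
#' have them).  Rows are renormalized to sum to 1; a warning reports rows
#' whose raw sum deviates from 1 by more than 0.02, so rounded published
#' tables load without silently hiding data-entry issues.  Structural-zero
#' cells may be empty or `NA` (treated as 0).
#'
#' @param path CSV path.
#' @param label optional label.
#' @return A [transition_params] object.
#' @export
load_matrix_csv <- function(path, label = NULL) {
  df <- read.csv(path)
  stopifnot("state" %in% names(df), all(STATE_NAMES %in% names(df)))
  M <- as.matrix(df[STATE_NAMES])
  rownames(M) <- df$state
  M <- M[STATE_NAMES, ]
  M[is.na(M)] <- 0
  params_from_matrix(M, label = label, renormalize = TRUE, tol = 0.02)
}

#' Write a panel, states or transitions table to CSV
#'
#' Thin wrapper fixing the conventions (UTF-8, header, no row names).
#'
#' @param df data.frame.
#' @param path output path.
#' @param force overwrite an existing file?
#' @return The path, invisibly.
#' @export
write_table_csv <- function(df, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("output file exists: ", path, " (use force = TRUE to overwrite)",
         call. = FALSE)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
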