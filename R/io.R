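#' Read a bout-log CSV
#'
#' The bout-log dialect has one row per bout with columns `individual_id`,
#' `diet`, `instar`, `state` (`feeding`/`nonfeeding`), `start_s`, `end_s`,
#' and `trial_length_s` (default 3600).  Each individual's rows must form a
#' valid bout sequence (contiguous, strictly alternating, covering the
#' window); violations raise errors naming the offending rows.
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @return A list with elements `sequences` (named list of
#'   [bout_sequence()]), `meta` (data frame `individual_id`, `diet`,
#'   `instar`, one row per individual) and `trials` (the
#'   [trials_from_bouts()] table).
#' @export
read_bout_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "diet", "instar", "state", "start_s", "end_s")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("bout log missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$trial_length_s)) df$trial_length_s <- 3600
  df$.row <- seq_len(nrow(df)) + 1L      # file line numbers (header = 1)
  seqs <- list(); meta <- list()
  for (id in unique(df$individual_id)) {
    rows <- df[df$individual_id == id, , drop = FALSE]
    rows <- rows[order(rows$start_s), , drop = FALSE]
    seq <- tryCatch(
      bout_sequence(rows$state, rows$start_s, rows$end_s,
                    rows$trial_length_s[1] / SECONDS_PER_HOUR),
      error = function(e)
        stop(sprintf("individual '%s' (file rows %s): %s", id,
                     paste(range(rows$.row), collapse = "-"),
                     conditionMessage(e)), call. = FALSE))
    seqs[[id]] <- seq
    meta[[id]] <- data.frame(individual_id = id, diet = rows$diet[1],
                             instar = rows$instar[1])
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  trials <- trials_from_bouts(seqs,
                              meta[, c("diet", "instar"), drop = FALSE])
  trials$individual_id <- meta$individual_id
  rownames(trials) <- NULL
  list(sequences = seqs, meta = meta, trials = trials)
}

#' Write a bout-log data frame as CSV
#'
#' @param boutlog Data frame in the bout-log dialect (see
#'   [read_bout_log()]), e.g. from [generate_trials()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bout_log <- function(boutlog, path) {
  write.csv(boutlog, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mass-record CSV
#'
#' Columns: `individual_id`, `diet`, `instar`, `mass_molt_g`,
#' `mass_pretrial_g`, `elapsed_h`.
#'
#' @param path Path to the CSV.
#' @return Validated data frame.
#' @export
read_mass_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "diet", "instar", "mass_molt_g",
           "mass_pretrial_g", "elapsed_h")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("mass records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$mass_molt_g <= 0) || any(df$mass_pretrial_g <= 0) ||
      any(df$elapsed_h <= 0))
    stop("masses and elapsed times must be positive", call. = FALSE)
  df
}

#' Adapter for externally deposited trial archives
#'
#' Deposited data rarely match the package's column names exactly.  This
#' loader reads an arbitrary delimited file and renames columns according to
#' `col_map`, then validates the result as a bout log.  State labels can be
#' recoded via `state_map`.
#'
#' @param path Path to the delimited file.
#' @param col_map Named character vector mapping bout-log dialect names to
#'   the file's column names, e.g. `c(individual_id = "larva", state =
#'   "behavior", ...)`.  Unmapped dialect columns must already be present
#'   under their own names.
#' @param state_map Named character vector recoding the file's state labels
#'   to `"feeding"`/`"nonfeeding"`, e.g. `c(F = "feeding", N =
#'   "nonfeeding")`.
#' @param sep Field separator (default `","`).
#' @return As [read_bout_log()].
#' @export
read_trial_archive <- function(path, col_map = character(0),
                               state_map = NULL, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  for (target in names(col_map)) {
    src <- col_map[[target]]
    if (!src %in% names(df))
      stop(sprintf("mapped column '%s' not found in %s", src, path),
           call. = FALSE)
    df[[target]] <- df[[src]]
  }
  if (!is.null(state_map)) {
    known <- df$state %in% names(state_map)
    if (!all(known))
      stop("unmapped state labels: ",
           paste(unique(df$state[!known]), collapse = ", "), call. = FALSE)
    df$state <- unname(state_map[df$state])
  }
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write.csv(df, tmp, row.names = FALSE)
  read_bout_log(tmp)
}

#' Write a per-group alpha table
#'
#' @param alphas Data frame with columns `diet`, `instar`, `alpha_mean`,
#'   `alpha_sd`, `n`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alpha_table <- function(alphas, path) {
  write.csv(alphas, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# plain-text run log: seed, package version, parameters
write_run_log <- function(path, subcommand, seed, params) {
  lines <- c(
    sprintf("boutgrow %s", as.character(packageVersion("boutgrow"))),
    sprintf("subcommand: %s", subcommand),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("seed: %s", seed),
    vapply(names(params), function(k)
      sprintf("%s: %s", k, paste(format(params[[k]]), collapse = ",")),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}
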