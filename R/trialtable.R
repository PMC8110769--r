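# Trial-table I/O. The trial table is the interchange format between all
# stages: one row per trial, orientations of the stimulus sequence joined
# with ";" in a single column, plain UTF-8 CSV with "." decimals.

TRIAL_TABLE_REQUIRED <- c("participant", "block", "trial", "condition",
                          "orientations", "reported", "rt")
TRIAL_TABLE_OPTIONAL <- c("experiment", "n_stimuli", "rotation_delta",
                          "is_early_control", "is_rotation_break_control",
                          "target")

.parse_orientations <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), as.numeric)
}

#' Convert a generated session to a trial table
#'
#' @param session list of `trial_sequence` objects from [make_session()].
#' @param participant participant identifier.
#' @param experiment experiment label (taken from the trials if missing).
#' @return a `data.frame` in the trial-table schema with `reported` and
#'   `rt` set to `NA` (to be filled by an observer or by real data).
#' @export
session_to_table <- function(session, participant = 1L, experiment = NULL) {
  stopifnot(length(session) > 0, inherits(session[[1]], "trial_sequence"))
  if (is.null(experiment)) experiment <- session[[1]]$experiment
  block <- vapply(session, `[[`, integer(1), "block")
  data.frame(
    participant = participant,
    experiment = experiment,
    block = block,
    trial = stats::ave(seq_along(session), block, FUN = seq_along),
    condition = vapply(session, `[[`, character(1), "condition"),
    n_stimuli = vapply(session, `[[`, integer(1), "n_stimuli"),
    rotation_delta = vapply(session, `[[`, numeric(1), "rotation_delta"),
    is_early_control = vapply(session, `[[`, logical(1), "is_early_control"),
    is_rotation_break_control =
      vapply(session, `[[`, logical(1), "is_rotation_break_control"),
    orientations = vapply(session, function(tr) {
      paste(tr$orientations, collapse = ";")
    }, character(1)),
    target = vapply(session, function(tr) tr$orientations[tr$n_stimuli],
                    numeric(1)),
    reported = NA_real_,
    rt = NA_real_,
    stringsAsFactors = FALSE)
}

#' Read a trial table from CSV
#'
#' Reads a trial-level CSV and validates the schema. External files whose
#' columns are named differently (for example a public data deposit) can be
#' adapted with `col_map`, a named character vector mapping external column
#' names to the canonical ones (`c(subj = "participant", resp = "reported")`),
#' or the path to a YAML/JSON file holding such a mapping.
#'
#' @param path CSV file path.
#' @param col_map optional column mapping (named character vector, named
#'   list, or path to a YAML/JSON mapping file).
#' @return a `data.frame` in the trial-table schema.
#' @export
read_trials <- function(path, col_map = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    if (is.character(col_map) && length(col_map) == 1 && file.exists(col_map)) {
      col_map <- if (grepl("\\.ya?ml$", col_map, ignore.case = TRUE)) {
        if (!requireNamespace("yaml", quietly = TRUE)) {
          stop("reading a YAML column map requires the 'yaml' package")
        }
        unlist(yaml::read_yaml(col_map))
      } else {
        unlist(jsonlite::read_json(col_map, simplifyVector = TRUE))
      }
    }
    col_map <- unlist(col_map)
    hit <- names(tab) %in% names(col_map)
    names(tab)[hit] <- unname(col_map[names(tab)[hit]])
  }
  missing_cols <- setdiff(TRIAL_TABLE_REQUIRED, names(tab))
  if (length(missing_cols) > 0) {
    stop("trial table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ors <- .parse_orientations(tab$orientations)
  if (any(vapply(ors, function(o) any(is.na(o)), logical(1)))) {
    stop("could not parse `orientations`: expected ';'-separated degrees")
  }
  if (is.null(tab$n_stimuli)) tab$n_stimuli <- lengths(ors)
  if (is.null(tab$target)) {
    tab$target <- vapply(seq_along(ors), function(i) ors[[i]][tab$n_stimuli[i]],
                         numeric(1))
  }
  if (is.null(tab$experiment)) tab$experiment <- NA_character_
  if (is.null(tab$rotation_delta)) tab$rotation_delta <- NA_real_
  if (is.null(tab$is_early_control)) tab$is_early_control <- FALSE
  if (is.null(tab$is_rotation_break_control)) tab$is_rotation_break_control <- FALSE
  tab$is_early_control <- as.logical(tab$is_early_control)
  tab$is_rotation_break_control <- as.logical(tab$is_rotation_break_control)
  tab
}

#' Write a trial table to CSV
#'
#' Numeric columns are formatted with 17 significant digits so that a
#' write/read round trip reproduces the doubles exactly.
#'
#' @param table a trial-table `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path) {
  out <- table
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- NA_character_
      out[[nm]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
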