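#' Read and validate a CSAS-PR codebook
#'
#' The codebook maps item columns to their role in the instrument: 18
#' disorder items on a 0--3 Likert scale (two per DSM-5 IGD criterion),
#' four device-frequency items on a 0--6 Likert scale (computer, game
#' console, portable game console, mobile phone), and the two gaming-time
#' fields. The packaged default codebook is returned by
#' [default_codebook()].
#'
#' @param path path to a comma-delimited codebook with columns `item_id`,
#'   `scale_min`, `scale_max`, `role`, `criterion`, `item_pair_index`.
#' @return a data.frame of class `csas_codebook`.
#' @seealso [read_responses()], [default_codebook()]
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop_hz("codebook file not found: %s", path)
  cb <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_codebook(cb)
}

#' The packaged default CSAS-PR codebook
#'
#' Only three item pairings are documented for the instrument (give up
#' other activities = items 11/15, continue despite problems = 6/14,
#' risk/lose = 16/18); the remaining six criteria are assigned the
#' remaining twelve items by a fixed package convention. Users with the
#' authoritative mapping can supply their own codebook file.
#'
#' @return a validated `csas_codebook` data.frame.
#' @export
default_codebook <- function() {
  read_codebook(system.file("extdata", "codebook_csas_pr.csv",
                            package = "hazescore", mustWork = TRUE))
}

IGD_CRITERIA <- c("preoccupation", "tolerance", "withdrawal", "loss_of_control",
                  "escape_mood", "continue_despite_problems", "deception",
                  "give_up_activities", "risk_lose")
DEVICES <- c("computer", "game_console", "portable_console", "mobile_phone")

#' Validate a codebook data.frame
#'
#' Enforces the structural invariants of the instrument: unique item ids,
#' exactly 18 disorder items with two per criterion across all nine IGD
#' criteria, exactly four device-frequency items, and sane scale bounds.
#'
#' @param cb a data.frame with the codebook columns.
#' @return the validated codebook, classed `csas_codebook`.
#' @export
validate_codebook <- function(cb) {
  need <- c("item_id", "scale_min", "scale_max", "role", "criterion",
            "item_pair_index")
  miss <- setdiff(need, names(cb))
  if (length(miss)) stop_hz("codebook lacks column(s): %s", toString(miss))
  dup <- cb$item_id[duplicated(cb$item_id)]
  if (length(dup)) stop_hz("duplicate item_id in codebook: %s", toString(unique(dup)))
  ord <- cb$role %in% c("igd_item", "frequency_item")
  bad <- ord & (is.na(cb$scale_min) | is.na(cb$scale_max) |
                  cb$scale_min >= cb$scale_max)
  if (any(bad))
    stop_hz("inverted or missing scale bounds for: %s", toString(cb$item_id[bad]))
  igd <- cb[cb$role == "igd_item", ]
  if (nrow(igd) != 18)
    stop_hz("codebook must contain exactly 18 igd_item entries, found %d", nrow(igd))
  tab <- table(igd$criterion)
  if (length(tab) != 9 || any(tab != 2))
    stop_hz("each of the 9 IGD criteria needs exactly 2 items; offending: %s",
            toString(names(tab)[tab != 2]))
  fr <- cb[cb$role == "frequency_item", ]
  if (nrow(fr) != 4 || !setequal(fr$criterion, DEVICES))
    stop_hz("codebook must contain exactly 4 frequency_item entries labelled %s",
            toString(DEVICES))
  class(cb) <- c("csas_codebook", "data.frame")
  cb
}

META_COLS <- c("subject_id", "group", "gender", "age_years")

#' Read a CSAS-PR response table
#'
#' Reads a comma-delimited, one-header-row response file and validates it
#' against a codebook: every non-missing ordinal response must lie within
#' its item's scale bounds, subject ids must be unique, and gaming-time
#' minutes must be nonnegative. Missing cells (empty or `NA`) are
#' preserved as missing; nothing is imputed.
#'
#' @param path path to the CSV response file.
#' @param codebook a `csas_codebook`, e.g. [default_codebook()].
#' @return a data.frame of class `csas_responses` with metadata columns
#'   (`subject_id`, `group`, `gender`, `age_years`), one integer column
#'   per ordinal item and numeric `weekday_minutes`/`weekend_minutes`.
#' @export
read_responses <- function(path, codebook = default_codebook()) {
  if (!file.exists(path)) stop_hz("response file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validate_responses(df, codebook)
}

#' Validate an in-memory response table against a codebook
#'
#' @param df a data.frame shaped like the output of [read_responses()].
#' @inheritParams read_responses
#' @return the validated table, classed `csas_responses`.
#' @export
validate_responses <- function(df, codebook = default_codebook()) {
  items <- codebook$item_id[codebook$role %in% c("igd_item", "frequency_item")]
  timec <- codebook$item_id[codebook$role == "time_item"]
  unknown <- setdiff(names(df), c(META_COLS, items, timec))
  if (length(unknown)) stop_hz("unknown column(s): %s", toString(unknown))
  miss <- setdiff(c(META_COLS, items, timec), names(df))
  if (length(miss)) stop_hz("response table lacks column(s): %s", toString(miss))
  if (anyDuplicated(df$subject_id))
    stop_hz("duplicate subject_id: %s",
            toString(unique(df$subject_id[duplicated(df$subject_id)])))
  badg <- !df$group %in% c("school", "clinic")
  if (any(badg)) stop_hz("invalid group value for subject(s): %s",
                         toString(df$subject_id[badg]))
  bads <- !df$gender %in% c("female", "male", "unspecified")
  if (any(bads)) stop_hz("invalid gender value for subject(s): %s",
                         toString(df$subject_id[bads]))
  for (it in items) {
    v <- df[[it]]
    lo <- codebook$scale_min[codebook$item_id == it]
    hi <- codebook$scale_max[codebook$item_id == it]
    bad <- !is.na(v) & (v < lo | v > hi | v != round(v))
    if (any(bad)) {
      i <- which(bad)[1]
      stop_hz("response out of range: subject %s, item %s, value %s (scale %d-%d)",
              df$subject_id[i], it, format(v[i]), lo, hi)
    }
    df[[it]] <- as.integer(v)
  }
  for (tc in timec) {
    v <- df[[tc]]
    bad <- !is.na(v) & v < 0
    if (any(bad)) {
      i <- which(bad)[1]
      stop_hz("negative gaming time: subject %s, column %s, value %s",
              df$subject_id[i], tc, format(v[i]))
    }
    df[[tc]] <- as.numeric(v)
  }
  class(df) <- c("csas_responses", "data.frame")
  df
}

#' Write a response table in the package CSV dialect
#'
#' Missing values are written as empty cells so that
#' `read_responses(write_responses(x))` round-trips exactly.
#'
#' @param table a `csas_responses` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-item and per-subject missingness
#'
#' Reports, for every item and time column, the number of non-missing
#' responses (the per-item "N" of a descriptives table) and, per subject,
#' the number of missing entries. No imputation is performed anywhere in
#' the package; downstream stages apply their own valid-data rules.
#'
#' @inheritParams validate_responses
#' @return list with `per_item` (data.frame: item_id, n_nonmissing,
#'   n_missing) and `per_subject` (data.frame: subject_id, n_missing).
#' @export
missingness_report <- function(df, codebook = default_codebook()) {
  cols <- codebook$item_id[codebook$role %in%
                             c("igd_item", "frequency_item", "time_item")]
  m <- as.matrix(is.na(df[, cols, drop = FALSE]))
  list(
    per_item = data.frame(item_id = cols,
                          n_nonmissing = nrow(df) - colSums(m),
                          n_missing = colSums(m),
                          row.names = NULL),
    per_subject = data.frame(subject_id = df$subject_id,
                             n_missing = rowSums(m),
                             row.names = NULL)
  )
}
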