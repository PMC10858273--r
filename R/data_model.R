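# Trial-level data model for repeated dyadic/triadic ultimatum games.
#
# A trial is one game round: on dyadic trials a single proposer pushes
# 1..8 grapes to the responder; on triadic trials two proposers offer
# (simultaneously, or consecutively with the second proposer seeing the
# first offer) and the responder can accept exactly one offer.  Offer 0
# encodes "no offer made within the allowed time"; such trials are kept
# in the table but excluded from model responses.

#' Condition labels
#'
#' Canonical labels for the three trial conditions: dyadic (one proposer),
#' triadic simultaneous (both proposers offer without seeing each other)
#' and triadic consecutive (the second proposer sees the first offer).
#'
#' @return Character vector of the three condition labels.
#' @export
ug_conditions <- function() {
  c("dyadic", "triadic_simultaneous", "triadic_consecutive")
}

#' Canonical trial-table columns
#'
#' Column names and order of the canonical trial CSV schema.
#'
#' @return Character vector of column names.
#' @export
ug_trial_columns <- function() {
  c("triad_id", "session_index", "trial_index", "condition",
    "left_proposer", "right_proposer", "responder",
    "first_side", "offer_left", "offer_right", "accepted_side")
}

#' Assemble and validate a trial dataset
#'
#' Coerces a data frame with the canonical columns into a validated
#' `ug_trials` tibble.  Validation enforces the structural invariants of
#' the experiment: offers in 0..8 (0 = timeout, sent offers are 1..8),
#' dyadic trials carry exactly one offer, an accepted side must hold a
#' sent offer, `first_side` is only defined on consecutive trials, and
#' `(triad_id, session_index, trial_index)` identifies a trial uniquely
#' with at most 8 trials per session.
#'
#' @param trials Data frame with the columns of [ug_trial_columns()].
#' @return A tibble of class `ug_trials`, ordered by triad, session and
#'   trial.
#' @export
as_ug_trials <- function(trials) {
  trials <- as_tibble(trials)
  missing_cols <- setdiff(ug_trial_columns(), names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ug_schema_error")
  }
  trials <- trials[, ug_trial_columns()]
  trials$triad_id <- as.character(trials$triad_id)
  trials$session_index <- as.integer(trials$session_index)
  trials$trial_index <- as.integer(trials$trial_index)
  for (col in c("condition", "left_proposer", "right_proposer",
                "responder", "first_side", "accepted_side")) {
    trials[[col]] <- as.character(trials[[col]])
  }
  trials$offer_left <- as.integer(trials$offer_left)
  trials$offer_right <- as.integer(trials$offer_right)

  problems <- validate_ug_trials(trials)
  if (nrow(problems) > 0) {
    msg <- paste0(
      "invalid trial data (", nrow(problems), " problem(s)):\n",
      paste0("  row ", problems$row, ": ", problems$problem,
             collapse = "\n"))
    abort(msg, class = "ug_validation_error", problems = problems)
  }
  trials <- arrange(trials, .data$triad_id, .data$session_index,
                    .data$trial_index)
  class(trials) <- c("ug_trials", class(trials))
  trials
}

#' Row-level validation diagnostics for a trial table
#'
#' Checks every structural invariant of the trial schema and returns one
#' row per violation rather than failing on the first, so that malformed
#' files can be diagnosed in a single pass.
#'
#' @param trials Data frame with canonical columns (not yet validated).
#' @return Tibble with columns `row` (1-based row number in `trials`) and
#'   `problem` (human-readable description); zero rows when valid.
#' @export
validate_ug_trials <- function(trials) {
  probs <- list()
  add <- function(rows, what) {
    if (length(rows) > 0) {
      probs[[length(probs) + 1L]] <<- tibble(row = rows, problem = what)
    }
  }
  offer_ok <- function(x) is.na(x) | (x >= 0L & x <= 8L)

  add(which(!trials$condition %in% ug_conditions()),
      "condition not one of dyadic/triadic_simultaneous/triadic_consecutive")
  add(which(is.na(trials$session_index) | trials$session_index < 1L),
      "session_index must be a positive integer")
  add(which(is.na(trials$trial_index) | trials$trial_index < 1L |
              trials$trial_index > 8L),
      "trial_index must lie in 1..8")
  add(which(!offer_ok(trials$offer_left)), "offer_left outside 0..8")
  add(which(!offer_ok(trials$offer_right)), "offer_right outside 0..8")
  add(which(!is.na(trials$accepted_side) &
              !trials$accepted_side %in% c("left", "right", "none")),
      "accepted_side must be left, right or none")
  add(which(!is.na(trials$first_side) &
              !trials$first_side %in% c("left", "right")),
      "first_side must be left, right or NA")

  dyadic <- trials$condition == "dyadic"
  n_offers <- (!is.na(trials$offer_left)) + (!is.na(trials$offer_right))
  add(which(dyadic & n_offers != 1L),
      "dyadic trial must have exactly one non-missing offer")
  add(which(!dyadic & !is.na(trials$condition) & n_offers == 0L),
      "triadic trial must have at least one recorded offer")

  acc_l <- !is.na(trials$accepted_side) & trials$accepted_side == "left"
  acc_r <- !is.na(trials$accepted_side) & trials$accepted_side == "right"
  sent <- function(x) !is.na(x) & x >= 1L
  add(which(acc_l & !sent(trials$offer_left)),
      "accepted_side = left but no sent offer on the left")
  add(which(acc_r & !sent(trials$offer_right)),
      "accepted_side = right but no sent offer on the right")

  add(which(!is.na(trials$first_side) &
              trials$condition != "triadic_consecutive"),
      "first_side defined outside a consecutive trial")

  key <- paste(trials$triad_id, trials$session_index, trials$trial_index)
  add(which(duplicated(key)),
      "duplicate (triad_id, session_index, trial_index)")

  per_session <- table(paste(trials$triad_id, trials$session_index))
  bad_sessions <- names(per_session)[per_session > 8L]
  if (length(bad_sessions) > 0) {
    rows <- which(paste(trials$triad_id, trials$session_index) %in%
                    bad_sessions & trials$trial_index == 1L)
    add(rows, "session holds more than 8 trials")
  }

  if (length(probs) == 0) {
    return(tibble(row = integer(), problem = character()))
  }
  arrange(bind_rows(probs), .data$row)
}

#' Read a trial CSV
#'
#' Loads a trial-level CSV into a validated `ug_trials` tibble.  Files in
#' the canonical schema load directly; external files are adapted through
#' a *dialect*: a named list (or YAML file) with a `columns` block mapping
#' canonical names to the file's column names and optional `values` blocks
#' remapping condition/side codes.
#'
#' @param path Path to a CSV file (UTF-8, header row, empty fields are
#'   missing values).
#' @param dialect `NULL` for the canonical schema, a named list, or the
#'   path to a YAML dialect file.
#' @return Validated `ug_trials` tibble.
#' @export
#' @examples
#' d <- simulate_experiment(generate_design("dyadic", "P1"),
#'                          strategy_minimal(), strategy_minimal(),
#'                          responder_maximizer(), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_trials(d, f)
#' identical(load_trials(f), d)
load_trials <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ug_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE,
                         show_col_types = FALSE)
  if (is.character(dialect) && length(dialect) == 1L) {
    dialect <- yaml::read_yaml(dialect)
  }
  if (!is.null(dialect)) {
    raw <- apply_dialect(raw, dialect)
  }
  as_ug_trials(raw)
}

apply_dialect <- function(raw, dialect) {
  cols <- dialect$columns
  if (!is.null(cols)) {
    missing_src <- setdiff(unlist(cols), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0("dialect maps missing column(s): ",
                   paste(missing_src, collapse = ", ")),
            class = "ug_schema_error")
    }
    for (canon in names(cols)) {
      raw[[canon]] <- raw[[cols[[canon]]]]
    }
  }
  for (canon in names(dialect$values)) {
    map <- dialect$values[[canon]]
    v <- raw[[canon]]
    hit <- v %in% names(map)
    v[hit] <- unlist(map)[v[hit]]
    raw[[canon]] <- v
  }
  raw
}

#' Write a trial CSV
#'
#' Writes a validated trial table to the canonical CSV layout (stable
#' column order, missing values as empty fields).  The round trip through
#' [load_trials()] is lossless on every field.
#'
#' @param trials `ug_trials` tibble (or coercible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- as_ug_trials(trials)
  readr::write_csv(as_tibble(trials)[, ug_trial_columns()], path,
                   na = "", progress = FALSE)
  invisible(path)
}

#' Per-triad role roster
#'
#' @param trials `ug_trials` tibble.
#' @return Tibble with one row per triad listing the two proposers and the
#'   responder.
#' @export
ug_roster <- function(trials) {
  trials %>%
    as_tibble() %>%
    group_by(.data$triad_id) %>%
    summarise(
      proposers = list(sort(unique(c(.data$left_proposer,
                                     .data$right_proposer)))),
      responder = unique(.data$responder)[1],
      n_sessions = dplyr::n_distinct(.data$session_index),
      .groups = "drop")
}

#' Proposer-level trial views
#'
#' Reshapes the trial table to one row per (proposer, trial on which that
#' proposer made a sent offer), adding the within-session history each
#' escalation model conditions on: the proposer's own previous sent offer
#' and whether it was accepted, and the offer accepted on the immediately
#' preceding trial of the session (with a flag for whether that winning
#' offer was the proposer's own).  History never crosses a session
#' boundary, so each proposer's first offering trial of a session has all
#' `previous_*` fields missing.
#'
#' @param trials `ug_trials` tibble.
#' @return Tibble with columns `triad_id`, `proposer_id`, `session_index`,
#'   `trial_index`, `condition`, `side`, `own_offer`, `own_accepted`,
#'   `acted_second`, `first_offer_seen`, `previous_own_offer`,
#'   `previous_own_accepted`, `previous_winning_offer`,
#'   `previous_winner_own`.
#' @export
proposer_views <- function(trials) {
  trials <- as_ug_trials(trials)
  long <- bind_rows(
    trials %>%
      mutate(proposer_id = .data$left_proposer, side = "left",
             own_offer = .data$offer_left),
    trials %>%
      mutate(proposer_id = .data$right_proposer, side = "right",
             own_offer = .data$offer_right)) %>%
    filter(!is.na(.data$own_offer), .data$own_offer >= 1L) %>%
    mutate(
      own_accepted = !is.na(.data$accepted_side) &
        .data$accepted_side == .data$side,
      acted_second = .data$condition == "triadic_consecutive" &
        !is.na(.data$first_side) & .data$side != .data$first_side,
      first_offer_seen = if_else(
        .data$acted_second,
        if_else(.data$first_side == "left",
                .data$offer_left, .data$offer_right),
        NA_integer_))

  winners <- trials %>%
    as_tibble() %>%
    mutate(
      winning_offer = dplyr::case_when(
        .data$accepted_side == "left" ~ .data$offer_left,
        .data$accepted_side == "right" ~ .data$offer_right,
        TRUE ~ NA_integer_),
      winner_proposer = dplyr::case_when(
        .data$accepted_side == "left" ~ .data$left_proposer,
        .data$accepted_side == "right" ~ .data$right_proposer,
        TRUE ~ NA_character_)) %>%
    select("triad_id", "session_index", "trial_index",
           "winning_offer", "winner_proposer")

  long %>%
    left_join(winners %>%
                mutate(trial_index = .data$trial_index + 1L) %>%
                rename(previous_winning_offer = "winning_offer",
                       previous_winner = "winner_proposer"),
              by = c("triad_id", "session_index", "trial_index")) %>%
    arrange(.data$triad_id, .data$proposer_id, .data$session_index,
            .data$trial_index) %>%
    group_by(.data$triad_id, .data$proposer_id, .data$session_index) %>%
    mutate(previous_own_offer = lag(.data$own_offer),
           previous_own_accepted = lag(.data$own_accepted)) %>%
    ungroup() %>%
    mutate(
      previous_winner_own = if_else(
        is.na(.data$previous_winning_offer), NA,
        .data$previous_winner == .data$proposer_id)) %>%
    select("triad_id", "proposer_id", "session_index", "trial_index",
           "condition", "side", "own_offer", "own_accepted",
           "acted_second", "first_offer_seen",
           "previous_own_offer", "previous_own_accepted",
           "previous_winning_offer", "previous_winner_own")
}
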