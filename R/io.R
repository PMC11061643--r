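#' Read and write chase event logs
#'
#' An event log holds one row per timed behavioural event within a chase:
#' the chase it belongs to, the onset time in seconds since flight
#' initiation, the actor (`predator` or `flock`) and the behaviour label
#' (see [behaviour_labels()]). Behaviour and actor labels are canonicalised
#' case-insensitively. Extra columns are preserved but ignored by all
#' analyses.
#'
#' @param path path to a CSV file with header
#'   `chase_id,t_onset_s,actor,behaviour`.
#' @param events an event data frame as returned by `read_events()`.
#' @return `read_events()` returns a data frame with columns `chase_id`
#'   (character), `t_onset_s` (numeric, non-negative), `actor` and
#'   `behaviour` (character), one row per event in file order.
#'   `write_events()` writes the canonical CSV form and returns `path`
#'   invisibly.
#' @seealso [read_chases()], [validate_dataset()]
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("chase_id", "t_onset_s", "actor", "behaviour")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("event file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(data.frame(chase_id = character(), t_onset_s = numeric(),
                      actor = character(), behaviour = character(),
                      stringsAsFactors = FALSE))
  }
  t <- suppressWarnings(as.numeric(df$t_onset_s))
  bad_t <- which(is.na(t) | t < 0)
  if (length(bad_t)) {
    stop("malformed onset time in event row ", bad_t[1],
         " (value '", df$t_onset_s[bad_t[1]], "'): must be a non-negative number")
  }
  beh <- canonical_label(df$behaviour)
  bad_b <- which(!beh %in% behaviour_labels())
  if (length(bad_b)) {
    stop("unknown behaviour label '", df$behaviour[bad_b[1]],
         "' in event row ", bad_b[1])
  }
  act <- canonical_label(df$actor)
  bad_a <- which(!act %in% c("predator", "flock"))
  if (length(bad_a)) {
    stop("unknown actor '", df$actor[bad_a[1]], "' in event row ", bad_a[1],
         ": must be 'predator' or 'flock'")
  }
  df$t_onset_s <- t
  df$actor <- act
  df$behaviour <- beh
  df
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  out <- events[, c("chase_id", "t_onset_s", "actor", "behaviour")]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write chase metadata
#'
#' One row per chase: species, predator type, duration, chasing intensity
#' (the proportion of the chase the predator spent in active pursuit or
#' attack), approach altitude class (`high` = above 50 m, `low` = below
#' 50 m, else `unknown`), a multi-species-flock flag, the operator, and an
#' optional flock size. Duplicate chase ids and out-of-range values are
#' rejected; a blank altitude field defaults to `unknown`.
#'
#' @param path path to a CSV file with header
#'   `chase_id,species,predator_type,duration_s,chasing_intensity,altitude_class,multiple_species,operator_id,flock_size`.
#' @param chases a chase data frame as returned by `read_chases()`.
#' @return `read_chases()` returns a data frame with one row per chase.
#'   `write_chases()` writes the canonical CSV form and returns `path`
#'   invisibly.
#' @export
read_chases <- function(path) {
  if (!file.exists(path)) stop("chase file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("chase_id", "species", "predator_type", "duration_s",
            "chasing_intensity", "altitude_class", "multiple_species",
            "operator_id", "flock_size")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("chase file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) return(empty_chases())
  dup <- df$chase_id[duplicated(df$chase_id)]
  if (length(dup)) stop("duplicate chase_id: ", dup[1])

  sp <- canonical_label(df$species)
  bad <- which(!sp %in% species_levels())
  if (length(bad)) stop("unknown species '", df$species[bad[1]], "' in chase row ", bad[1])
  pt <- canonical_label(df$predator_type)
  bad <- which(!pt %in% predator_levels())
  if (length(bad)) stop("unknown predator_type '", df$predator_type[bad[1]], "' in chase row ", bad[1])

  dur <- suppressWarnings(as.numeric(df$duration_s))
  bad <- which(is.na(dur) | dur <= 0)
  if (length(bad)) stop("duration_s must be a positive number (chase row ", bad[1], ")")
  ci <- suppressWarnings(as.numeric(df$chasing_intensity))
  bad <- which(is.na(ci) | ci < 0 | ci > 1)
  if (length(bad)) {
    stop("chasing_intensity must lie in [0, 1] (chase row ", bad[1],
         ", value '", df$chasing_intensity[bad[1]], "')")
  }
  alt <- canonical_label(df$altitude_class)
  alt[alt == "" | is.na(alt)] <- "unknown"
  bad <- which(!alt %in% altitude_levels())
  if (length(bad)) stop("unknown altitude_class '", df$altitude_class[bad[1]], "' in chase row ", bad[1])
  ms <- parse_logical(df$multiple_species)
  bad <- which(is.na(ms))
  if (length(bad)) stop("multiple_species must be true/false (chase row ", bad[1], ")")
  fs <- suppressWarnings(as.integer(df$flock_size))
  fs[df$flock_size == ""] <- NA_integer_
  bad <- which(!is.na(fs) & fs <= 0)
  if (length(bad)) stop("flock_size must be a positive integer (chase row ", bad[1], ")")

  data.frame(chase_id = df$chase_id, species = sp, predator_type = pt,
             duration_s = dur, chasing_intensity = ci, altitude_class = alt,
             multiple_species = ms, operator_id = df$operator_id,
             flock_size = fs, stringsAsFactors = FALSE)
}

#' @rdname read_chases
#' @export
write_chases <- function(chases, path) {
  out <- chases[, c("chase_id", "species", "predator_type", "duration_s",
                    "chasing_intensity", "altitude_class", "multiple_species",
                    "operator_id", "flock_size")]
  out$multiple_species <- tolower(as.character(out$multiple_species))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

empty_chases <- function() {
  data.frame(chase_id = character(), species = character(),
             predator_type = character(), duration_s = numeric(),
             chasing_intensity = numeric(), altitude_class = character(),
             multiple_species = logical(), operator_id = character(),
             flock_size = integer(), stringsAsFactors = FALSE)
}

parse_logical <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' Import a BORIS-style tabular event export
#'
#' Maps a BORIS-like behavioural observation export (one row per coded
#' event, with an observation id, a time in seconds and a behaviour column)
#' onto the canonical event schema. The actor is inferred from the behaviour
#' label's class: predator acts get actor `predator`, escape patterns get
#' actor `flock`.
#'
#' @param path path to the tabular export (CSV).
#' @param obs_col,time_col,behaviour_col column names in the export holding
#'   the observation (chase) id, the event time in seconds and the behaviour
#'   label.
#' @return an event data frame in the canonical schema (see
#'   [read_events()]).
#' @export
read_events_boris <- function(path, obs_col = "Observation.id",
                              time_col = "Time", behaviour_col = "Behavior") {
  if (!file.exists(path)) stop("event file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c(obs_col, time_col, behaviour_col), names(df))
  if (length(miss)) {
    stop("BORIS export ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  beh <- canonical_label(df[[behaviour_col]])
  bad <- which(!beh %in% behaviour_labels())
  if (length(bad)) {
    stop("unknown behaviour label '", df[[behaviour_col]][bad[1]],
         "' in row ", bad[1])
  }
  t <- suppressWarnings(as.numeric(df[[time_col]]))
  bad <- which(is.na(t) | t < 0)
  if (length(bad)) stop("malformed time in row ", bad[1])
  data.frame(chase_id = as.character(df[[obs_col]]), t_onset_s = t,
             actor = ifelse(is_predator_act(beh), "predator", "flock"),
             behaviour = beh, stringsAsFactors = FALSE)
}

#' Cross-validate an event log against chase metadata
#'
#' Checks the joint consistency of an event log and its chase metadata and
#' returns a report of findings rather than failing: (i) events whose
#' `chase_id` has no metadata row, (ii) events with onset later than the
#' chase duration, (iii) actor/label mismatches (a `flock` actor must carry
#' an escape-pattern label, a `predator` actor a predator-act label). An
#' empty report means the dataset is analysable.
#'
#' @param events event data frame (see [read_events()]).
#' @param chases chase data frame (see [read_chases()]).
#' @return a data frame of class `validation_report` with columns `finding`,
#'   `chase_id`, `row` (event row number) and `detail`; zero rows if the
#'   dataset is consistent.
#' @export
validate_dataset <- function(events, chases) {
  findings <- list()
  add <- function(finding, chase_id, row, detail) {
    findings[[length(findings) + 1L]] <<- data.frame(
      finding = finding, chase_id = chase_id, row = row, detail = detail,
      stringsAsFactors = FALSE)
  }
  if (nrow(events)) {
    orphan <- which(!events$chase_id %in% chases$chase_id)
    for (i in orphan) {
      add("unknown_chase", events$chase_id[i], i, "event references a chase with no metadata row")
    }
    dur <- chases$duration_s[match(events$chase_id, chases$chase_id)]
    late <- which(!is.na(dur) & events$t_onset_s > dur)
    for (i in late) {
      add("onset_after_end", events$chase_id[i], i,
          sprintf("t_onset %.3f s exceeds chase duration %.3f s", events$t_onset_s[i], dur[i]))
    }
    mism <- which((events$actor == "flock" & !is_escape_pattern(events$behaviour)) |
                  (events$actor == "predator" & !is_predator_act(events$behaviour)))
    for (i in mism) {
      add("actor_label_mismatch", events$chase_id[i], i,
          sprintf("actor '%s' with behaviour '%s'", events$actor[i], events$behaviour[i]))
    }
  }
  rep <- if (length(findings)) do.call(rbind, findings) else
    data.frame(finding = character(), chase_id = character(), row = integer(),
               detail = character(), stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("validation report: no findings; dataset is analysable\n")
  } else {
    cat("validation report:", nrow(x), "finding(s)\n")
    print.data.frame(x, ...)
  }
  invisible(x)
}

stop_unless_valid <- function(events, chases) {
  rep <- validate_dataset(events, chases)
  if (nrow(rep)) {
    stop("dataset fails validation (", nrow(rep), " finding(s)); ",
         "first: ", rep$finding[1], " for chase ", rep$chase_id[1])
  }
  invisible(TRUE)
}
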