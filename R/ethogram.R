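#' Ethogram vocabulary
#'
#' The behavioural vocabulary used throughout the package: three acts of the
#' (artificial) predator and nine patterns of collective escape by the flock.
#' Every event in an event log carries exactly one of these twelve labels;
#' each label belongs to exactly one of the two classes.
#'
#' @details
#' Predator acts: `attack` (a manoeuvre aimed at intercepting prey),
#' `pursuit` (actively chasing the flock without intercepting) and
#' `not_chasing` (flying in the vicinity of, but not towards, the flock).
#'
#' Escape patterns: `collective_turn`, `compacting`, `split`,
#' `collective_dive`, `merge`, `blackening`, `flash_expansion`, `cordon` and
#' `wave_event`.
#'
#' @param x character vector of behaviour labels.
#' @return `behaviour_labels()` returns all twelve labels;
#'   `predator_acts()` and `escape_patterns()` return the two classes;
#'   `is_predator_act()` / `is_escape_pattern()` return logical vectors.
#' @examples
#' behaviour_labels()
#' is_escape_pattern(c("split", "attack"))
#' @export
behaviour_labels <- function() c(predator_acts(), escape_patterns())

#' @rdname behaviour_labels
#' @export
predator_acts <- function() c("attack", "pursuit", "not_chasing")

#' @rdname behaviour_labels
#' @export
escape_patterns <- function() {
  c("collective_turn", "compacting", "split", "collective_dive", "merge",
    "blackening", "flash_expansion", "cordon", "wave_event")
}

#' @rdname behaviour_labels
#' @export
is_predator_act <- function(x) x %in% predator_acts()

#' @rdname behaviour_labels
#' @export
is_escape_pattern <- function(x) x %in% escape_patterns()

# canonical factor levels for chase covariates
species_levels <- function() c("corvids", "gulls", "lapwings", "starlings")
predator_levels <- function() c("drone", "robotfalcon", "falcon")
altitude_levels <- function() c("high", "low", "unknown")

# canonicalise a behaviour label: case-insensitive, trimmed, spaces/hyphens
# mapped to underscores
canonical_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ -]+", "_", x)
}
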