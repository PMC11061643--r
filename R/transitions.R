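#' Configuration of the behavioural follow rule
#'
#' A behaviour B is classified as following an event A when B's onset falls
#' within the follow window after A's onset, inside the same chase. The
#' window is the half-open interval `(0, window_s]`: simultaneous events are
#' not transitions, an onset exactly at the window edge is. Two pairing
#' conventions are offered: `all_pairs` counts every ordered pair inside the
#' window (the default); `next_event` counts, for each antecedent, only the
#' first eligible event that follows it.
#'
#' @param window_s positive follow window in seconds (default 5).
#' @param pairing `"all_pairs"` or `"next_event"`.
#' @param include_predator_as_target should predator attacks be eligible as
#'   subsequents (matrix columns) as well as antecedents? Default `FALSE`.
#' @return a list of class `transition_config`.
#' @export
transition_config <- function(window_s = 5,
                              pairing = c("all_pairs", "next_event"),
                              include_predator_as_target = FALSE) {
  if (!is.numeric(window_s) || length(window_s) != 1 || window_s <= 0) {
    stop("window_s must be a single positive number")
  }
  cfg <- list(window_s = window_s, pairing = match.arg(pairing),
              include_predator_as_target = isTRUE(include_predator_as_target),
              boundary = "(0, window_s]")
  class(cfg) <- "transition_config"
  cfg
}

transition_row_labels <- function() c("attack", escape_patterns())
transition_col_labels <- function(cfg) {
  if (cfg$include_predator_as_target) c("attack", escape_patterns()) else escape_patterns()
}

#' Build a behavioural transition matrix for a group of chases
#'
#' Counts ordered antecedent-to-subsequent behaviour pairs under the follow
#' rule of a [transition_config()], pooled over the selected chases.
#' Antecedents are the nine escape patterns plus predator `attack`;
#' subsequents are the escape patterns (plus `attack` only if configured).
#' `pursuit` and `not_chasing` never enter the matrix — they describe chase
#' phases already captured by chasing intensity. Transitions never cross
#' chase boundaries.
#'
#' @inheritParams escape_counts_per_chase
#' @param config a [transition_config()].
#' @param species,predator_type,chase_ids optional filters selecting the
#'   group of chases to pool; an empty selection is an error.
#' @return an object of class `transition_matrix`: a list with `counts`
#'   (labelled integer matrix), `row_margins`, `col_margins`, `n_chases`,
#'   `n_events` (eligible events in the selection), `config` and `group`
#'   (a label describing the filter).
#' @examples
#' ev <- data.frame(chase_id = "c1", t_onset_s = c(0, 3, 6),
#'                  actor = c("predator", "flock", "flock"),
#'                  behaviour = c("attack", "flash_expansion", "split"))
#' ch <- data.frame(chase_id = "c1", species = "starlings",
#'                  predator_type = "robotfalcon", duration_s = 60,
#'                  chasing_intensity = 0.5, altitude_class = "high",
#'                  multiple_species = FALSE, operator_id = "op1",
#'                  flock_size = NA_integer_)
#' tm <- build_transitions(ev, ch)
#' tm$counts["attack", "flash_expansion"]  # 1
#' @export
build_transitions <- function(events, chases, config = transition_config(),
                              species = NULL, predator_type = NULL,
                              chase_ids = NULL) {
  stop_unless_valid(events, chases)
  sel <- rep(TRUE, nrow(chases))
  if (!is.null(species)) sel <- sel & chases$species %in% species
  if (!is.null(predator_type)) sel <- sel & chases$predator_type %in% predator_type
  if (!is.null(chase_ids)) sel <- sel & chases$chase_id %in% chase_ids
  ids <- chases$chase_id[sel]
  if (length(ids) == 0) {
    stop("chase filter selects no chases (species = ",
         paste(species %||% "any", collapse = "/"), ", predator_type = ",
         paste(predator_type %||% "any", collapse = "/"), ")")
  }

  rows <- transition_row_labels()
  cols <- transition_col_labels(config)
  counts <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  universe <- union(rows, cols)
  ev <- events[events$chase_id %in% ids & events$behaviour %in% universe, , drop = FALSE]

  for (id in unique(ev$chase_id)) {
    e <- ev[ev$chase_id == id, , drop = FALSE]
    e <- e[order(e$t_onset_s), , drop = FALSE]
    n <- nrow(e)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      a <- e$behaviour[i]
      if (!a %in% rows) next
      dt <- e$t_onset_s[(i + 1):n] - e$t_onset_s[i]
      j <- which(dt > 0 & dt <= config$window_s) + i
      j <- j[e$behaviour[j] %in% cols]
      if (!length(j)) next
      if (config$pairing == "next_event") j <- j[1]
      for (k in j) counts[a, e$behaviour[k]] <- counts[a, e$behaviour[k]] + 1L
    }
  }

  out <- list(counts = counts, row_margins = rowSums(counts),
              col_margins = colSums(counts), n_chases = length(ids),
              n_events = nrow(ev), config = config,
              group = paste0(paste(species %||% "all-species", collapse = "+"), " x ",
                             paste(predator_type %||% "all-predators", collapse = "+")))
  class(out) <- "transition_matrix"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.transition_matrix <- function(x, ...) {
  cat("behavioural transition matrix —", x$group, "\n")
  cat(sprintf("%d chases, %d eligible events, %d transitions (%s pairing, window %g s)\n",
              x$n_chases, x$n_events, sum(x$counts), x$config$pairing,
              x$config$window_s))
  print(x$counts, ...)
  invisible(x)
}

#' Row-normalised transition proportions
#'
#' Converts a transition matrix to row-stochastic form: each row with a
#' nonzero margin is divided by its margin; all-zero rows stay zero and are
#' flagged in the `zero_rows` attribute.
#'
#' @param tm a [build_transitions()] object.
#' @return a numeric matrix with the same dimnames; attribute `zero_rows`
#'   names the antecedents with no outgoing transitions.
#' @export
transition_proportions <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  p <- tm$counts / ifelse(tm$row_margins == 0, 1, tm$row_margins)
  attr(p, "zero_rows") <- names(which(tm$row_margins == 0))
  p
}

#' Flatten a transition matrix to an edge list
#'
#' One edge per nonzero cell, suitable for graph rendering of the
#' transition structure. If a permutation-test result is supplied its
#' per-cell statistics are attached to each edge.
#'
#' @param tm a [build_transitions()] object.
#' @param results optionally, a [permutation_test()] result on the same
#'   matrix (labels must match).
#' @param alpha significance level used for the `significant` flag when
#'   `results` is given.
#' @return data frame with columns `from`, `to`, `count` and, when results
#'   are attached, `null_mean`, `null_sd`, `p_two_tailed`, `direction`,
#'   `adjusted_p`, `significant`.
#' @export
transition_edge_list <- function(tm, results = NULL, alpha = 0.05) {
  stopifnot(inherits(tm, "transition_matrix"))
  nz <- which(tm$counts > 0, arr.ind = TRUE)
  out <- data.frame(from = rownames(tm$counts)[nz[, 1]],
                    to = colnames(tm$counts)[nz[, 2]],
                    count = tm$counts[nz], stringsAsFactors = FALSE)
  if (!is.null(results)) {
    stopifnot(inherits(results, "transition_test"))
    if (!identical(dimnames(results$observed), dimnames(tm$counts))) {
      stop("labels of the test results do not match the transition matrix")
    }
    p <- if (results$correction == "none") results$p_two_tailed else results$adjusted_p
    out$null_mean <- results$null_mean[nz]
    out$null_sd <- results$null_sd[nz]
    out$p_two_tailed <- results$p_two_tailed[nz]
    out$adjusted_p <- if (is.null(results$adjusted_p)) NA_real_ else results$adjusted_p[nz]
    out$direction <- results$direction[nz]
    out$significant <- p[nz] <= alpha
  }
  rownames(out) <- NULL
  out[order(out$from, out$to), , drop = FALSE]
}
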