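#' Per-chase collective-escape counts and rates
#'
#' Counts flock-actor events (collective escape patterns) per chase and
#' converts them to a per-minute rate, the descriptive unit used throughout
#' the analyses. Chases without any escape event appear with count 0.
#'
#' @param events event data frame (see [read_events()]).
#' @param chases chase data frame (see [read_chases()]).
#' @return data frame with one row per chase: `chase_id`, `n_escapes`,
#'   `rate_per_min` (`n_escapes / (duration_s / 60)`).
#' @export
escape_counts_per_chase <- function(events, chases) {
  stop_unless_valid(events, chases)
  esc <- events[events$actor == "flock", , drop = FALSE]
  n <- vapply(chases$chase_id, function(id) sum(esc$chase_id == id), integer(1))
  data.frame(chase_id = chases$chase_id, n_escapes = as.integer(n),
             rate_per_min = as.numeric(n) / (chases$duration_s / 60),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarise a chase dataset by species and predator type
#'
#' Per (predator type x species) cell: number of chases, mean chase duration
#' with its standard error, and the total number of collective escape events
#' (flock-actor events only). A `total` row per predator type gives the
#' summed chase and escape counts and the chase-count-weighted overall mean
#' duration. The standard error of a single chase's duration is reported as
#' `NA`, not 0.
#'
#' @inheritParams escape_counts_per_chase
#' @return data frame of class `dataset_summary` with columns
#'   `predator_type`, `species` (or `"total"`), `n_chases`,
#'   `mean_duration_s`, `se_duration_s`, `n_escape_events`.
#' @export
summarize_dataset <- function(events, chases) {
  stop_unless_valid(events, chases)
  counts <- escape_counts_per_chase(events, chases)
  chases$n_escapes <- counts$n_escapes[match(chases$chase_id, counts$chase_id)]

  se <- function(x) if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  rows <- list()
  for (pt in intersect(predator_levels(), unique(chases$predator_type))) {
    sub <- chases[chases$predator_type == pt, , drop = FALSE]
    for (sp in intersect(species_levels(), unique(sub$species))) {
      cell <- sub[sub$species == sp, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        predator_type = pt, species = sp, n_chases = nrow(cell),
        mean_duration_s = mean(cell$duration_s),
        se_duration_s = se(cell$duration_s),
        n_escape_events = sum(cell$n_escapes), stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      predator_type = pt, species = "total", n_chases = nrow(sub),
      mean_duration_s = mean(sub$duration_s),
      se_duration_s = se(sub$duration_s),
      n_escape_events = sum(sub$n_escapes), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dataset_summary", "data.frame")
  out
}

#' @export
print.dataset_summary <- function(x, digits = 1, ...) {
  cat("chase dataset summary (escape events are flock-actor events)\n")
  y <- x
  y$mean_duration_s <- round(y$mean_duration_s, digits)
  y$se_duration_s <- round(y$se_duration_s, digits)
  print.data.frame(y, ...)
  invisible(x)
}

#' Composition of collective-escape types per group
#'
#' For each chase with at least one escape event, the percentage share of
#' each escape pattern is computed within the chase (shares sum to 100);
#' chases are then averaged with equal weight within each group, so a long
#' chase with many events counts no more than a short one. Chases without
#' escape events are excluded and listed in the `excluded_chases` attribute.
#'
#' @inheritParams escape_counts_per_chase
#' @param grouping character vector of chase covariate columns to group by
#'   (e.g. `"species"` or `c("species", "predator_type")`).
#' @return data frame with one row per group x escape pattern: the grouping
#'   columns, `behaviour`, `mean_pct`, `se_pct` and `n_chases`. Groups with
#'   zero usable chases are dropped with a warning.
#' @export
escape_type_composition <- function(events, chases, grouping = "species") {
  stop_unless_valid(events, chases)
  miss <- setdiff(grouping, names(chases))
  if (length(miss)) stop("unknown grouping column(s): ", paste(miss, collapse = ", "))
  esc <- events[events$actor == "flock", , drop = FALSE]

  counts <- escape_counts_per_chase(events, chases)
  zero <- counts$chase_id[counts$n_escapes == 0]
  if (length(zero)) {
    warning(length(zero), " chase(s) without escape events excluded from composition")
  }
  use <- chases[!chases$chase_id %in% zero, , drop = FALSE]
  pats <- escape_patterns()

  # per-chase percentage vector over the nine patterns
  shares <- t(vapply(use$chase_id, function(id) {
    b <- esc$behaviour[esc$chase_id == id]
    100 * tabulate(factor(b, levels = pats), nbins = length(pats)) / length(b)
  }, numeric(length(pats))))
  colnames(shares) <- pats

  key <- interaction(use[, grouping, drop = FALSE], drop = TRUE, sep = "\r")
  out <- lapply(levels(key), function(k) {
    i <- which(key == k)
    grp <- use[i[1], grouping, drop = FALSE]
    m <- shares[i, , drop = FALSE]
    data.frame(grp, behaviour = pats, mean_pct = colMeans(m),
               se_pct = if (length(i) < 2) NA_real_ else
                 apply(m, 2, sd) / sqrt(length(i)),
               n_chases = length(i), row.names = NULL, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "excluded_chases") <- zero
  res
}
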