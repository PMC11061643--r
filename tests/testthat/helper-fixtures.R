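# In-code fixtures shared across the suite. Everything is generated
# programmatically; no data files.

toy_chase <- function(chase_id = "c1", species = "starlings",
                      predator_type = "robotfalcon", duration_s = 60,
                      chasing_intensity = 0.5, altitude_class = "high",
                      multiple_species = FALSE, operator_id = "op1",
                      flock_size = NA_integer_) {
  data.frame(chase_id = chase_id, species = species,
             predator_type = predator_type, duration_s = duration_s,
             chasing_intensity = chasing_intensity,
             altitude_class = altitude_class,
             multiple_species = multiple_species, operator_id = operator_id,
             flock_size = flock_size, stringsAsFactors = FALSE)
}

toy_events <- function(chase_id, t, behaviour) {
  data.frame(chase_id = chase_id, t_onset_s = t,
             actor = ifelse(behaviour %in% predator_acts(), "predator", "flock"),
             behaviour = behaviour, stringsAsFactors = FALSE)
}

# chase metadata + events reproducing the robotic-falcon arm of the field
# campaign's summary table: per-species chase counts, mean durations and
# escape-event totals (every chase in a cell gets the cell's mean duration,
# so the weighted overall mean is exact)
table2_fixture <- function() {
  cells <- data.frame(
    species = c("corvids", "gulls", "lapwings", "starlings",
                "corvids", "gulls", "starlings"),
    predator_type = c(rep("robotfalcon", 4), rep("drone", 3)),
    n = c(15L, 20L, 8L, 23L, 19L, 19L, 18L),
    dur = c(58.8, 67.6, 70.4, 80.2, 102.3, 195.8, 95.2),
    escapes = c(113L, 150L, 76L, 368L, 89L, 86L, 146L),
    stringsAsFactors = FALSE)
  chases <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    with(cells[i, ], toy_chase(
      chase_id = sprintf("%s_%s_%02d", substr(species, 1, 3), substr(predator_type, 1, 2), seq_len(n)),
      species = species, predator_type = predator_type, duration_s = dur,
      altitude_class = "unknown"))
  }))
  # spread each cell's escape total over its chases (exact partition)
  events <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    ids <- chases$chase_id[chases$species == cell$species &
                           chases$predator_type == cell$predator_type]
    per <- rep(cell$escapes %/% cell$n, cell$n)
    per[seq_len(cell$escapes %% cell$n)] <- per[seq_len(cell$escapes %% cell$n)] + 1L
    do.call(rbind, lapply(seq_along(ids), function(k) {
      if (per[k] == 0) return(NULL)
      toy_events(ids[k], seq(0.5, cell$dur - 0.5, length.out = per[k]),
                 rep("collective_turn", per[k]))
    }))
  }))
  list(chases = chases, events = events)
}

# normalise coefficient names so that simulator ground-truth names and
# model-fit names agree regardless of interaction component order
canonical_terms <- function(x) {
  vapply(strsplit(x, ":", fixed = TRUE),
         function(p) paste(sort(p), collapse = ":"), character(1))
}

# balanced 4 species x 2 predator design used by the recovery simulations
balanced_design <- function(n_per_cell = 50L) {
  data.frame(species = rep(c("corvids", "gulls", "lapwings", "starlings"), 2),
             predator_type = rep(c("robotfalcon", "drone"), each = 4),
             n_chases = n_per_cell, stringsAsFactors = FALSE)
}

# independent Poisson MLE oracle: direct maximisation of the log-likelihood
# over the design matrix, no glm machinery
poisson_mle_oracle <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - exp(eta))
  }
  gr <- function(b) {
    mu <- exp(drop(X %*% b))
    -drop(crossprod(X, y - mu))
  }
  opt <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  setNames(opt$par, colnames(X))
}
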