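#' Two-tailed permutation test of transition counts
#'
#' Tests, cell by cell, whether observed behavioural transitions occur more
#' or less often than expected by chance, against a null ensemble of random
#' tables with the observed matrix's own row and column margins (see
#' [patefield_sample()]). With `G` the number of null tables whose cell is
#' at least the observed count and `L` the number at most the observed
#' count, the two-tailed Monte-Carlo p-value is
#' `min(1, 2 * (min(G, L) + 1) / (n_null + 1))`; the add-one form keeps
#' p strictly positive. Direction is `over` when the observed count exceeds
#' the null mean, `under` when below, `none` when equal.
#'
#' @param tm a [build_transitions()] object.
#' @param ensemble optionally a pre-drawn [patefield_sample()] ensemble; its
#'   margins must equal the matrix's margins. If `NULL`, `n_null` tables are
#'   drawn.
#' @param n_null number of null tables to draw when `ensemble` is `NULL`
#'   (default 100000, the conventional ensemble size for this test).
#' @param seed optional integer seed used when drawing the ensemble.
#' @param alpha significance level recorded in the result (default 0.05).
#' @param correction multiplicity correction across the cells of the
#'   matrix: `"none"` (default) or `"benjamini_hochberg"`.
#' @return an object of class `transition_test`: a list with matrices
#'   `observed`, `null_mean`, `null_sd`, `p_two_tailed`, `direction`,
#'   `adjusted_p` (NULL when `correction = "none"`), plus `n_null`, `seed`,
#'   `alpha`, `correction` and the `group`/`config` carried over from `tm`.
#' @export
permutation_test <- function(tm, ensemble = NULL, n_null = 1e5, seed = NULL,
                             alpha = 0.05,
                             correction = c("none", "benjamini_hochberg")) {
  stopifnot(inherits(tm, "transition_matrix"))
  correction <- match.arg(correction)
  if (is.null(ensemble)) {
    ensemble <- patefield_sample(tm$row_margins, tm$col_margins, n_null, seed)
  } else {
    stopifnot(inherits(ensemble, "patefield_ensemble"))
    if (!identical(as.integer(ensemble$row_margins), as.integer(unname(tm$row_margins))) ||
        !identical(as.integer(ensemble$col_margins), as.integer(unname(tm$col_margins)))) {
      stop("ensemble margins differ from the observed matrix margins; ",
           "the null must be conditioned on the observed margins")
    }
  }
  n <- ensemble$n_null
  if (n < 1) stop("ensemble is empty; draw at least one null table")

  obs <- tm$counts
  ncell <- length(obs)
  flat <- matrix(ensemble$matrices, nrow = ncell)
  ge <- rowSums(flat >= as.vector(obs))
  le <- rowSums(flat <= as.vector(obs))
  p <- pmin(1, 2 * (pmin(ge, le) + 1) / (n + 1))
  mu <- rowMeans(flat)
  sdv <- apply(flat, 1, sd)

  shape <- function(v) matrix(v, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  dir <- ifelse(as.vector(obs) > mu, "over", ifelse(as.vector(obs) < mu, "under", "none"))
  adj <- if (correction == "benjamini_hochberg") shape(p.adjust(p, "BH")) else NULL

  structure(list(observed = obs, null_mean = shape(mu), null_sd = shape(sdv),
                 p_two_tailed = shape(p), direction = shape(dir),
                 adjusted_p = adj, n_null = n, seed = ensemble$seed,
                 alpha = alpha, correction = correction,
                 group = tm$group, config = tm$config),
            class = "transition_test")
}

#' @export
print.transition_test <- function(x, ...) {
  cat("permutation test of transition counts —", x$group, "\n")
  cat(sprintf("null: %d fixed-margin tables; correction: %s; alpha = %g\n",
              x$n_null, x$correction, x$alpha))
  sig <- significant_transitions(x)
  if (nrow(sig) == 0) {
    cat("no transitions deviate from the fixed-margin null at alpha\n")
  } else {
    cat(nrow(sig), "transition(s) deviate from the null:\n")
    print.data.frame(sig, digits = 4)
  }
  invisible(x)
}

#' Significant transitions from a permutation test
#'
#' Filters the per-cell results of [permutation_test()] to the transitions
#' whose (adjusted, if a correction was applied) p-value is at or below
#' `alpha`, annotated with the direction of deviation.
#'
#' @param result a [permutation_test()] result.
#' @param alpha significance level; defaults to the level stored in the
#'   result.
#' @param correction override the correction stored in the result
#'   (`"none"` or `"benjamini_hochberg"`).
#' @return data frame with columns `from`, `to`, `observed`, `null_mean`,
#'   `null_sd`, `p_two_tailed`, `adjusted_p`, `direction`, sorted by
#'   p-value.
#' @export
significant_transitions <- function(result, alpha = result$alpha,
                                    correction = result$correction) {
  stopifnot(inherits(result, "transition_test"))
  correction <- match.arg(correction, c("none", "benjamini_hochberg"))
  adj <- switch(correction,
                none = NULL,
                benjamini_hochberg = result$adjusted_p %||%
                  matrix(p.adjust(result$p_two_tailed, "BH"),
                         nrow(result$observed), dimnames = dimnames(result$observed)))
  crit <- adj %||% result$p_two_tailed
  idx <- which(crit <= alpha, arr.ind = TRUE)
  out <- data.frame(
    from = rownames(result$observed)[idx[, 1]],
    to = colnames(result$observed)[idx[, 2]],
    observed = result$observed[idx],
    null_mean = result$null_mean[idx],
    null_sd = result$null_sd[idx],
    p_two_tailed = result$p_two_tailed[idx],
    adjusted_p = if (is.null(adj)) rep(NA_real_, nrow(idx)) else adj[idx],
    direction = result$direction[idx],
    stringsAsFactors = FALSE)
  out <- out[order(out$p_two_tailed), , drop = FALSE]
  rownames(out) <- NULL
  out
}
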