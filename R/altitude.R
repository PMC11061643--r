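#' Bin collective-escape events per 20 s of chase time
#'
#' Partitions each chase with a known approach-altitude class into
#' consecutive bins of `bin_s` seconds after flight initiation (bin b
#' covers `[(b-1)*bin_s, b*bin_s)`), counting the flock-actor events per
#' bin. The final partial bin is retained with its actual width recorded;
#' an event exactly at the chase's end falls into that last bin. Chases
#' whose altitude class is `unknown` are excluded.
#'
#' @inheritParams escape_counts_per_chase
#' @param bin_s bin width in seconds (default 20).
#' @return data frame with one row per chase x bin: `chase_id`, `bin`
#'   (1-based index), `t_start_s`, `width_s`, `count`, `altitude_class`.
#'   Zero-count bins are included, so per-chase counts partition the
#'   chase's escape events.
#' @export
altitude_binned_counts <- function(events, chases, bin_s = 20) {
  stop_unless_valid(events, chases)
  if (bin_s <= 0) stop("bin_s must be positive")
  use <- chases[chases$altitude_class %in% c("high", "low"), , drop = FALSE]
  esc <- events[events$actor == "flock", , drop = FALSE]
  rows <- lapply(seq_len(nrow(use)), function(i) {
    ch <- use[i, ]
    n_bins <- max(1L, ceiling(ch$duration_s / bin_s))
    t <- esc$t_onset_s[esc$chase_id == ch$chase_id]
    bin <- pmin(floor(t / bin_s) + 1L, n_bins)  # t == duration joins the last bin
    b <- seq_len(n_bins)
    data.frame(chase_id = ch$chase_id, bin = b,
               t_start_s = (b - 1) * bin_s,
               width_s = pmin(bin_s, ch$duration_s - (b - 1) * bin_s),
               count = tabulate(bin, nbins = n_bins),
               altitude_class = ch$altitude_class,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chase_id = character(), bin = integer(), t_start_s = numeric(),
               width_s = numeric(), count = integer(),
               altitude_class = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Altitude effect on the binned escape rate
#'
#' Poisson mixed model of per-bin escape counts on approach-altitude class
#' (high, above 50 m, versus low) and bin index, with a chase-level random
#' intercept and a `log(width_s)` offset so that partial final bins
#' contribute through their true exposure. Returns the Type-II Wald test of
#' the altitude term.
#'
#' @param binned output of [altitude_binned_counts()].
#' @return a list of class `altitude_fit`: `fit` (an `escape_rate_fit`-like
#'   wrapper of the underlying `glmerMod`), `altitude_test` (data frame
#'   `chisq`, `df`, `p`), `rate_ratio` (fitted high/low rate ratio).
#' @export
fit_altitude_model <- function(binned) {
  cls <- unique(binned$altitude_class)
  if (length(cls) < 2) {
    stop("need both altitude classes; data contain only: ",
         paste(cls, collapse = ", "))
  }
  d <- binned
  d$altitude_class <- factor(d$altitude_class, levels = c("low", "high"))
  d$chase_id <- factor(d$chase_id)
  fit <- withCallingHandlers(
    lme4::glmer(count ~ altitude_class + bin + offset(log(width_s)) + (1 | chase_id),
                data = d, family = stats::poisson(),
                control = lme4::glmerControl(optimizer = "nloptwrap", calc.derivs = FALSE)),
    warning = function(w) invokeRestart("muffleWarning"))
  a <- car::Anova(fit, type = "II")
  at <- data.frame(chisq = a["altitude_class", "Chisq"],
                   df = a["altitude_class", "Df"],
                   p = a["altitude_class", "Pr(>Chisq)"])
  co <- summary(fit)$coefficients
  structure(list(model = fit, altitude_test = at,
                 rate_ratio = exp(co["altitude_classhigh", "Estimate"]),
                 coefficients = data.frame(term = rownames(co),
                                           estimate = co[, 1], se = co[, 2],
                                           row.names = NULL)),
            class = "altitude_fit")
}

#' @export
print.altitude_fit <- function(x, digits = 4, ...) {
  cat("altitude model: Poisson bin counts ~ altitude_class + bin + (1 | chase),",
      "offset log(bin width)\n")
  print.data.frame(within(x$coefficients, {
    estimate <- signif(estimate, digits); se <- signif(se, digits)
  }), row.names = FALSE)
  cat(sprintf("high/low rate ratio: %.3f; altitude Wald chi-sq %.3f (df %d), p = %.4g\n",
              x$rate_ratio, x$altitude_test$chisq, x$altitude_test$df,
              x$altitude_test$p))
  invisible(x)
}
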