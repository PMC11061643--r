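#' Estimated marginal means of a factor on the response scale
#'
#' Model-derived factor-level means on a balanced reference grid: the other
#' factors are weighted equally, covariates are held at their observed
#' means, and the link-scale means are back-transformed to the response
#' scale (expected escapes per chase for the count models), with standard
#' errors by the delta method. Computed via the `emmeans` package.
#'
#' @param fit an [fit_poisson_glmm()] fit.
#' @param factor name of a factor in the model (default `"species"`).
#' @return an object of class `escape_emm`: a list with `table` (data frame
#'   `level`, `emmean`, `se` on the response scale), `factor` and `grid`
#'   (the underlying `emmGrid`, reusable for contrasts).
#' @export
estimated_marginal_means <- function(fit, factor = "species") {
  stopifnot(inherits(fit, "escape_rate_fit"))
  if (!factor %in% fit$spec$fixed_effects) {
    stop("factor '", factor, "' is not in the fitted model")
  }
  grid <- emmeans::emmeans(fit$model, specs = factor, data = fit$data)
  resp <- as.data.frame(emmeans::regrid(grid, transform = "response"))
  out <- data.frame(level = as.character(resp[[1]]),
                    emmean = resp[["rate"]] %||% resp[["response"]] %||% resp[["emmean"]],
                    se = resp[["SE"]], stringsAsFactors = FALSE)
  structure(list(table = out, factor = factor, grid = grid),
            class = "escape_emm")
}

#' @export
print.escape_emm <- function(x, digits = 4, ...) {
  cat("estimated marginal means of", x$factor,
      "(response scale; balanced grid, covariates at means)\n")
  print.data.frame(within(x$table, {
    emmean <- signif(emmean, digits); se <- signif(se, digits)
  }), row.names = FALSE)
  invisible(x)
}

#' Tukey-adjusted pairwise contrasts between factor levels
#'
#' All pairwise differences between the factor levels of an
#' [estimated_marginal_means()] result, on the link scale, with z-ratios
#' and family-wise p-values adjusted by the Tukey (studentized-range)
#' method for the number of means compared.
#'
#' @param emm an [estimated_marginal_means()] result.
#' @return data frame with columns `contrast`, `estimate` (link-scale
#'   difference), `se`, `z_ratio`, `p_adjusted`.
#' @export
pairwise_contrasts <- function(emm) {
  stopifnot(inherits(emm, "escape_emm"))
  ct <- as.data.frame(emmeans::contrast(emm$grid, method = "pairwise",
                                        adjust = "tukey"))
  zcol <- if ("z.ratio" %in% names(ct)) "z.ratio" else "t.ratio"
  data.frame(contrast = as.character(ct$contrast), estimate = ct$estimate,
             se = ct$SE, z_ratio = ct[[zcol]], p_adjusted = ct$p.value,
             stringsAsFactors = FALSE)
}

#' Pooled two-sample comparison of per-chase escape counts
#'
#' Student's pooled-variance two-sample t-test of per-chase collective
#' escape counts between two chase groups (robotic-falcon versus
#' wild-falcon chases on starlings, in the motivating analysis); degrees of
#' freedom are `n_a + n_b - 2`. A Welch variant is available.
#'
#' @param counts_a,counts_b numeric vectors of per-chase escape counts,
#'   each of length at least 2.
#' @param welch use the Welch (unequal-variance) variant instead of the
#'   pooled test.
#' @return an object of class `htest` (from [stats::t.test()]): `statistic`
#'   is t, `parameter` the degrees of freedom, `p.value` the two-sided p.
#' @export
compare_robot_vs_falcon <- function(counts_a, counts_b, welch = FALSE) {
  if (length(counts_a) < 2 || length(counts_b) < 2) {
    stop("each sample needs at least 2 chases")
  }
  t.test(counts_a, counts_b, var.equal = !welch)
}
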