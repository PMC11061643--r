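#' Specification of the per-chase escape-count model
#'
#' Describes a Poisson log-link mixed model for the number of collective
#' escapes per chase. The full default specification has fixed effects for
#' species, predator type, chasing intensity, chase duration and the
#' multi-species flag; the three two-way interactions of species x chasing
#' intensity, species x predator type and predator type x chasing
#' intensity; and random intercepts for operator and for chase id. The
#' chase-id intercept is observation-level (one count per chase) and
#' doubles as a device absorbing extra-Poisson variation. Reference levels
#' are `corvids` (species) and `drone` (predator type); covariates enter on
#' their natural scale (seconds, proportion).
#'
#' @param fixed_effects character vector of main-effect terms.
#' @param interactions character vector of `a:b` interaction terms; each
#'   must be formed from included main effects.
#' @param random_intercepts character vector of grouping columns receiving
#'   random intercepts (default `chase_id` and `operator_id`; empty for a
#'   plain Poisson GLM).
#' @param offset_duration if `TRUE`, `log(duration_s)` enters as an offset
#'   instead of duration as a covariate (sensitivity variant; not the
#'   default).
#' @return a list of class `rate_model_spec`.
#' @export
rate_model_spec <- function(fixed_effects = c("species", "predator_type",
                                              "chasing_intensity", "duration_s",
                                              "multiple_species"),
                            interactions = c("species:chasing_intensity",
                                             "species:predator_type",
                                             "predator_type:chasing_intensity"),
                            random_intercepts = c("chase_id", "operator_id"),
                            offset_duration = FALSE) {
  offset_duration <- isTRUE(offset_duration)
  if (offset_duration) fixed_effects <- setdiff(fixed_effects, "duration_s")
  for (ia in interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% fixed_effects)) {
      stop("interaction ", ia, " uses a term not in fixed_effects")
    }
  }
  structure(list(fixed_effects = fixed_effects, interactions = interactions,
                 random_intercepts = random_intercepts,
                 offset_duration = offset_duration,
                 reference_levels = c(species = "corvids", predator_type = "drone")),
            class = "rate_model_spec")
}

#' @export
print.rate_model_spec <- function(x, ...) {
  cat("Poisson escape-count model specification\n")
  cat("  fixed effects:", paste(x$fixed_effects, collapse = ", "), "\n")
  cat("  interactions: ", if (length(x$interactions))
    paste(x$interactions, collapse = ", ") else "(none)", "\n")
  cat("  random intercepts:", if (length(x$random_intercepts))
    paste(x$random_intercepts, collapse = ", ") else "(none)", "\n")
  if (x$offset_duration) cat("  offset: log(duration_s)\n")
  invisible(x)
}

spec_formula <- function(spec, response = "n_escapes") {
  rhs <- c(spec$fixed_effects, spec$interactions)
  if (length(rhs) == 0) rhs <- "1"
  re <- sprintf("(1 | %s)", spec$random_intercepts)
  off <- if (spec$offset_duration) "offset(log(duration_s))" else NULL
  as.formula(paste(response, "~", paste(c(rhs, off, re), collapse = " + ")))
}

#' Assemble the per-chase count table for rate modelling
#'
#' Merges per-chase escape counts with the chase covariates and applies the
#' canonical factor codings (species with reference `corvids`, predator
#' type with reference `drone`).
#'
#' @inheritParams escape_counts_per_chase
#' @return data frame with one row per chase: `chase_id`, `n_escapes`,
#'   `rate_per_min` and all chase covariates, factors releveled.
#' @export
escape_count_table <- function(events, chases) {
  counts <- escape_counts_per_chase(events, chases)
  d <- merge(counts, chases, by = "chase_id", sort = FALSE)
  d$species <- factor(d$species, levels = species_levels())
  d$predator_type <- factor(d$predator_type, levels = predator_levels())
  d$species <- droplevels_keep_ref(d$species)
  d$predator_type <- droplevels_keep_ref(d$predator_type)
  d
}

# drop canonical levels entirely absent from the data (e.g. no falcon
# chases) while keeping the declared ordering
droplevels_keep_ref <- function(f) {
  present <- levels(f)[levels(f) %in% unique(as.character(f))]
  factor(as.character(f), levels = present)
}

#' Fit the Poisson mixed model of per-chase escape counts
#'
#' Maximum-likelihood fit of a [rate_model_spec()] to a per-chase count
#' table, with random intercepts integrated by the Laplace approximation
#' (via `lme4::glmer`). With no random intercepts in the specification the
#' model is the ordinary Poisson regression MLE (via `stats::glm`), which
#' is also the limit of the mixed fit with both random-effect variances
#' fixed at zero.
#'
#' @param data per-chase count table (see [escape_count_table()]), or any
#'   data frame holding the response and the model columns.
#' @param spec a [rate_model_spec()].
#' @param response name of the count response column.
#' @return an object of class `escape_rate_fit`: a list with `model` (the
#'   underlying `glmerMod`/`glm` fit), `spec`, `coefficients` (data frame
#'   term/estimate/se), `re_variances` (named numeric), `loglik`,
#'   `converged`, `n_obs`, `response`, `data`.
#' @export
fit_poisson_glmm <- function(data, spec = rate_model_spec(),
                             response = "n_escapes") {
  stopifnot(inherits(spec, "rate_model_spec"))
  y <- data[[response]]
  if (is.null(y)) stop("response column '", response, "' not found")
  if (any(is.na(y)) || any(y < 0) || any(y != round(y))) {
    stop("response must be non-negative integer counts")
  }
  for (v in intersect(c("species", "predator_type"), spec$fixed_effects)) {
    if (!is.factor(data[[v]])) data[[v]] <- factor(data[[v]])
    empty <- setdiff(levels(data[[v]]), unique(as.character(data[[v]])))
    if (length(empty)) {
      stop("factor ", v, " has level(s) with no observations: ",
           paste(empty, collapse = ", "))
    }
  }
  # rank check on the fixed-effects design
  fx <- c(spec$fixed_effects, spec$interactions)
  fml_fixed <- as.formula(paste("~", if (length(fx)) paste(fx, collapse = " + ") else "1"))
  X <- model.matrix(fml_fixed, data)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effects design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }

  fml <- spec_formula(spec, response)
  if (length(spec$random_intercepts) == 0) {
    fit <- stats::glm(fml, data = data, family = stats::poisson())
    conv <- fit$converged
    co <- summary(fit)$coefficients
    revar <- setNames(numeric(0), character(0))
    ll <- as.numeric(logLik(fit))
  } else {
    for (g in spec$random_intercepts) {
      if (is.null(data[[g]])) stop("random-intercept column '", g, "' not found")
      data[[g]] <- factor(data[[g]])
    }
    fit <- withCallingHandlers(
      lme4::glmer(fml, data = data, family = stats::poisson(),
                  control = lme4::glmerControl(optimizer = "nloptwrap", calc.derivs = FALSE)),
      warning = function(w) invokeRestart("muffleWarning"))
    msgs <- fit@optinfo$conv$lme4$messages
    conv <- fit@optinfo$conv$opt == 0 &&
      (is.null(msgs) || !any(grepl("failed to converge", unlist(msgs))))
    co <- summary(fit)$coefficients
    vc <- lme4::VarCorr(fit)
    revar <- vapply(vc, function(m) m[1, 1], numeric(1))
    ll <- as.numeric(logLik(fit))
  }
  coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = fit, spec = spec, coefficients = coefs,
                 re_variances = revar, loglik = ll, converged = conv,
                 n_obs = nrow(data), response = response, data = data),
            class = "escape_rate_fit")
}

#' @export
print.escape_rate_fit <- function(x, digits = 4, ...) {
  cat("Poisson escape-count model (", x$n_obs, " chases, log link)\n", sep = "")
  if (!x$converged) cat("** WARNING: fit did not converge **\n")
  co <- x$coefficients
  co$estimate <- signif(co$estimate, digits)
  co$se <- signif(co$se, digits)
  print.data.frame(co, row.names = FALSE)
  if (length(x$re_variances)) {
    cat("random-intercept variances:\n")
    print(signif(x$re_variances, digits))
  }
  cat("log-likelihood:", format(x$loglik, digits = digits + 2), "\n")
  invisible(x)
}

#' @export
summary.escape_rate_fit <- function(object, ...) {
  print(object, ...)
  cat("\nType-II Wald term tests:\n")
  print(term_tests(object), digits = 4)
  invisible(object)
}

#' @export
coef.escape_rate_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Type-II Wald chi-squared tests per model term
#'
#' Tests each fixed-effect term of a fitted escape-count model jointly
#' (multi-level factors on all their coefficients at once) with Type-II
#' Wald chi-squared statistics, via `car::Anova`.
#'
#' @param fit an [fit_poisson_glmm()] fit.
#' @return data frame with columns `term`, `chisq`, `df`, `p`.
#' @export
term_tests <- function(fit) {
  stopifnot(inherits(fit, "escape_rate_fit"))
  if (!fit$converged) warning("term tests on a non-converged fit")
  a <- if (inherits(fit$model, "glm")) {
    car::Anova(fit$model, type = "II", test.statistic = "Wald")
  } else {
    car::Anova(fit$model, type = "II")
  }
  chisq_col <- grep("Chisq", names(a))[1]
  p_col <- grep("^Pr", names(a))[1]
  out <- data.frame(term = rownames(a), chisq = a[[chisq_col]],
                    df = a[["Df"]], p = a[[p_col]],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[out$term != "(Intercept)", , drop = FALSE]
}

#' Overdispersion check for the Poisson count model
#'
#' Computes the Pearson dispersion ratio (Pearson chi-squared over residual
#' degrees of freedom) of a fixed-effects-only Poisson fit, with an upper
#' chi-squared tail test of the hypothesis that the data are not
#' overdispersed. Requires a fit without the observation-level random
#' intercept, which would itself absorb the overdispersion being tested.
#'
#' @param fit an [fit_poisson_glmm()] fit with no random intercepts.
#' @param alpha significance level for the verdict (default 0.05).
#' @return a list of class `dispersion_check`: `ratio`, `pearson_chisq`,
#'   `df`, `p`, `overdispersed` (logical verdict).
#' @export
check_overdispersion <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "escape_rate_fit"))
  if (length(fit$spec$random_intercepts)) {
    stop("overdispersion check requires a fixed-effects-only fit ",
         "(no observation-level random intercept)")
  }
  rdf <- df.residual(fit$model)
  if (rdf <= 0) stop("zero residual degrees of freedom; cannot assess dispersion")
  pearson <- sum(stats::residuals(fit$model, type = "pearson")^2)
  p <- pchisq(pearson, df = rdf, lower.tail = FALSE)
  structure(list(ratio = pearson / rdf, pearson_chisq = pearson, df = rdf,
                 p = p, overdispersed = p < alpha),
            class = "dispersion_check")
}

#' @export
print.dispersion_check <- function(x, ...) {
  cat(sprintf("dispersion ratio %.3f (Pearson chi-sq %.1f on %d df), p = %.4g -> %s\n",
              x$ratio, x$pearson_chisq, x$df, x$p,
              if (x$overdispersed) "overdispersed" else "not overdispersed"))
  invisible(x)
}

#' Prune non-significant interactions to the best model
#'
#' Applies the Type-II Wald tests to the full model's interactions and
#' drops, in a single pass, every interaction with p at or above `alpha`;
#' main effects are never removed. The pruned specification is refitted and
#' returned with an audit trail of removals.
#'
#' @param fit a full-model [fit_poisson_glmm()] fit.
#' @param alpha removal threshold (default 0.05).
#' @return a list of class `model_pruning`: `spec` (the retained
#'   specification), `fit` (the refit, or the input fit when nothing was
#'   dropped), `dropped` (data frame term/p of removals), `retained`
#'   (character vector of retained interactions).
#' @export
prune_to_best_model <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "escape_rate_fit"))
  tt <- term_tests(fit)
  ints <- fit$spec$interactions
  sel <- select_interactions(setNames(tt$p, tt$term), ints, alpha)
  spec2 <- fit$spec
  spec2$interactions <- sel$retained
  refit <- if (length(sel$dropped$term)) {
    fit_poisson_glmm(fit$data, spec2, fit$response)
  } else fit
  structure(list(spec = spec2, fit = refit, dropped = sel$dropped,
                 retained = sel$retained),
            class = "model_pruning")
}

# the pruning rule on its own: given named per-term p-values, keep the
# interactions with p < alpha
select_interactions <- function(p_values, interactions, alpha = 0.05) {
  p <- p_values[interactions]
  keep <- !is.na(p) & p < alpha
  list(retained = interactions[keep],
       dropped = data.frame(term = interactions[!keep],
                            p = unname(p[!keep]), stringsAsFactors = FALSE))
}

#' @export
print.model_pruning <- function(x, ...) {
  cat("model pruning (single-pass removal of interactions with p >= alpha)\n")
  if (nrow(x$dropped)) {
    cat("dropped:\n"); print.data.frame(x$dropped, row.names = FALSE, digits = 4)
  } else cat("nothing dropped\n")
  cat("retained interactions:", if (length(x$retained))
    paste(x$retained, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
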