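test_that("intercept-only Poisson fit recovers the closed-form MLE log(mean)", {
  d <- data.frame(n_escapes = c(2L, 4L, 6L))
  spec <- rate_model_spec(fixed_effects = character(), interactions = character(),
                          random_intercepts = character())
  fit <- fit_poisson_glmm(d, spec)
  expect_equal(unname(coef(fit)), log(4), tolerance = 1e-8)
})

test_that("without random effects the fit equals an independent Poisson MLE", {
  sim <- simulate_dataset(simulation_config(design = balanced_design(15L),
                                            olre_sd = 0, operator_sd = 0),
                          seed = 17)
  d <- escape_count_table(sim$events, sim$chases)
  spec <- rate_model_spec(random_intercepts = character())
  fit <- fit_poisson_glmm(d, spec)

  X <- model.matrix(~ species + predator_type + chasing_intensity + duration_s +
                      multiple_species + species:chasing_intensity +
                      species:predator_type + predator_type:chasing_intensity, d)
  oracle <- poisson_mle_oracle(X, d$n_escapes)
  expect_equal(coef(fit)[names(oracle)], oracle, tolerance = 1e-6)
})

test_that("model fitting rejects empty factor levels and aliased designs", {
  sim <- simulate_dataset(seed = 23)
  d <- escape_count_table(sim$events, sim$chases)
  # a declared species level with no observations is an error naming it
  d2 <- d[d$species != "lapwings", ]
  d2$species <- factor(as.character(d2$species), levels = species_levels())
  expect_error(fit_poisson_glmm(d2, rate_model_spec(interactions = character())),
               "lapwings")
  # lapwings were never chased by drone: species:predator_type is aliased
  expect_error(fit_poisson_glmm(d, rate_model_spec()), "aliased")
  expect_error(rate_model_spec(fixed_effects = "species",
                               interactions = "species:chasing_intensity"),
               "not in fixed_effects")
})

test_that("a single 2-level factor's Wald chi-squared equals its squared z", {
  set.seed(5)
  d <- data.frame(n_escapes = rpois(80, rep(c(4, 7), each = 40)),
                  predator_type = factor(rep(c("drone", "robotfalcon"), each = 40),
                                         levels = c("drone", "robotfalcon")))
  spec <- rate_model_spec(fixed_effects = "predator_type",
                          interactions = character(),
                          random_intercepts = character())
  fit <- fit_poisson_glmm(d, spec)
  tt <- term_tests(fit)
  z <- with(fit$coefficients, estimate[term == "predator_typerobotfalcon"] /
              se[term == "predator_typerobotfalcon"])
  expect_equal(tt$chisq[tt$term == "predator_type"], z^2, tolerance = 1e-6)
  expect_equal(tt$df[tt$term == "predator_type"], 1)
})

test_that("Wald and likelihood-ratio term tests agree asymptotically", {
  set.seed(8)
  n <- 2000
  d <- data.frame(x = factor(sample(c("a", "b", "c"), n, replace = TRUE)),
                  z = rnorm(n))
  d$n_escapes <- rpois(n, exp(0.5 + 0.3 * (d$x == "b") - 0.2 * (d$x == "c") + 0.1 * d$z))
  spec <- rate_model_spec(fixed_effects = c("x", "z"), interactions = character(),
                          random_intercepts = character())
  fit <- fit_poisson_glmm(d, spec)
  wald <- term_tests(fit)
  lr <- car::Anova(fit$model, type = "II", test.statistic = "LR")
  expect_equal(wald$chisq[wald$term == "x"], lr["x", "LR Chisq"], tolerance = 0.1)
})

test_that("term tests are calibrated under a true null effect", {
  # 200 Poisson datasets with no predator effect: p approximately uniform
  set.seed(14)
  spec <- rate_model_spec(fixed_effects = c("predator_type", "chasing_intensity"),
                          interactions = character(),
                          random_intercepts = character())
  p <- replicate(200, {
    d <- data.frame(
      n_escapes = rpois(60, 5),
      predator_type = factor(rep(c("drone", "robotfalcon"), each = 30)),
      chasing_intensity = runif(60))
    tt <- term_tests(fit_poisson_glmm(d, spec))
    tt$p[tt$term == "predator_type"]
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  # rejection rate near the nominal 5% (99% binomial envelope)
  env <- qbinom(c(0.005, 0.995), 200, 0.05)
  expect_gte(sum(p <= 0.05), env[1])
  expect_lte(sum(p <= 0.05), env[2])
})

test_that("the overdispersion check separates Poisson from overdispersed counts", {
  set.seed(21)
  spec <- rate_model_spec(fixed_effects = "chasing_intensity",
                          interactions = character(),
                          random_intercepts = character())
  # Poisson data: ratio near 1, not overdispersed in most replicates
  verdicts <- replicate(40, {
    d <- data.frame(chasing_intensity = runif(100),
                    n_escapes = rpois(100, 6))
    check_overdispersion(fit_poisson_glmm(d, spec))$overdispersed
  })
  expect_gte(mean(!verdicts), 0.9)

  # negative-binomial data with variance ~5x the mean: flagged
  d_nb <- data.frame(chasing_intensity = runif(200),
                     n_escapes = rnbinom(200, mu = 6, size = 1.5))
  expect_true(check_overdispersion(fit_poisson_glmm(d_nb, spec))$overdispersed)

  # the check refuses a mixed fit and zero residual df
  sim <- simulate_dataset(seed = 3)
  d <- escape_count_table(sim$events, sim$chases)
  mixed <- fit_poisson_glmm(d, rate_model_spec(interactions = character()))
  expect_error(check_overdispersion(mixed), "fixed-effects-only")
  tiny <- data.frame(n_escapes = c(3L, 5L),
                     chasing_intensity = c(0.2, 0.8))
  expect_error(check_overdispersion(fit_poisson_glmm(tiny, spec)),
               "residual degrees of freedom")
})

test_that("interaction pruning drops exactly the terms at or above alpha", {
  # the rule applied to a fitted-model p-value pattern with one interaction
  # significant at 0.033 and the others at 0.103 and 0.319
  p <- c("species" = 1e-4, "predator_type" = 1e-4,
         "species:chasing_intensity" = 0.033,
         "species:predator_type" = 0.103,
         "predator_type:chasing_intensity" = 0.319)
  ints <- c("species:chasing_intensity", "species:predator_type",
            "predator_type:chasing_intensity")
  sel <- flockescape:::select_interactions(p, ints, alpha = 0.05)
  expect_equal(sel$retained, "species:chasing_intensity")
  expect_setequal(sel$dropped$term,
                  c("species:predator_type", "predator_type:chasing_intensity"))

  # all significant -> unchanged; none significant -> main effects only
  all_sig <- setNames(rep(0.001, 3), ints)
  expect_equal(flockescape:::select_interactions(all_sig, ints)$retained, ints)
  none_sig <- setNames(rep(0.5, 3), ints)
  expect_length(flockescape:::select_interactions(none_sig, ints)$retained, 0)

  # end-to-end: generator has zero interaction coefficients, so pruning a
  # fitted full model usually lands on main effects (fixed seed)
  sim <- simulate_dataset(simulation_config(design = balanced_design(25L)),
                          seed = 77)
  d <- escape_count_table(sim$events, sim$chases)
  pr <- prune_to_best_model(fit_poisson_glmm(d))
  expect_s3_class(pr, "model_pruning")
  expect_equal(sort(c(pr$retained, pr$dropped$term)),
               sort(rate_model_spec()$interactions))
  expect_true(all(pr$fit$spec$interactions == pr$retained))
})

test_that("marginal means reduce to group means in the balanced one-factor case", {
  set.seed(30)
  d <- data.frame(species = factor(rep(species_levels(), each = 25),
                                   levels = species_levels()))
  d$n_escapes <- rpois(100, exp(1 + 0.4 * (d$species == "starlings")))
  spec <- rate_model_spec(fixed_effects = "species", interactions = character(),
                          random_intercepts = character())
  fit <- fit_poisson_glmm(d, spec)
  emm <- estimated_marginal_means(fit, "species")
  grp <- tapply(d$n_escapes, d$species, mean)
  expect_equal(emm$table$emmean, as.numeric(grp[emm$table$level]), tolerance = 1e-6)
  expect_error(estimated_marginal_means(fit, "predator_type"), "not in the fitted model")
})

test_that("marginal means are invariant to shifting a covariate", {
  set.seed(31)
  d <- data.frame(species = factor(rep(c("corvids", "gulls"), each = 40)),
                  duration_s = runif(80, 30, 120))
  d$n_escapes <- rpois(80, exp(0.5 + 0.4 * (d$species == "gulls") +
                                 0.004 * d$duration_s))
  spec <- rate_model_spec(fixed_effects = c("species", "duration_s"),
                          interactions = character(),
                          random_intercepts = character())
  e1 <- estimated_marginal_means(fit_poisson_glmm(d, spec), "species")
  d2 <- d; d2$duration_s <- d2$duration_s - 1000  # shift, refit, re-evaluate
  e2 <- estimated_marginal_means(fit_poisson_glmm(d2, spec), "species")
  expect_equal(e1$table$emmean, e2$table$emmean, tolerance = 1e-6)
})

test_that("pairwise contrasts give z = 0, p = 1 for identical groups and are antisymmetric", {
  d <- data.frame(species = factor(rep(c("corvids", "gulls"), each = 30)),
                  n_escapes = rep(c(3L, 5L, 7L), 20))
  spec <- rate_model_spec(fixed_effects = "species", interactions = character(),
                          random_intercepts = character())
  emm <- estimated_marginal_means(fit_poisson_glmm(d, spec), "species")
  ct <- pairwise_contrasts(emm)
  expect_equal(ct$z_ratio, 0, tolerance = 1e-8)
  expect_equal(ct$p_adjusted, 1, tolerance = 1e-8)

  # antisymmetry: reversing the factor level order flips z, keeps p
  d2 <- d; d2$species <- factor(as.character(d2$species),
                                levels = c("gulls", "corvids"))
  d2$n_escapes <- rpois(60, exp(1 + 0.5 * (d2$species == "corvids")))
  emm2 <- estimated_marginal_means(fit_poisson_glmm(d2, spec), "species")
  ct2 <- pairwise_contrasts(emm2)
  d3 <- d2; d3$species <- factor(as.character(d3$species),
                                 levels = c("corvids", "gulls"))
  emm3 <- estimated_marginal_means(fit_poisson_glmm(d3, spec), "species")
  ct3 <- pairwise_contrasts(emm3)
  expect_equal(ct2$z_ratio, -ct3$z_ratio, tolerance = 1e-6)
  expect_equal(ct2$p_adjusted, ct3$p_adjusted, tolerance = 1e-6)
})

test_that("altitude binning partitions events with the stated boundary convention", {
  ch <- toy_chase("c1", duration_s = 70)
  ev <- toy_events("c1", c(0, 19.9, 20.0, 55, 70),
                   rep("collective_turn", 5))
  b <- altitude_binned_counts(ev, ch, bin_s = 20)
  expect_equal(b$width_s, c(20, 20, 20, 10))
  expect_equal(b$count, c(2L, 1L, 1L, 1L))      # 0 and 19.9 in bin 1; 20.0 in bin 2
  expect_equal(sum(b$count), 5L)                 # partition property
  # unknown-altitude chases are excluded
  ch2 <- rbind(ch, toy_chase("c2", altitude_class = "unknown"))
  ev2 <- rbind(ev, toy_events("c2", 5, "split"))
  expect_false("c2" %in% altitude_binned_counts(ev2, ch2)$chase_id)
})

test_that("the altitude model uses bin width as an offset and needs both classes", {
  set.seed(44)
  n_chases <- 40
  binned <- do.call(rbind, lapply(seq_len(n_chases), function(i) {
    data.frame(chase_id = sprintf("c%02d", i), bin = 1:4,
               t_start_s = seq(0, 60, 20), width_s = 20,
               count = rpois(4, 4),
               altitude_class = ifelse(i <= n_chases / 2, "high", "low"),
               stringsAsFactors = FALSE)
  }))
  f1 <- fit_altitude_model(binned)
  doubled <- binned; doubled$width_s <- binned$width_s * 2
  f2 <- fit_altitude_model(doubled)
  i1 <- f1$coefficients$estimate[f1$coefficients$term == "(Intercept)"]
  i2 <- f2$coefficients$estimate[f2$coefficients$term == "(Intercept)"]
  expect_equal(i2 - i1, -log(2), tolerance = 1e-4)
  expect_equal(f2$altitude_test$chisq, f1$altitude_test$chisq, tolerance = 1e-4)

  expect_error(fit_altitude_model(binned[binned$altitude_class == "high", ]),
               "altitude classes")
})

test_that("the pooled two-sample comparison has df = n_a + n_b - 2 and matches hand computation", {
  set.seed(50)
  a <- rpois(23, 16); b <- rpois(46, 15)
  tt <- compare_robot_vs_falcon(a, b)
  expect_equal(unname(tt$parameter), 67)

  # identical samples: t = 0, p = 1
  x <- c(3, 5, 7, 9)
  t0 <- compare_robot_vs_falcon(x, x)
  expect_equal(unname(t0$statistic), 0)
  expect_equal(t0$p.value, 1)

  # hand computation: (1,2,3) vs (4,5,6), pooled s^2 = 1,
  # t = -3 / sqrt(2/3) = -3.674, df = 4
  th <- compare_robot_vs_falcon(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(th$statistic), -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(unname(th$parameter), 4)

  # Welch variant generally has non-integer df
  tw <- compare_robot_vs_falcon(c(1, 2, 3, 10), c(4, 5, 6), welch = TRUE)
  expect_false(isTRUE(all.equal(unname(tw$parameter), 5)))
  expect_error(compare_robot_vs_falcon(1, c(2, 3)), "at least 2")
})
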