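#' Configuration of the end-to-end analysis pipeline
#'
#' Bundles every setting of [run_pipeline()]: the input files (or a
#' simulation configuration standing in for them), the follow-rule
#' configuration, the permutation-null settings, the count-model settings
#' and the output directory. A run's configuration is archived in its
#' manifest together with a content hash, so reruns are verifiably
#' identical.
#'
#' @param events_file,chases_file paths to the canonical input CSVs;
#'   ignored when `simulate` is given.
#' @param simulate optionally a [simulation_config()]; the pipeline then
#'   generates its own inputs.
#' @param out_dir output directory.
#' @param seed integer seed driving simulation and permutation sampling.
#' @param transition a [transition_config()].
#' @param n_null number of fixed-margin null tables per transition panel.
#' @param alpha significance level for flagged transitions and pruning.
#' @param correction `"none"` or `"benjamini_hochberg"`.
#' @param model `"best"` (prune non-significant interactions) or `"full"`.
#' @param emm_factor factor for the marginal-means post hoc analysis.
#' @param offset_duration sensitivity variant: duration as offset rather
#'   than covariate.
#' @param min_chases minimum chases for a species x predator panel to enter
#'   the transition analysis.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(events_file = NULL, chases_file = NULL,
                            simulate = NULL, out_dir = tempfile("flockescape_run_"),
                            seed = 1, transition = transition_config(),
                            n_null = 1e4, alpha = 0.05,
                            correction = c("none", "benjamini_hochberg"),
                            model = c("best", "full"),
                            emm_factor = "species", offset_duration = FALSE,
                            min_chases = 10) {
  if (is.null(simulate) && (is.null(events_file) || is.null(chases_file))) {
    stop("either input files or a simulation config must be given")
  }
  structure(list(events_file = events_file, chases_file = chases_file,
                 simulate = simulate, out_dir = out_dir, seed = seed,
                 transition = transition, n_null = n_null, alpha = alpha,
                 correction = match.arg(correction), model = match.arg(model),
                 emm_factor = emm_factor,
                 offset_duration = isTRUE(offset_duration),
                 min_chases = min_chases),
            class = "pipeline_config")
}

# small polynomial content hash of the deparsed configuration;
# analysis-relevant settings only (the output directory does not influence
# results)
config_hash <- function(config) {
  c2 <- config
  c2$out_dir <- NULL
  txt <- paste(deparse(c2), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full collective-escape analysis pipeline
#'
#' Executes, in order: ingestion (reading or simulating the dataset),
#' validation, descriptive summaries (dataset summary and escape-type
#' composition), transition-matrix construction per species x predator
#' panel, the fixed-margin permutation test per panel, the count-model
#' stage (full Poisson mixed model, overdispersion check of the
#' fixed-effects fit, optional pruning, Type-II term tests, marginal means
#' and Tukey contrasts), the altitude-binned rate model (when both
#' altitude classes are present) and the robotic-vs-wild-falcon comparison
#' (when both predator groups are present for starlings). Each stage's
#' artefacts are written as CSV under `out_dir`; failures abort naming the
#' stage, retaining the artefacts already written. A `manifest.json`
#' records the stages, timings, seed, package version and configuration
#' hash.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("summary", "transitions", "models")) {
    dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  }
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  stages <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    el <- proc.time()[["elapsed"]] - t0
    stages[[length(stages) + 1L]] <<- list(name = name, seconds = round(el, 3))
    logline(sprintf("stage %-12s done in %.2f s", name, el))
    res
  }
  out <- function(...) file.path(config$out_dir, ...)
  wcsv <- function(x, path) write.csv(x, path, row.names = FALSE)

  dat <- stage("ingest", function() {
    if (!is.null(config$simulate)) {
      sim <- simulate_dataset(config$simulate, seed = config$seed)
      write_simulation(sim, out("input"))
      list(events = sim$events, chases = sim$chases)
    } else {
      list(events = read_events(config$events_file),
           chases = read_chases(config$chases_file))
    }
  })

  stage("validate", function() {
    rep <- validate_dataset(dat$events, dat$chases)
    wcsv(rep, out("summary", "validation.csv"))
    if (nrow(rep)) stop(nrow(rep), " validation finding(s); see summary/validation.csv")
  })

  stage("summarize", function() {
    wcsv(summarize_dataset(dat$events, dat$chases), out("summary", "dataset_summary.csv"))
    comp <- suppressWarnings(
      escape_type_composition(dat$events, dat$chases,
                              grouping = c("species", "predator_type")))
    wcsv(comp, out("summary", "composition.csv"))
    wcsv(escape_counts_per_chase(dat$events, dat$chases),
         out("summary", "per_chase_counts.csv"))
  })

  panels <- NULL
  tms <- stage("transitions", function() {
    tab <- table(dat$chases$species, dat$chases$predator_type)
    idx <- which(tab >= config$min_chases, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("no species x predator panel reaches min_chases = ",
                             config$min_chases)
    panels <<- data.frame(species = rownames(tab)[idx[, 1]],
                          predator_type = colnames(tab)[idx[, 2]],
                          stringsAsFactors = FALSE)
    lapply(seq_len(nrow(panels)), function(i) {
      tm <- build_transitions(dat$events, dat$chases, config$transition,
                              species = panels$species[i],
                              predator_type = panels$predator_type[i])
      m <- as.data.frame(tm$counts)
      m <- cbind(from = rownames(tm$counts), m)
      wcsv(m, out("transitions", sprintf("matrix_%s_%s.csv", panels$species[i],
                                         panels$predator_type[i])))
      tm
    })
  })

  stage("permutation", function() {
    for (i in seq_along(tms)) {
      res <- permutation_test(tms[[i]], n_null = config$n_null,
                              seed = config$seed + i, alpha = config$alpha,
                              correction = config$correction)
      edges <- transition_edge_list(tms[[i]], res, alpha = config$alpha)
      wcsv(edges, out("transitions", sprintf("edges_%s_%s.csv",
                                             panels$species[i], panels$predator_type[i])))
      wcsv(significant_transitions(res),
           out("transitions", sprintf("significant_%s_%s.csv",
                                      panels$species[i], panels$predator_type[i])))
    }
  })

  stage("rate_models", function() {
    d <- escape_count_table(dat$events, dat$chases)
    # the GLMM compares robotic falcon and drone; wild-falcon hunts have no
    # chase covariates comparable to the artificial-predator protocol
    d <- d[d$predator_type %in% c("robotfalcon", "drone"), , drop = FALSE]
    d$predator_type <- droplevels_keep_ref(d$predator_type)
    d$species <- droplevels_keep_ref(d$species)
    has_two_species <- nlevels(d$species) > 1
    has_two_pred <- nlevels(d$predator_type) > 1
    fe <- c(if (has_two_species) "species", if (has_two_pred) "predator_type",
            "chasing_intensity", "duration_s", "multiple_species")
    # species x predator is only estimable when every species was chased by
    # both predator types (e.g. not when one species lacks drone chases)
    crossed <- has_two_species && has_two_pred &&
      all(table(d$species, d$predator_type) > 0)
    ia <- c(if (has_two_species) "species:chasing_intensity",
            if (crossed) "species:predator_type",
            if (has_two_pred) "predator_type:chasing_intensity")
    spec <- rate_model_spec(fixed_effects = fe, interactions = ia,
                            offset_duration = config$offset_duration)
    full <- fit_poisson_glmm(d, spec)
    if (!full$converged) stop("count model did not converge")
    disp <- check_overdispersion(
      fit_poisson_glmm(d, rate_model_spec(fixed_effects = fe, interactions = ia,
                                          random_intercepts = character(),
                                          offset_duration = config$offset_duration)))
    wcsv(data.frame(ratio = disp$ratio, pearson_chisq = disp$pearson_chisq,
                    df = disp$df, p = disp$p, overdispersed = disp$overdispersed),
         out("models", "overdispersion.csv"))
    use <- full
    if (config$model == "best") {
      pr <- prune_to_best_model(full, alpha = config$alpha)
      wcsv(pr$dropped, out("models", "pruned_interactions.csv"))
      use <- pr$fit
    }
    wcsv(use$coefficients, out("models", "coefficients.csv"))
    wcsv(term_tests(use), out("models", "term_tests.csv"))
    wcsv(data.frame(group = names(use$re_variances),
                    variance = unname(use$re_variances)),
         out("models", "random_effects.csv"))
    if (config$emm_factor %in% use$spec$fixed_effects &&
        nlevels(d[[config$emm_factor]]) > 1) {
      emm <- estimated_marginal_means(use, config$emm_factor)
      wcsv(emm$table, out("models", "emmeans.csv"))
      wcsv(pairwise_contrasts(emm), out("models", "contrasts.csv"))
    }
  })

  stage("altitude", function() {
    binned <- altitude_binned_counts(dat$events, dat$chases)
    if (length(unique(binned$altitude_class)) < 2) {
      wcsv(data.frame(note = "fewer than two altitude classes; model skipped"),
           out("models", "altitude.csv"))
      return(invisible(NULL))
    }
    af <- fit_altitude_model(binned)
    wcsv(cbind(af$altitude_test, rate_ratio = af$rate_ratio),
         out("models", "altitude.csv"))
  })

  stage("compare", function() {
    d <- escape_count_table(dat$events, dat$chases)
    a <- d$n_escapes[d$species == "starlings" & d$predator_type == "robotfalcon"]
    b <- d$n_escapes[d$species == "starlings" & d$predator_type == "falcon"]
    if (length(a) >= 2 && length(b) >= 2) {
      tt <- compare_robot_vs_falcon(a, b)
      wcsv(data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value, n_robotfalcon = length(a),
                      n_falcon = length(b)),
           out("models", "robot_vs_falcon.csv"))
    } else {
      wcsv(data.frame(note = "needs starling chases for both robotfalcon and falcon"),
           out("models", "robot_vs_falcon.csv"))
    }
  })

  manifest <- list(package = "flockescape",
                   version = as.character(packageVersion("flockescape")),
                   seed = config$seed, config_hash = config_hash(config),
                   stages = stages,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logline("pipeline complete: ", length(stages), " stages")
  invisible(manifest)
}
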