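#' Configuration for the full assessment pipeline
#'
#' @param input `"synthetic"` (generate a survey from `profile`) or a path to
#'   a sample-table CSV.
#' @param profile A `study_profile` used when `input = "synthetic"` and for
#'   reference constants.
#' @param n_sites Number of synthetic sites.
#' @param seed Integer seed driving every stochastic stage.
#' @param reference A [reference_table()].
#' @param toxicology A [default_toxicology()] table.
#' @param er_mode Ecological-risk form, see [single_metal_risk()].
#' @param n_iterations,ci_level Monte Carlo settings, see [mc_config()].
#' @param out_dir Output directory for the report bundle.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = "synthetic",
                            profile = default_liuye_profile(),
                            n_sites = profile$n_sites,
                            seed = 1,
                            reference = default_reference(),
                            toxicology = default_toxicology(),
                            er_mode = c("paper_division", "hakanson_product"),
                            n_iterations = 10000,
                            ci_level = 0.95,
                            out_dir = tempfile("sedrisk_report_")) {
  er_mode <- match.arg(er_mode)
  structure(list(input = input, profile = profile, n_sites = n_sites,
                 seed = as.integer(seed), reference = reference,
                 toxicology = toxicology, er_mode = er_mode,
                 mc = mc_config(n_iterations, seed, ci_level),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# deterministic full-precision CSV writer (byte-identical across runs)
.write_table <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- sprintf("%.15g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  path
}

#' Run the full sediment risk-assessment pipeline
#'
#' Orchestrates the complete analysis — acquire data (synthetic or CSV),
#' summarize, fit and rank distribution families, compute deterministic
#' pollution/ecological indices per site, Monte Carlo index summaries with
#' class probabilities, health-risk HI/TCR tables with exceedance
#' probabilities for the three population groups and two routes, and
#' contribution-to-variance sensitivity — and writes a tidy CSV/JSON report
#' bundle plus a run log. Any stage failure aborts with the stage name and
#' removes partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory tables and `out_dir`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    .write_table(df, path)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    # --- data -----------------------------------------------------------
    stage <- "data"
    samples <- if (identical(config$input, "synthetic")) {
      generate_samples(config$profile, config$n_sites, config$seed)
    } else {
      read_sample_table(config$input)
    }

    # --- summary --------------------------------------------------------
    stage <- "summary"
    stats <- summarize_samples(samples)
    emit(stats, "summary_stats.csv")
    corr <- correlation_matrix(samples)
    emit(cbind(data.frame(metal = rownames(corr)), as.data.frame(corr)),
         "correlation.csv")

    # --- distribution fitting -------------------------------------------
    stage <- "fit"
    candidates <- c("normal", "lognormal", "uniform", "triangular",
                    "beta_scaled", "weibull")
    fits <- lapply(metal_names(), function(m) {
      ranked <- select_family(samples[[m]], candidates)
      tibble::tibble(metal = m, rank = seq_len(nrow(ranked)),
                     family = ranked$family, ad = ranked$ad,
                     spec = ranked$spec)
    })
    fit_tbl <- do.call(rbind, fits)
    emit(fit_tbl[, c("metal", "rank", "family", "ad")], "fitted_families.csv")
    best_spec <- lapply(stats::setNames(metal_names(), metal_names()),
                        function(m) fit_tbl$spec[fit_tbl$metal == m &
                                                 fit_tbl$rank == 1][[1]])

    # --- deterministic indices ------------------------------------------
    stage <- "indices"
    assessment <- assess_pollution(samples, config$reference, config$er_mode)
    emit(assessment$by_metal, "indices_by_metal.csv")
    emit(assessment$by_site, "indices_by_site.csv")

    # --- Monte Carlo index summaries ------------------------------------
    stage <- "mc_indices"
    ref <- config$reference
    al_ratio_mean <- if ("Al" %in% names(samples))
      mean(samples$Al) / ref$al_background else NA_real_
    mc_rows <- list(); cp_rows <- list()
    er_draw_sum <- 0
    for (m in metal_names()) {
      conc_spec <- best_spec[[m]]
      cfg <- mc_config(config$mc$n_iterations,
                       derive_seed(config$seed, paste0("mc_", m)),
                       config$mc$ci_level)
      res_ig <- run_mc(function(x) igeo(x$conc, ref$background[[m]]),
                       list(conc = conc_spec), cfg)
      res_er <- run_mc(function(x)
        single_metal_risk(contamination_factor(x$conc, ref$background[[m]]),
                          ref$toxic_response[[m]], config$er_mode),
        list(conc = conc_spec), cfg)
      er_draw_sum <- er_draw_sum + res_er$draws
      summ <- function(q, r) tibble::tibble(
        metal = m, quantity = q, mean = r$mean, median = r$median,
        ci_low = r$ci_low, ci_high = r$ci_high)
      mc_rows[[length(mc_rows) + 1]] <- summ("igeo", res_ig)
      mc_rows[[length(mc_rows) + 1]] <- summ("er", res_er)
      cp <- class_probabilities(res_ig, igeo_scheme())
      cp_rows[[length(cp_rows) + 1]] <- tibble::tibble(
        metal = m, index = "igeo", label = names(cp), probability = unname(cp))
      if (is.finite(al_ratio_mean)) {
        res_ef <- run_mc(function(x)
          enrichment_factor(x$conc, x$al_ratio * ref$al_background,
                            ref$background[[m]], ref$al_background),
          list(conc = conc_spec,
               al_ratio = config$profile$al_model), cfg)
        mc_rows[[length(mc_rows) + 1]] <- summ("ef", res_ef)
        cpe <- class_probabilities(res_ef, ef_scheme())
        cp_rows[[length(cp_rows) + 1]] <- tibble::tibble(
          metal = m, index = "ef", label = names(cpe),
          probability = unname(cpe))
      }
    }
    ri_q <- stats::quantile(er_draw_sum,
                            c((1 - config$mc$ci_level) / 2,
                              1 - (1 - config$mc$ci_level) / 2), names = FALSE)
    mc_rows[[length(mc_rows) + 1]] <- tibble::tibble(
      metal = "ALL", quantity = "ri", mean = mean(er_draw_sum),
      median = stats::median(er_draw_sum), ci_low = ri_q[1], ci_high = ri_q[2])
    cpr <- class_probabilities(er_draw_sum, ri_scheme())
    cp_rows[[length(cp_rows) + 1]] <- tibble::tibble(
      metal = "ALL", index = "ri", label = names(cpr),
      probability = unname(cpr))
    emit(do.call(rbind, mc_rows), "mc_indices.csv")
    emit(do.call(rbind, cp_rows), "mc_class_probabilities.csv")

    # --- health risk ----------------------------------------------------
    stage <- "health_risk"
    conc_mean <- stats::setNames(stats$mean, stats$metal)
    hr_rows <- list(); sens_rows <- list()
    for (group in c("adult_male", "adult_female", "child")) {
      prof <- default_exposure_profile(group)
      for (route in c("ingestion", "dermal")) {
        cfg <- mc_config(config$mc$n_iterations,
                         derive_seed(config$seed, paste(group, route)),
                         config$mc$ci_level)
        hi <- simulate_hazard_index(conc_mean, prof, route,
                                    config$toxicology, cfg)
        tcr <- simulate_carcinogenic_risk(conc_mean, prof, route,
                                          config$toxicology, cfg)
        hr_rows[[length(hr_rows) + 1]] <- tibble::tibble(
          group = group, route = route,
          hi_mean = hi$mean, hi_median = hi$median,
          hi_ci_low = hi$ci_low, hi_ci_high = hi$ci_high,
          p_hi_above_1 = exceedance_probability(hi, 1),
          tcr_mean = tcr$mean, tcr_class = classify_tcr(tcr$mean),
          p_tcr_unacceptable = exceedance_probability(tcr, 1e-4))
        sens <- mc_sensitivity(hi)
        sens_rows[[length(sens_rows) + 1]] <- tibble::tibble(
          group = group, route = route, input = names(sens),
          contribution_pct = unname(sens))
      }
    }
    health <- do.call(rbind, hr_rows)
    emit(health, "health_risk.csv")
    emit(do.call(rbind, sens_rows), "sensitivity.csv")

    # --- machine-readable summary + log ---------------------------------
    stage <- "report"
    json_path <- file.path(config$out_dir, "results.json")
    jsonlite::write_json(list(
      seed = config$seed, er_mode = config$er_mode,
      n_iterations = config$mc$n_iterations,
      ri_mean = mean(er_draw_sum),
      hi = stats::setNames(as.list(health$hi_mean),
                           paste(health$group, health$route, sep = "_"))
    ), json_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, json_path)
    log_path <- file.path(config$out_dir, "run_log.txt")
    writeLines(c(
      sprintf("sedrisk %s", as.character(utils::packageVersion("sedrisk"))),
      sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seed: %d", config$seed),
      sprintf("er_mode: %s", config$er_mode),
      sprintf("n_iterations: %d", config$mc$n_iterations),
      sprintf("input: %s", if (identical(config$input, "synthetic"))
        sprintf("synthetic (%d sites)", config$n_sites) else config$input)
    ), log_path)
    written <- c(written, log_path)

    list(samples = samples, summary = stats, fits = fit_tbl,
         assessment = assessment, mc_indices = do.call(rbind, mc_rows),
         class_probabilities = do.call(rbind, cp_rows),
         health_risk = health, sensitivity = do.call(rbind, sens_rows),
         out_dir = config$out_dir)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
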