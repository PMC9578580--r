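#' Read a long-format growth CSV
#'
#' Expects a header with columns `strain`, `replicate`, `time_h`, `value`,
#' `modality` (comma separator, `.` decimal). Rows are validated and
#' time-sorted; duplicated (strain, replicate, modality, time) rows are an
#' error.
#'
#' @param path CSV file path.
#' @return A validated long data frame.
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "replicate", "time_h", "value", "modality")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!is.numeric(df$time_h) || !is.numeric(df$value))
    stop("time_h and value must be numeric", call. = FALSE)
  if (any(df$time_h < 0)) stop("negative times", call. = FALSE)
  key <- paste(df$strain, df$replicate, df$modality, df$time_h)
  if (anyDuplicated(key)) {
    stop("duplicated (strain, replicate, time) row(s): row ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }
  df[order(df$strain, df$replicate, df$modality, df$time_h), , drop = FALSE]
}

#' @rdname read_growth_csv
#' @param data Long data frame to write.
#' @export
write_growth_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize replicate curves to fold change
#'
#' Divides each (strain, replicate, modality) curve by its own `t = 0`
#' value. Replicates lacking a `t = 0` point are an error.
#'
#' @param data Long data frame (`strain`, `replicate`, `time_h`, `value`).
#' @return The data frame with `value` replaced by fold change.
#' @export
normalize_fold_change <- function(data) {
  mod <- if ("modality" %in% names(data)) data$modality else ""
  key <- paste(data$strain, data$replicate, mod)
  for (k in unique(key)) {
    sel <- key == k
    i0 <- sel & data$time_h == 0
    if (!any(i0)) stop("replicate without a t = 0 point: ", k, call. = FALSE)
    data$value[sel] <- data$value[sel] / data$value[i0][1]
  }
  data
}

#' Validate a pipeline configuration
#'
#' @param config Named list (or YAML path) with entries: one of `input`
#'   (CSV path) or `synth` (list passed to [generate_archetype_panel()]);
#'   optional `schedule`, `models`, `fit` (n_starts, seed, residual_scale),
#'   `clustering` (k, transform), `pca_preprocessing`, `feasibility`
#'   (preset, n_samples), `seed`, `outdir`.
#' @return The validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$input) && is.null(config$synth))
    stop("config needs either `input` (CSV path) or `synth` (generator spec)",
         call. = FALSE)
  defaults <- list(
    schedule = "coarse9", models = c("R", "RQ"),
    fit = list(n_starts = 8, seed = 1, residual_scale = "linear"),
    clustering = list(k = 3, transform = "log10"),
    pca_preprocessing = "log_z",
    feasibility = list(preset = "fig3b", n_samples = 2000),
    seed = 1, outdir = "qsgrowth_run"
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (sub in names(defaults[[nm]]))
        if (is.null(config[[nm]][[sub]])) config[[nm]][[sub]] <- defaults[[nm]][[sub]]
  }
  config
}

#' Run the full analysis pipeline
#'
#' Chains the stages end-to-end: (optional) synthetic-data generation,
#' fold-change normalization, growth/death rate estimation, per-replicate
#' fits of the resource-only and density-dependent models, model
#' comparison, feasibility mapping, and phenotype analysis. All stage
#' outputs are written as CSV/JSON under `config$outdir` together with a
#' machine-readable run manifest; reruns with the same config are
#' reproducible.
#'
#' @param config See [validate_config()].
#' @return Invisibly, a list of the stage results.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- list()
  tryCatch({
    if (!is.null(config$input)) {
      data <- read_growth_csv(config$input)
      truth <- NULL
    } else {
      stage <- "synth"
      panel <- do.call(generate_archetype_panel,
                       c(config$synth, list(seed = config$seed)))
      data <- panel$data
      if (!is.null(panel$od)) data <- rbind(data, panel$od)
      truth <- panel$truth
      write_growth_csv(data, file.path(outdir, "synthetic_data.csv"))
      utils::write.csv(truth, file.path(outdir, "synthetic_truth.csv"),
                       row.names = FALSE)
    }
    cfu <- data[data$modality == "CFU", ]

    stage <- "rate_estimation"
    rates <- rate_table(data)
    utils::write.csv(rates, file.path(outdir, "rates.csv"), row.names = FALSE)

    stage <- "model_fitting"
    fc <- normalize_fold_change(cfu)
    fits <- list()
    rows <- list()
    for (s in unique(fc$strain)) {
      g_med <- median(rates$rate[rates$strain == s & rates$which == "growth"])
      d_med <- median(rates$rate[rates$strain == s & rates$which == "death"])
      if (!is.finite(d_med)) d_med <- 0.05
      lam <- if ("OD" %in% data$modality[data$strain == s]) g_med else g_med + d_med
      if (!is.finite(lam)) lam <- 1
      for (r in unique(fc$replicate[fc$strain == s])) {
        tr <- fc[fc$strain == s & fc$replicate == r, ]
        for (m in config$models) {
          f <- try(two_stage_fit(tr$time_h, tr$value, lam, d_med, model = m,
                                 n_starts = config$fit$n_starts,
                                 seed = config$fit$seed,
                                 residual_scale = config$fit$residual_scale),
                   silent = TRUE)
          if (inherits(f, "try-error")) next
          fits[[paste(s, r, m)]] <- f
          pp <- f$params
          rows[[paste(s, r, m)]] <- data.frame(
            strain = s, replicate = r, model = m,
            lambda_max = pp$lambda_max, d = pp$d, B = pp$B, K_r = pp$K_r,
            K_qs = pp$K_qs, inv_B = 1 / pp$B,
            lambda_fixed = f$fixed_mask["lambda_max"], d_fixed = f$fixed_mask["d"],
            rss = f$rss, aic = f$aic, bic = f$bic,
            spearman_rho = f$spearman_rho, spearman_p = f$spearman_p,
            converged = f$converged,
            max_fc = max(tr$value))
        }
      }
    }
    fit_tab <- do.call(rbind, rows)
    utils::write.csv(fit_tab, file.path(outdir, "fits.csv"), row.names = FALSE)

    stage <- "model_comparison"
    cmp <- NULL
    if (all(c("R", "RQ") %in% config$models)) {
      keys <- unique(sub(" R$", "", grep(" R$", names(fits), value = TRUE)))
      keys <- keys[paste(keys, "RQ") %in% names(fits)]
      if (length(keys) >= 2) {
        cmp <- compare_models_dataset(fits[paste(keys, "R")], fits[paste(keys, "RQ")])
        jsonlite::write_json(cmp, file.path(outdir, "model_comparison.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }

    stage <- "feasibility"
    feas <- NULL
    if (!is.null(config$feasibility)) {
      pts <- sample_phase_space(feasibility_ranges(config$feasibility$preset),
                                n_samples = config$feasibility$n_samples,
                                model = "R", seed = config$seed)
      feas <- region_boundary(pts)
      write_region_json(pts, feas, file.path(outdir, "feasibility_R.json"))
    }

    stage <- "phenotype_analysis"
    mt <- median_trajectories(cfu)
    cl <- cluster_timeseries(mt, k = config$clustering$k,
                             transform = config$clustering$transform)
    utils::write.csv(data.frame(strain = names(cl$labels), cluster = cl$labels),
                     file.path(outdir, "clusters.csv"), row.names = FALSE)
    rq <- fit_tab[fit_tab$model == "RQ", ]
    pheno <- NULL
    if (nrow(rq) >= 3 && length(unique(rq$strain)) >= 3) {
      # tiny panels can leave a variable constant (e.g. K_r pinned at a
      # bound); the report is skipped rather than halting the pipeline
      pheno <- tryCatch(phenotype_report(rq), error = function(e) {
        message("phenotype report skipped: ", conditionMessage(e))
        NULL
      })
      if (!is.null(pheno))
        utils::write.csv(
          cbind(strain = rownames(pheno$table$median), pheno$table$median),
          file.path(outdir, "phenotype_medians.csv"), row.names = FALSE)
    }

    stage <- "manifest"
    strip_cls <- function(x) if (is.list(x)) lapply(unclass(x), strip_cls) else x
    manifest <- list(
      config = strip_cls(config[setdiff(names(config), "outdir")]),
      seed = config$seed,
      r_version = as.character(getRversion()),
      n_strains = length(unique(cfu$strain)),
      n_fits = length(fits))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    res <- list(data = data, rates = rates, fits = fit_tab,
                comparison = cmp, feasibility = feas,
                clusters = cl, phenotypes = pheno)
  }, error = function(e) {
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
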