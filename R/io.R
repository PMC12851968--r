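#' Read an RRi recording from a text file
#'
#' Two layouts are supported: a single column of intervals in ms (one
#' per line, beat times reconstructed by cumulative summation from 0),
#' or a two-column CSV `time_min,rri_ms` with a header. Validation
#' failures report the offending line number.
#'
#' @param path File path.
#' @param subject_id Label; defaults to the file name without extension.
#' @return An `rri_recording` with an all-`FALSE` mask.
#' @export
read_rri <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("read_rri: file not found: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_rri: empty file: ", path)

  if (grepl(",", lines[1])) {
    header <- grepl("[A-Za-z]", lines[1])
    body <- if (header) lines[-1] else lines
    offset <- if (header) 1L else 0L
    if (!length(body)) stop("read_rri: no data rows in ", path)
    parts <- strsplit(body, ",")
    tm <- numeric(length(body)); rr <- numeric(length(body))
    for (i in seq_along(parts)) {
      ln <- i + offset
      p <- suppressWarnings(as.numeric(trimws(parts[[i]])))
      if (length(p) < 2L || anyNA(p[1:2]))
        stop("read_rri: unparseable row at line ", ln, " of ", path)
      tm[i] <- p[1]; rr[i] <- p[2]
      if (rr[i] <= 0)
        stop("read_rri: nonpositive interval at line ", ln, " of ", path)
    }
    if (any(diff(tm) <= 0)) {
      bad <- which(diff(tm) <= 0)[1] + 1L + offset
      stop("read_rri: beat times not strictly increasing at line ", bad,
           " of ", path)
    }
    return(rri_recording(tm, rr, subject_id = subject_id))
  }

  rr <- suppressWarnings(as.numeric(trimws(lines)))
  if (anyNA(rr)) {
    stop("read_rri: unparseable value at line ", which(is.na(rr))[1],
         " of ", path)
  }
  if (any(rr <= 0)) {
    stop("read_rri: nonpositive interval at line ", which(rr <= 0)[1],
         " of ", path)
  }
  tm <- c(0, cumsum(rr[-length(rr)])) / 60000
  rri_recording(tm, rr, subject_id = subject_id)
}

#' Write an RRi recording as a two-column CSV
#'
#' Columns `time_min,rri_ms`, full double precision. Optionally writes a
#' JSON sidecar with ground-truth parameters.
#'
#' @param rec An `rri_recording`.
#' @param path Output CSV path.
#' @param truth Optional `cas_parameters` written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_rri <- function(rec, path, truth = NULL) {
  stopifnot(inherits(rec, "rri_recording"))
  df <- data.frame(time_min = sprintf("%.12g", rec$time),
                   rri_ms = sprintf("%.12g", rec$rri))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(as.list(unlist(as_cas_parameters(truth))),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write / read the cohort immune predictor table
#'
#' CSV with columns `subject_id`, the six immune counts, `age`, `sex`,
#' `fat_pct`, `muscle_kg`.
#'
#' @param immune Data frame (e.g. `simulate_cohort(...)$immune`).
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_immune_table <- function(immune, path) {
  utils::write.csv(immune, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_immune_table
#' @export
read_immune_table <- function(path) {
  if (!file.exists(path)) stop("read_immune_table: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", predictor_names())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_immune_table: missing columns: ", paste(miss, collapse = ", "))
  if (any(df$lymphocytes < 0) || any(df$b_total < 0))
    stop("read_immune_table: negative immune counts")
  df
}

# stable polynomial hash of the serialized configuration, for manifests
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles every stage configuration plus the global seed for
#' [run_pipeline()].
#'
#' @param protocol,filter_cfg,ectopic_cfg,bounds,spec Stage configs.
#' @param n_starts Optimisation starts per subject.
#' @param preprocess_order Passed to [preprocess_rri()].
#' @param seed Global seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(protocol = protocol_timing(),
                            filter_cfg = filter_config(),
                            ectopic_cfg = ectopic_config(),
                            bounds = cas_bounds(protocol),
                            spec = regression_spec(),
                            n_starts = 5L,
                            preprocess_order = "ectopic_first",
                            seed = 1L) {
  structure(list(protocol = protocol, filter_cfg = filter_cfg,
                 ectopic_cfg = ectopic_cfg, bounds = bounds, spec = spec,
                 n_starts = as.integer(n_starts),
                 preprocess_order = preprocess_order,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full two-stage analysis pipeline
#'
#' Preprocesses every recording, fits the per-subject CAS parameters,
#' standardizes, runs the second-stage Bayesian regression, and produces
#' SEXIT summaries and MCMC diagnostics. Any stage failure aborts with
#' the stage name and subject id.
#'
#' @param recordings List of `rri_recording` objects (or a directory of
#'   recording files readable by [read_rri()]).
#' @param immune Immune predictor data frame or CSV path.
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory; when given, stage outputs (CAS
#'   table, SEXIT summary, diagnostics, manifest) are written as
#'   CSV/JSON.
#' @return List with `cas_table`, `draws`, `sexit`, `diagnostics`,
#'   `preprocess_reports` and `manifest`.
#' @export
run_pipeline <- function(recordings, immune, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(recordings)) {
    files <- sort(list.files(recordings, full.names = TRUE,
                             pattern = "\\.(csv|txt)$"))
    recordings <- lapply(files, read_rri)
  }
  if (is.character(immune)) immune <- read_immune_table(immune)

  reports <- list(); cleaned <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    pp <- tryCatch(preprocess_rri(rec, config$filter_cfg, config$ectopic_cfg,
                                  order = config$preprocess_order),
                   error = function(e)
                     stop("run_pipeline: preprocess failed for subject ",
                          rec$subject_id, ": ", conditionMessage(e)))
    cleaned[[i]] <- pp$recording
    reports[[i]] <- pp$report
  }

  cas_table <- tryCatch(
    fit_cohort(cleaned, config$protocol, bounds = config$bounds,
               n_starts = config$n_starts, seed = config$seed,
               preprocess = FALSE),
    error = function(e) stop("run_pipeline: fit-cas stage failed: ",
                             conditionMessage(e)))

  spec <- config$spec
  spec$seed <- config$seed
  draws <- fit_cas_regression(cas_table, immune, spec)
  sexit <- sexit_summary(draws)
  diag <- mcmc_diagnostics(draws)

  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_recordings = length(recordings),
    n_cas_rows = nrow(cas_table),
    n_sexit_rows = nrow(sexit),
    n_draws = nrow(draws$draws),
    chains = spec$chains,
    include_confounders = spec$include_confounders,
    removal_fractions = vapply(reports, function(r) r$removal_fraction,
                               numeric(1)),
    warnings = draws$warnings,
    package_version = as.character(utils::packageVersion("cardiosig"))
  )

  out <- list(cas_table = cas_table, draws = draws, sexit = sexit,
              diagnostics = diag, preprocess_reports = reports,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cas_table, file.path(out_dir, "cas_estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(sexit, file.path(out_dir, "sexit_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(diag, file.path(out_dir, "diagnostics.csv"),
                     row.names = FALSE)
    draws_df <- data.frame(chain = draws$chain, iteration = draws$iteration,
                           draws$draws, check.names = FALSE)
    utils::write.csv(draws_df, file.path(out_dir, "posterior_draws.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Cohort-level CAS summary table
#'
#' Mean and normal-theory 95% interval of each fitted CAS parameter
#' across subjects, mirroring the cohort-level reporting style of the
#' reference analysis.
#'
#' @param cas_table Output of [fit_cohort()] (or `run_pipeline()$cas_table`).
#' @return Data frame with `parameter`, `mean`, `ci_low`, `ci_high`.
#' @export
cas_cohort_table <- function(cas_table) {
  rows <- lapply(cas_par_names(), function(pn) {
    x <- cas_table[[pn]]
    se <- stats::sd(x) / sqrt(length(x))
    data.frame(parameter = pn, mean = mean(x),
               ci_low = mean(x) - stats::qnorm(0.975) * se,
               ci_high = mean(x) + stats::qnorm(0.975) * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a human-readable run report
#'
#' Prints the cohort CAS table and the per-predictor SEXIT table, and
#' (when `ggplot2` is installed and `plot_dir` is given) writes RRi
#' trajectory plots with fitted curves and posterior density plots with
#' ROPE shading.
#'
#' @param result Output of [run_pipeline()].
#' @param recordings Optional list of the (cleaned) recordings for the
#'   trajectory panels.
#' @param plot_dir Optional directory for figures.
#' @return Invisibly, a list with the two tables.
#' @export
cas_report <- function(result, recordings = NULL, plot_dir = NULL) {
  cohort <- cas_cohort_table(result$cas_table)
  cat("Cohort CAS parameters (mean [95% CI]):\n")
  for (i in seq_len(nrow(cohort)))
    cat(sprintf("  %-6s %9.3f [%9.3f, %9.3f]\n", cohort$parameter[i],
                cohort$mean[i], cohort$ci_low[i], cohort$ci_high[i]))
  sx <- result$sexit
  sx <- sx[!grepl(":intercept$", sx$coefficient), , drop = FALSE]
  cat("\nSEXIT summary (standardized effects):\n")
  for (i in seq_len(nrow(sx)))
    cat(sprintf("  %-28s ES %6.2f [%6.2f, %6.2f]  pd %5.1f%%  ps %5.1f%%\n",
                sx$coefficient[i], sx$median[i], sx$hdi_low[i],
                sx$hdi_high[i], 100 * sx$pd[i], 100 * sx$ps[i]))

  if (!is.null(plot_dir) && requireNamespace("ggplot2", quietly = TRUE)) {
    dir.create(plot_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(recordings) && length(recordings)) {
      rec <- recordings[[1L]]
      est <- result$cas_table[result$cas_table$subject_id == rec$subject_id, ]
      if (nrow(est) == 1L) {
        grid <- seq(min(rec$time), max(rec$time), length.out = 400)
        p <- as_cas_parameters(unlist(est[1, cas_par_names()]))
        df <- data.frame(time = rec$time, rri = rec$rri, masked = rec$mask)
        fit_df <- data.frame(time = grid, rri = cas_curve(grid, p))
        gg <- ggplot2::ggplot(df, ggplot2::aes(x = time, y = rri)) +
          ggplot2::geom_point(ggplot2::aes(colour = masked), size = 0.4) +
          ggplot2::geom_line(data = fit_df, colour = "red") +
          ggplot2::labs(x = "time (min)", y = "RRi (ms)",
                        title = paste("CAS fit:", rec$subject_id))
        ggplot2::ggsave(file.path(plot_dir, "trajectory_fit.png"), gg,
                        width = 7, height = 4, dpi = 120)
      }
    }
    dd <- result$draws$draws
    eff_cols <- colnames(dd)[!grepl(":(sigma|intercept)$", colnames(dd))]
    long <- data.frame(
      coefficient = rep(eff_cols, each = nrow(dd)),
      value = as.numeric(dd[, eff_cols]))
    gg2 <- ggplot2::ggplot(long, ggplot2::aes(x = value)) +
      ggplot2::annotate("rect", xmin = -0.1, xmax = 0.1, ymin = -Inf,
                        ymax = Inf, alpha = 0.2, fill = "grey40") +
      ggplot2::geom_density(fill = "steelblue", alpha = 0.5) +
      ggplot2::facet_wrap(~coefficient, scales = "free") +
      ggplot2::labs(x = "standardized effect", y = "posterior density")
    ggplot2::ggsave(file.path(plot_dir, "posterior_densities.png"), gg2,
                    width = 12, height = 10, dpi = 110)
  }
  invisible(list(cohort = cohort, sexit = sx))
}
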