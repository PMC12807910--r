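# Canonical trial-table file format: comma-separated, header row, UTF-8.
# Required columns: participant, experiment (1|2), condition (closed
# vocabulary), soa_ms (signed, on the design grid), probe_first (0|1).
# Optional: stimulus_color, ratio_difficulty, query_correct, sal_used,
# is_query_trial, block, careless_truth.

.known_conditions <- c("BlueBlue", "RedRed", "BlueRed",
                       "2correct", "2false", "1each")
.required_cols <- c("participant", "experiment", "condition", "soa_ms",
                    "probe_first")

#' Write a trial table to the canonical CSV format
#'
#' @param trials trial table data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(.required_cols, names(trials))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a canonical trial table
#'
#' Validates the schema (required columns, closed condition vocabulary,
#' binary responses) and snaps `soa_ms` values onto the known design grid:
#' any value within `tolerance` ms of a grid point (e.g. a rounded one-frame
#' SOA of 16.67 or 17) is normalized to the exact grid value, including the
#' exact 50/3 frame duration.
#'
#' @param path CSV file path.
#' @param soa_grid numeric grid to normalize onto; default the one-frame
#'   design grid.
#' @param tolerance snap tolerance in ms (default 0.5, half a ms; well below
#'   the one-frame grid spacing).
#' @return validated trial table.
#' @export
read_trials <- function(path,
                        soa_grid = c(-100, -50, -FRAME_MS, 0, FRAME_MS,
                                     50, 100),
                        tolerance = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  if (nrow(trials) == 0L) stop("empty trial table: ", path)
  missing_cols <- setdiff(.required_cols, names(trials))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad_cond <- setdiff(unique(trials$condition), .known_conditions)
  if (length(bad_cond)) {
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "))
  }
  if (!all(trials$probe_first %in% c(0L, 1L))) {
    stop("probe_first must be 0 or 1")
  }
  if (!all(trials$experiment %in% c(1L, 2L))) {
    stop("experiment must be 1 or 2")
  }
  d <- abs(outer(trials$soa_ms, soa_grid, "-"))
  nearest <- apply(d, 1, which.min)
  off <- d[cbind(seq_len(nrow(trials)), nearest)]
  if (any(off > tolerance)) {
    stop(sprintf("soa_ms values off the design grid by more than %g ms: %s",
                 tolerance,
                 paste(unique(trials$soa_ms[off > tolerance]),
                       collapse = ", ")))
  }
  trials$soa_ms <- soa_grid[nearest]
  trials
}

#' Export posterior draws of the headline quantities as delimited text
#'
#' Long format with named dimensions (`chain`, `draw`, `quantity`,
#' optionally `participant`) so the container is self-describing.
#'
#' @param fit a `tvatoj_fit`.
#' @param path output CSV path.
#' @param quantities population-level quantity labels to export.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path,
                            quantities = c("population_C", "sample_mean_C",
                                           "mean_w")) {
  n_it <- nrow(fit$C_mu); n_ch <- ncol(fit$C_mu)
  blocks <- lapply(quantities, function(q) {
    d <- posterior_draws(fit, q)  # pooled, chain-major
    data.frame(chain = rep(seq_len(n_ch), each = n_it),
               draw = rep(seq_len(n_it), n_ch),
               quantity = q, value = d)
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Resolved run configuration for provenance
#'
#' Collects the settings that determine a run's output so they can be
#' serialized next to every results artifact.
#'
#' @param seed master seed.
#' @param fit a [fit_config()].
#' @param hdi_mass HDI mass.
#' @param rope_c,rope_w [rope_spec()]s for capacity (Hz) and weight
#'   contrasts.
#' @param exclusion_alpha familywise alpha of the careless-exclusion rule.
#' @return named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, fit = fit_config(), hdi_mass = 0.95,
                       rope_c = rope_spec(), rope_w = rope_spec_weight(),
                       exclusion_alpha = 0.05) {
  structure(list(seed = as.integer(seed), fit = fit, hdi_mass = hdi_mass,
                 rope_c = rope_c, rope_w = rope_w,
                 exclusion_alpha = exclusion_alpha,
                 r_version = as.character(getRversion()),
                 package_version = as.character(
                   utils::packageVersion("tvatoj"))),
            class = "run_config")
}

#' Serialize a run configuration as plain-text key-value lines
#'
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- c(
    sprintf("seed=%d", config$seed),
    sprintf("fit.profile=%s", config$fit$profile),
    sprintf("fit.chains=%d", config$fit$chains),
    sprintf("fit.tuning_draws=%d", config$fit$tuning_draws),
    sprintf("fit.posterior_draws=%d", config$fit$posterior_draws),
    sprintf("hdi_mass=%g", config$hdi_mass),
    sprintf("rope_c=(%g,%g]", config$rope_c$lower, config$rope_c$upper),
    sprintf("rope_w=(%g,%g]", config$rope_w$lower, config$rope_w$upper),
    sprintf("exclusion_alpha=%g", config$exclusion_alpha),
    sprintf("r_version=%s", config$r_version),
    sprintf("package_version=%s", config$package_version))
  writeLines(lines, path)
  invisible(path)
}
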