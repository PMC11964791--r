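study_record_columns <- function() {
  c("study_id", "n", "mean_age", "sleep_min", "sed_min", "lpa_min",
    "mvpa_min", "outcome_name", "outcome_scale", "mean_outcome",
    "behavior", "beta1", "se", "ci_low", "ci_high", "p_value",
    "quality_pct")
}

#' Read and validate a study-record table
#'
#' One row per study x behavior. Compositions whose printed parts do not
#' sum to 1440 min (as geometric means generally do not) are closed to
#' 1440 with a message. Rows violating an invariant are reported with
#' their line number; any violation aborts the read.
#'
#' Validated invariants: full schema header; no duplicate
#' (study_id, behavior); behavior labels known; n >= 1; mean age within
#' [3, 18]; positive composition parts; outcome_scale linear/log with
#' mean_outcome present for log; exactly one uncertainty representation
#' per coefficient among se, (ci_low, ci_high), p_value — p-values must
#' be exact numbers, so inequality strings such as "<0.001" fail the
#' numeric schema rather than being converted.
#'
#' @param path CSV file path.
#' @return Validated data frame of study records (compositions closed).
#' @export
read_study_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(study_record_columns(), names(df))
  if (length(miss))
    stop("schema mismatch in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  validate_study_records(df, source = path)
}

#' Validate an in-memory study-record table
#' @param records Data frame with the [read_study_records()] schema.
#' @param source Label used in diagnostics.
#' @return The validated records (compositions closed to 1440).
#' @export
validate_study_records <- function(records, source = "records") {
  df <- records
  num_cols <- setdiff(study_record_columns(),
                      c("study_id", "outcome_name", "outcome_scale",
                        "behavior"))
  problems <- character()
  flag <- function(i, msg)
    problems <<- c(problems, sprintf("row %d: %s", i, msg))

  for (v in num_cols) {
    if (!is.numeric(df[[v]])) {
      bad <- which(!is.na(df[[v]]) & is.na(suppressWarnings(
        as.numeric(df[[v]]))))
      for (i in bad) flag(i, sprintf(
        "column '%s' has non-numeric value '%s' (inequality-censored values are not converted)",
        v, df[[v]][i]))
      df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
    }
  }
  dup <- duplicated(df[, c("study_id", "behavior")])
  for (i in which(dup))
    flag(i, sprintf("duplicate (study_id, behavior) = (%s, %s)",
                    df$study_id[i], df$behavior[i]))

  cols <- unname(comp_columns())
  closed_any <- FALSE
  for (i in seq_len(nrow(df))) {
    if (!df$behavior[i] %in% behaviors())
      flag(i, paste0("unknown behavior '", df$behavior[i], "'"))
    if (!is.finite(df$n[i]) || df$n[i] < 1)
      flag(i, "sample size n must be >= 1")
    if (!is.finite(df$mean_age[i]) || df$mean_age[i] < 3 ||
          df$mean_age[i] > 18)
      flag(i, "mean_age outside the eligible range [3, 18] years")
    parts <- as.numeric(df[i, cols])
    if (any(!is.finite(parts)) || any(parts <= 0)) {
      flag(i, "composition parts must be strictly positive")
    } else {
      if (abs(sum(parts) - day_minutes()) > 1e-9 * day_minutes())
        closed_any <- TRUE
      df[i, cols] <- close_composition(parts)
    }
    if (!df$outcome_scale[i] %in% c("linear", "log"))
      flag(i, "outcome_scale must be 'linear' or 'log'")
    else if (df$outcome_scale[i] == "log" && !is.finite(df$mean_outcome[i]))
      flag(i, "log-scale outcome requires mean_outcome")
    if (!is.finite(df$beta1[i]))
      flag(i, "beta1 is missing")
    has <- c(se = is.finite(df$se[i]),
             ci = is.finite(df$ci_low[i]) && is.finite(df$ci_high[i]),
             p = is.finite(df$p_value[i]))
    if (sum(has) != 1L)
      flag(i, paste0("exactly one uncertainty representation required ",
                     "(se, ci_low+ci_high, or p_value); found ", sum(has)))
    else if (has[["ci"]] && df$ci_high[i] <= df$ci_low[i])
      flag(i, "ci_high must exceed ci_low")
    else if (has[["se"]] && df$se[i] <= 0)
      flag(i, "se must be positive")
    else if (has[["p"]] && (df$p_value[i] <= 0 || df$p_value[i] >= 1))
      flag(i, "p_value must lie strictly in (0, 1)")
  }
  if (length(problems))
    stop("invalid study records in ", source, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  if (closed_any)
    message("closed composition(s) to ", day_minutes(),
            " min/day in ", source)
  df
}

#' Read an individual-level study dataset
#'
#' @param path CSV with columns `study_id`, `sleep_min`, `sed_min`,
#'   `lpa_min`, `mvpa_min`, `outcome`, then covariate columns.
#' @return Data frame.
#' @export
read_individual_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", unname(comp_columns()), "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema mismatch in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

# Serialize a table with numbers at 10 significant digits (bit-stable
# regression outputs regardless of options(digits)).
write_table <- function(df, path) {
  out <- df
  for (v in names(out))
    if (is.numeric(out[[v]]) && !is.integer(out[[v]]))
      out[[v]] <- formatC(out[[v]], digits = 10, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Defaults reproduce the reference analysis settings: spline knots at
#' ages 5, 10 and 15 years; meta-regression based on the 30-minute
#' reallocation; meta-regression gated at 10 effect estimates; pooling
#' requires at least 2 studies; reallocation grid +-10..60 min in 10-min
#' steps.
#'
#' @param records Study-record data frame, or a CSV path.
#' @param output_dir Directory for output tables.
#' @param behaviors_list Behaviors to analyze (default all four).
#' @param outcomes Outcomes to analyze (default: all present).
#' @param grid Reallocation grid; built from `grid_sign` when `NULL`.
#' @param grid_sign `"symmetric"` or `"positive"`.
#' @param knots Meta-regression spline knots (years).
#' @param basis_delta Reallocation (minutes) on which meta-regression is
#'   based.
#' @param gate Minimum effects for meta-regression.
#' @param min_studies Minimum studies per pooled analysis.
#' @param se_p_mode Quantile family for p-value inversion.
#' @param seed Integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(records, output_dir,
                            behaviors_list = behaviors(),
                            outcomes = NULL, grid = NULL,
                            grid_sign = "symmetric",
                            knots = c(5, 10, 15), basis_delta = 30,
                            gate = 10L, min_studies = 2L,
                            se_p_mode = "normal", seed = 1L) {
  if (is.null(grid)) grid <- default_grid(grid_sign)
  structure(list(records = records, output_dir = output_dir,
                 behaviors = behaviors_list, outcomes = outcomes,
                 grid = grid, knots = knots, basis_delta = basis_delta,
                 gate = gate, min_studies = min_studies,
                 se_p_mode = se_p_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full meta-analytic pipeline
#'
#' Computes per-study effect curves, pools every (outcome, behavior,
#' delta) satisfying the at-least-two-studies rule, runs the age-spline
#' and quality meta-regressions per behavior where the effect-count gate
#' passes, and writes `effects.csv`, `pooled.csv`, `metareg.csv`,
#' `metareg_curves.csv` and `manifest.json` to the output directory.
#' Outputs are staged and only moved into place on success, so a failed
#' run leaves no partial tables. Given identical inputs the outputs are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory result tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- config$records
  if (is.character(records)) records <- read_study_records(records)
  else records <- validate_study_records(records)
  outcomes <- config$outcomes %||% unique(records$outcome_name)

  effects <- list(); pooled <- list(); metareg <- list(); curves <- list()
  for (oc in outcomes) {
    for (b in config$behaviors) {
      rows <- records[records$outcome_name == oc & records$behavior == b, ,
                      drop = FALSE]
      if (nrow(rows) < config$min_studies) {
        message("skipping ", oc, " x ", b, ": at least ",
                config$min_studies, " studies required (", nrow(rows),
                " available)")
        next
      }
      eff <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
        rec <- as.list(rows[i, ])
        comp <- close_composition(unlist(rec[unname(comp_columns())]))
        feasible <- config$grid[config$grid > -comp[[b]] &
                                  config$grid < day_minutes() - comp[[b]]]
        if (length(feasible) < length(config$grid))
          message("study ", rec$study_id, " x ", b,
                  ": dropped infeasible delta(s) ",
                  paste(setdiff(config$grid, feasible), collapse = ", "))
        study_effect_curve(rec, b, feasible, config$se_p_mode)
      }))
      effects[[paste(oc, b)]] <- eff
      pooled[[paste(oc, b)]] <-
        dose_response(rows, b, oc, config$grid, config$min_studies,
                      config$se_p_mode)

      basis <- eff[eff$delta_min == config$basis_delta, , drop = FALSE]
      if (nrow(basis) >= config$gate) {
        ages <- rows$mean_age[match(basis$study_id, rows$study_id)]
        qual <- rows$quality_pct[match(basis$study_id, rows$study_id)]
        mr <- meta_regress(basis$estimate, basis$variance, ages,
                           knots = config$knots, gate = config$gate)
        qr_row <- data.frame(outcome_name = oc, behavior = b,
                             moderator = "age_rcs",
                             q_moderator = mr$q_moderator, q_df = mr$q_df,
                             p_moderator = mr$p_moderator,
                             tau2_residual = mr$tau2_residual,
                             stringsAsFactors = FALSE)
        ms <- tryCatch(
          moderator_scalar(basis$estimate, basis$variance, qual,
                           gate = config$gate),
          error = function(e) NULL)
        if (!is.null(ms))
          qr_row <- rbind(qr_row, data.frame(
            outcome_name = oc, behavior = b, moderator = "quality_linear",
            q_moderator = ms$q_moderator, q_df = ms$q_df,
            p_moderator = ms$p_moderator,
            tau2_residual = ms$tau2_residual, stringsAsFactors = FALSE))
        metareg[[paste(oc, b)]] <- qr_row
        cv <- mr$curve
        cv$outcome_name <- oc; cv$behavior <- b
        curves[[paste(oc, b)]] <- cv
      } else {
        message("skipping meta-regression for ", oc, " x ", b,
                ": fewer than ", config$gate, " effect estimates (",
                nrow(basis), ")")
      }
    }
  }
  if (!length(pooled))
    stop("pipeline produced no poolable analyses", call. = FALSE)

  result <- list(effects = do.call(rbind, unname(effects)),
                 pooled = do.call(rbind, unname(pooled)),
                 metareg = if (length(metareg))
                   do.call(rbind, unname(metareg)) else NULL,
                 metareg_curves = if (length(curves))
                   do.call(rbind, unname(curves)) else NULL)
  rownames(result$effects) <- rownames(result$pooled) <- NULL

  stage <- file.path(tempfile("codameta_stage"))
  dir.create(stage, recursive = TRUE)
  write_table(result$effects, file.path(stage, "effects.csv"))
  write_table(result$pooled, file.path(stage, "pooled.csv"))
  if (!is.null(result$metareg)) {
    write_table(result$metareg, file.path(stage, "metareg.csv"))
    write_table(result$metareg_curves,
                file.path(stage, "metareg_curves.csv"))
  }
  manifest <- list(
    package = "codameta",
    version = as.character(utils::packageVersion("codameta")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    settings = config[c("behaviors", "outcomes", "grid", "knots",
                        "basis_delta", "gate", "min_studies",
                        "se_p_mode")],
    n_records = nrow(records))
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  for (f in list.files(stage))
    file.copy(file.path(stage, f), file.path(config$output_dir, f),
              overwrite = TRUE)
  unlink(stage, recursive = TRUE)
  invisible(result)
}
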