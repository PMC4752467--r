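#' Configuration for a full evaluation run
#'
#' A run is a pure function of (inputs, config, seed): the same config on the
#' same inputs reproduces identical outputs. Either `input` (a directory of
#' peak-table / DPPH CSVs) or `spec` (a [synthetic_spec()]) supplies the data.
#'
#' @param out_dir Output directory for the report bundle.
#' @param input Optional directory containing `peak_tables.csv` and
#'   `dpph.csv` (long formats written by [write_peak_tables()] /
#'   [run_pipeline()]'s simulate step).
#' @param spec Optional [synthetic_spec()]; used when `input` is NULL.
#' @param rt_tolerance Common-peak matching tolerance in minutes.
#' @param grade_table_path Optional CSV of grade bands; the built-in table is
#'   used (with a logged note) when NULL or missing.
#' @param cv_folds Cross-validation folds for the latent model.
#' @param n_components Predictive components for the PLS model.
#' @param exclude_outliers Exclude PCA-flagged batches from the
#'   fingerprint-efficacy model? Flagging is always reported; exclusion only
#'   happens when this is explicitly TRUE.
#' @param seed Integer seed controlling every random choice.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, input = NULL, spec = NULL, rt_tolerance = 0.2,
                       grade_table_path = NULL, cv_folds = 7,
                       n_components = 2, exclude_outliers = FALSE, seed = 1) {
  if (is.null(input) && is.null(spec)) {
    fq_stop("supply either 'input' (directory) or 'spec' (synthetic_spec)")
  }
  structure(list(out_dir = out_dir, input = input, spec = spec,
                 rt_tolerance = rt_tolerance,
                 grade_table_path = grade_table_path,
                 cv_folds = cv_folds, n_components = n_components,
                 exclude_outliers = isTRUE(exclude_outliers),
                 seed = as.integer(seed)),
            class = "run_config")
}

log_line <- function(log, fmt, ...) c(log, sprintf(fmt, ...))

#' Run the full fingerprint quality-consistency pipeline
#'
#' Orchestrates: fingerprint assembly (synthetic generation or reading +
#' common-peak matching) -> per-wavelength SQFM evaluation and grading ->
#' multi-wavelength integration -> marker percent contents -> PCA outlier
#' screen -> off-line DPPH IC50 -> PLS fingerprint-efficacy model. Writes a
#' report bundle to `config$out_dir`:
#' `sqfm_wavelength.csv`, `sqfm_integrated.csv`, `marker_table.csv`,
#' `ic50.csv`, `model.json` and `run_log.txt` (seed, config hash and every
#' default in effect). Rounding is applied only at render time; the returned
#' object keeps full precision.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all intermediate results and the paths of
#'   the written artifacts.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) fq_stop("'config' must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  stage <- "setup"
  result <- tryCatch({
    # ---- inputs ----
    stage <- "input"
    if (!is.null(config$input)) {
      tabs <- read_peak_tables(file.path(config$input, "peak_tables.csv"))
      wls <- vapply(tabs, function(t) t$wavelength, integer(1))
      matrices <- lapply(split(tabs, wls), match_common_peaks,
                         rt_tolerance = config$rt_tolerance)
      log <- log_line(log, "INFO input: %d peak tables from %s (rt_tolerance = %g min)",
                      length(tabs), config$input, config$rt_tolerance)
      dpph_path <- file.path(config$input, "dpph.csv")
      dpph <- if (file.exists(dpph_path)) utils::read.csv(dpph_path) else NULL
      activity <- NULL
    } else {
      fp <- generate_fingerprints(config$spec)
      matrices <- fp$matrices
      activity <- generate_activity(config$spec, fp)
      dpph <- activity$absorbance
      log <- log_line(log, "INFO input: synthetic spec, %d batches, seed %d",
                      config$spec$n_batches, config$spec$seed)
    }

    # ---- grade table ----
    stage <- "grade table"
    if (!is.null(config$grade_table_path) &&
        file.exists(config$grade_table_path)) {
      grades <- read_grade_table(config$grade_table_path)
      log <- log_line(log, "INFO grade table: %s", config$grade_table_path)
    } else {
      grades <- default_grade_table()
      if (!is.null(config$grade_table_path)) {
        warning("grade table file not found; using the built-in bands")
        log <- log_line(log,
          "WARN grade table '%s' not found; falling back to built-in bands",
          config$grade_table_path)
      } else {
        log <- log_line(log, "INFO grade table: built-in reconstructed bands")
      }
    }

    # ---- SQFM ----
    stage <- "sqfm"
    per_wl <- do.call(rbind, lapply(matrices, sqfm_evaluate_matrix,
                                    grade_table = grades))
    rownames(per_wl) <- NULL
    integrated <- do.call(rbind, lapply(split(per_wl, per_wl$batch_id),
      function(d) {
        r <- integrate_channels(d, grade_table = grades)
        data.frame(batch_id = r$batch_id, s_m_prime = r$s_m_prime,
                   p_m_prime = r$p_m_prime, alpha_prime = r$alpha_prime,
                   grade = r$grade, channel_count = r$channel_count)
      }))
    first <- matrices[[1]]
    integrated <- integrated[match(first$batch_ids, integrated$batch_id), ]
    utils::write.csv(format_sqfm(per_wl),
                     file.path(config$out_dir, "sqfm_wavelength.csv"),
                     row.names = FALSE)
    utils::write.csv(format_sqfm(integrated),
                     file.path(config$out_dir, "sqfm_integrated.csv"),
                     row.names = FALSE)
    log <- log_line(log, "INFO sqfm: %d batches x %d channels evaluated",
                    length(first$batch_ids), length(matrices))

    # ---- marker-style percent contents (marker-class peaks, first channel) ----
    stage <- "markers"
    marker_idx <- if (!is.null(config$spec)) {
      which(config$spec$channels[[1]]$classes != "other")
    } else {
      seq_len(min(7L, length(first$peak_ids)))
    }
    marker_areas <- first$areas[, marker_idx, drop = FALSE]
    pc <- percent_contents(marker_areas)
    marker_tab <- data.frame(batch_id = first$batch_ids,
                             round_half_up(pc$percent, 1),
                             p7c = round_half_up(pc$p7c, 1),
                             check.names = FALSE)
    utils::write.csv(marker_tab, file.path(config$out_dir, "marker_table.csv"),
                     row.names = FALSE)
    log <- log_line(log, "INFO markers: %d marker peaks; ND treated as 0 in summaries",
                    ncol(marker_areas))

    # ---- PCA outlier screen ----
    stage <- "pca"
    pca <- pca_screen(first$areas, k = min(2L, nrow(first$areas) - 1L),
                      confidence = 0.95)
    flagged <- names(pca$outlier_flags)[pca$outlier_flags]
    log <- log_line(log, "INFO pca: flagged [%s] at 95%%; exclude_outliers = %s",
                    paste(flagged, collapse = ", "), config$exclude_outliers)

    # ---- DPPH ----
    stage <- "dpph"
    ic50_tab <- NULL
    if (!is.null(dpph)) {
      ic50_tab <- do.call(rbind, lapply(split(dpph, dpph$batch_id),
        function(d) {
          inh <- inhibition(d$a_control, d$a_sample)
          r <- estimate_ic50(d$concentration, inh, batch_id = d$batch_id[1])
          data.frame(batch_id = r$batch_id, ic50 = r$ic50,
                     extrapolated = r$extrapolated)
        }))
      ic50_tab <- ic50_tab[match(first$batch_ids, ic50_tab$batch_id), ]
      utils::write.csv(ic50_tab, file.path(config$out_dir, "ic50.csv"),
                       row.names = FALSE)
      log <- log_line(log, "INFO dpph: IC50 estimated for %d batches",
                      nrow(ic50_tab))
    }

    # ---- fingerprint-efficacy model ----
    stage <- "model"
    model <- NULL
    if (!is.null(ic50_tab)) {
      y <- 1 / ic50_tab$ic50
      Xm <- first$areas
      if (config$exclude_outliers && length(flagged)) {
        keep <- !(rownames(Xm) %in% flagged)
        Xm <- Xm[keep, , drop = FALSE]
        y <- y[keep]
        log <- log_line(log, "INFO model: excluded %s as confirmed outliers",
                        paste(flagged, collapse = ", "))
      }
      model <- suppressWarnings(
        fit_pls(Xm, y, n_components = config$n_components,
                cv_folds = config$cv_folds, seed = config$seed))
      jsonlite::write_json(
        list(kind = model$kind, n_predictive = model$n_predictive,
             n_orthogonal = model$n_orthogonal,
             coefficients = as.list(model$coefficients),
             r2 = model$r2, q2 = model$q2, rmsee = model$rmsee,
             rmsecv = model$rmsecv, cv_folds = model$cv_folds,
             seed = model$seed,
             cv_partition = as.integer(model$cv_partition),
             scale_mode = model$scale_mode),
        file.path(config$out_dir, "model.json"),
        auto_unbox = TRUE, digits = NA)
      log <- log_line(log,
        "INFO model: PLS %d comp, uv scaling, %d-fold CV, R2=%.4f Q2=%.4f",
        model$n_predictive, config$cv_folds, model$r2, model$q2)
    }

    # ---- run log ----
    stage <- "log"
    cfg_json <- file.path(config$out_dir, "config.json")
    cfg_serializable <- config
    cfg_serializable$spec <- if (!is.null(config$spec)) {
      list(n_batches = config$spec$n_batches, seed = config$spec$seed,
           content_scale_sd = config$spec$content_scale_sd,
           peak_noise_cv = config$spec$peak_noise_cv)
    }
    jsonlite::write_json(unclass(cfg_serializable), cfg_json,
                         auto_unbox = TRUE, digits = NA, null = "null")
    log <- c(sprintf("fingerqc %s | R %s | seed %d | config md5 %s",
                     as.character(utils::packageVersion("fingerqc")),
                     paste(R.version$major, R.version$minor, sep = "."),
                     config$seed, unname(tools::md5sum(cfg_json))),
             log)
    writeLines(log, file.path(config$out_dir, "run_log.txt"))

    list(matrices = matrices, sqfm = per_wl, integrated = integrated,
         markers = marker_tab, pca = pca, ic50 = ic50_tab, model = model,
         activity = activity, log = log,
         paths = file.path(config$out_dir,
                           c("sqfm_wavelength.csv", "sqfm_integrated.csv",
                             "marker_table.csv", "ic50.csv", "model.json",
                             "run_log.txt")))
  }, fingerqc_validation_error = function(e) {
    fq_stop(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
  }, fingerqc_computation_error = function(e) {
    fq_compute_stop(sprintf("pipeline stage '%s' failed: %s", stage,
                            conditionMessage(e)))
  })
  invisible(result)
}

cli_args_value <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1] == length(args)) fq_stop(sprintf("flag %s needs a value", flag))
  args[i[1] + 1L]
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `sqfm` (evaluate a
#' fingerprint-matrix CSV), `run` (full pipeline on a synthetic spec or input
#' directory). Invoke as
#' `Rscript -e 'fingerqc::fingerqc_cli()' simulate --out dir [--seed 1]`.
#' Exit status: 0 on success, 2 on validation error, 3 on computation error.
#'
#' @param args Command-line arguments (default: those after `--args`).
#' @return The exit status, invisibly (call `quit(status = )` with it in
#'   scripts).
#' @export
fingerqc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) fq_stop("usage: fingerqc <simulate|sqfm|run> [flags]")
    cmd <- args[1]; rest <- args[-1]
    seed <- as.integer(cli_args_value(rest, "--seed", "1"))
    out <- cli_args_value(rest, "--out")
    if (is.null(out)) fq_stop("--out <path> is required")
    if (cmd == "simulate") {
      spec <- synthetic_spec(seed = seed)
      fp <- generate_fingerprints(spec)
      act <- generate_activity(spec, fp)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_peak_tables(as_peak_tables(spec, fp),
                        file.path(out, "peak_tables.csv"))
      utils::write.csv(act$absorbance, file.path(out, "dpph.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(scales = as.list(fp$truth$scales),
                                outlier_batches = fp$truth$outlier_batches,
                                ic50 = as.list(act$ic50), seed = seed),
                           file.path(out, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      message("simulated dataset written to ", out)
    } else if (cmd == "sqfm") {
      mpath <- cli_args_value(rest, "--matrix")
      if (is.null(mpath)) fq_stop("--matrix <csv> is required")
      fm <- read_fingerprint_matrix(mpath)
      gt <- cli_args_value(rest, "--grades")
      grades <- if (is.null(gt)) default_grade_table() else read_grade_table(gt)
      res <- sqfm_evaluate_matrix(fm, grade_table = grades)
      utils::write.csv(format_sqfm(res), out, row.names = FALSE)
      message("SQFM report written to ", out)
    } else if (cmd == "run") {
      input <- cli_args_value(rest, "--input")
      cfg <- if (is.null(input)) {
        run_config(out_dir = out, spec = synthetic_spec(seed = seed),
                   seed = seed)
      } else {
        run_config(out_dir = out, input = input, seed = seed)
      }
      run_pipeline(cfg)
      message("report bundle written to ", out)
    } else {
      fq_stop(sprintf("unknown subcommand '%s'", cmd))
    }
    0L
  },
  fingerqc_validation_error = function(e) {
    message("validation error: ", conditionMessage(e)); 2L
  },
  fingerqc_computation_error = function(e) {
    message("computation error: ", conditionMessage(e)); 3L
  },
  error = function(e) {
    message("computation error: ", conditionMessage(e)); 3L
  })
  invisible(status)
}
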