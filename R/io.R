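## CSV writing with a schema header comment; all pipeline outputs use this so
## schemas are self-describing and stable across runs
.write_schema_csv <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# columns: ", paste(names(df), collapse = ", ")), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_schema_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write paired-haul tables
#'
#' Writes the two-file interchange format: a counts CSV with one row per
#' (haul_id, class_lower) holding \code{test_count} and \code{control_count},
#' and a metadata CSV with one row per haul holding \code{mesh_type},
#' \code{mesh_size_mm}, \code{catch_weight_kg}, \code{sea_state},
#' \code{side}, \code{qt}, \code{qc}.
#'
#' @param hauls list of \code{\link{paired_haul}} objects.
#' @param counts_path,meta_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_haul_tables <- function(hauls, counts_path, meta_path) {
  counts <- do.call(rbind, lapply(hauls, function(h) {
    data.frame(haul_id = h$haul_id, class_lower = h$class_lower,
               test_count = h$test_count, control_count = h$control_count,
               stringsAsFactors = FALSE)
  }))
  meta <- do.call(rbind, lapply(hauls, function(h) {
    data.frame(haul_id = h$haul_id, mesh_type = h$covariates$mesh_type,
               mesh_size_mm = h$covariates$m,
               catch_weight_kg = h$covariates$w,
               sea_state = h$covariates$s, side = h$covariates$p,
               qt = h$qt, qc = h$qc, stringsAsFactors = FALSE)
  }))
  .write_schema_csv(counts, counts_path)
  .write_schema_csv(meta, meta_path)
  invisible(c(counts = counts_path, meta = meta_path))
}

#' Read paired-haul tables
#'
#' Reads and validates the two-file interchange format written by
#' \code{\link{write_haul_tables}}. Violations are reported with the
#' offending haul and row: negative counts, subsampling factors outside
#' (0, 1], mismatched test/control grids, hauls present in only one file.
#'
#' @param counts_path,meta_path input file paths.
#' @return list of \code{\link{paired_haul}} objects, in metadata order.
#' @export
read_haul_tables <- function(counts_path, meta_path) {
  for (p in c(counts_path, meta_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  counts <- .read_schema_csv(counts_path)
  meta <- .read_schema_csv(meta_path)
  need_c <- c("haul_id", "class_lower", "test_count", "control_count")
  need_m <- c("haul_id", "mesh_type", "mesh_size_mm", "catch_weight_kg",
              "sea_state", "side", "qt", "qc")
  miss <- setdiff(need_c, names(counts))
  if (length(miss)) stop(counts_path, ": missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(need_m, names(meta))
  if (length(miss)) stop(meta_path, ": missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(counts$test_count < 0 | counts$control_count < 0)
  if (length(bad)) {
    stop(counts_path, ": negative count in row ", bad[1], " (haul ",
         counts$haul_id[bad[1]], ", class ", counts$class_lower[bad[1]], ")",
         call. = FALSE)
  }
  bad <- which(!(meta$qt > 0 & meta$qt <= 1 & meta$qc > 0 & meta$qc <= 1))
  if (length(bad)) {
    stop(meta_path, ": qt/qc outside (0, 1] in row ", bad[1], " (haul ",
         meta$haul_id[bad[1]], ")", call. = FALSE)
  }
  only_counts <- setdiff(unique(counts$haul_id), meta$haul_id)
  only_meta <- setdiff(meta$haul_id, unique(counts$haul_id))
  if (length(only_counts) || length(only_meta)) {
    stop("haul id mismatch between files: ",
         paste(c(only_counts, only_meta), collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$haul_id[i]
    ci <- counts[counts$haul_id == id, , drop = FALSE]
    ci <- ci[order(ci$class_lower), , drop = FALSE]
    if (anyDuplicated(ci$class_lower)) {
      stop(counts_path, ": duplicated length class for haul ", id,
           call. = FALSE)
    }
    paired_haul(haul_id = id, class_lower = ci$class_lower,
                test_count = ci$test_count, control_count = ci$control_count,
                qt = meta$qt[i], qc = meta$qc[i],
                mesh_type = meta$mesh_type[i], mesh_size = meta$mesh_size_mm[i],
                catch_weight = meta$catch_weight_kg[i],
                sea_state = meta$sea_state[i], side = meta$side[i])
  })
}

#' Pooled population structure from control-codend catches
#'
#' Reconstructs the available population length structure by pooling the
#' control-codend counts over hauls, each raised by its subsampling factor
#' (count / qc) — the control codend is assumed non-selective.
#'
#' @param hauls list of \code{\link{paired_haul}} objects.
#' @return data frame \code{class_lower}, \code{count}.
#' @export
pooled_population <- function(hauls) {
  all_l <- sort(unique(unlist(lapply(hauls, `[[`, "class_lower"))))
  count <- numeric(length(all_l))
  for (h in hauls) {
    idx <- match(h$class_lower, all_l)
    count[idx] <- count[idx] + h$control_count / h$qc
  }
  data.frame(class_lower = all_l, count = count)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML pipeline configuration and validates it against the expected
#' schema before any stage runs. See \code{\link{run_pipeline}} for the
#' recognised fields.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config configuration list (as from YAML).
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% "selectivity_out"
  config$mls <- config$mls %||% 50
  config$at <- match.arg(config$at %||% "midpoint", c("midpoint", "lower"))
  config$D_type <- match.arg(config$D_type %||% "full",
                             c("full", "diagonal", "zero"))
  fm <- config$full_model %||% list(L50 = c("m", "m2", "w"),
                                    SR = c("m", "w"), SP = "intercept")
  config$full_model <- fe_structure(L50 = unlist(fm$L50),
                                    SR = unlist(fm$SR), SP = unlist(fm$SP))
  config$forced <- unlist(config$forced) %||% character()
  pg <- config$prediction %||% list()
  pg$mesh_sizes <- unlist(pg$mesh_sizes) %||% c(21, 23, 25, 27, 29)
  pg$r_levels <- unlist(pg$r_levels) %||% seq(5, 95, 5)
  pg$w <- pg$w %||% 35; pg$s <- pg$s %||% 0; pg$p <- pg$p %||% 0
  config$prediction <- pg
  has_input <- !is.null(config$counts_file) && !is.null(config$meta_file)
  if (!has_input && is.null(config$simulate) &&
      !isTRUE(config$use_reference_models)) {
    stop("config must provide input files (counts_file + meta_file), a 'simulate' block, or use_reference_models: true",
         call. = FALSE)
  }
  config
}

#' Run the full selectivity pipeline
#'
#' Sequences the analysis end to end: obtain paired-haul data (read from the
#' configured CSV files, or generate a synthetic experiment), fit every haul
#' by maximum likelihood, run the per-mesh-type Fryer meta-analysis with AICc
#' subset selection, predict mean selectivity over the configured mesh-size
#' grid with retention isolines, and compute usability indicators against the
#' pooled (control-codend) population structure. Each stage writes a
#' schema-commented CSV into \code{out_dir}; a run log records the seed,
#' package version, candidate counts and any excluded hauls with the reason.
#' Outputs are deterministic given the same configuration and seed.
#'
#' Recognised configuration fields: \code{seed}, \code{out_dir},
#' \code{counts_file}/\code{meta_file} (input mode) or \code{simulate}
#' (a list passed to \code{\link{synthetic_truth}}; \code{TRUE} for
#' defaults), \code{full_model} (term lists for L50/SR/SP),
#' \code{forced} (labels never toggled in the enumeration), \code{D_type},
#' \code{prediction} (\code{mesh_sizes}, \code{r_levels}, \code{w}, \code{s},
#' \code{p}), \code{mls}, \code{at}.
#'
#' @param config configuration list or path to a YAML file.
#' @return invisibly, a list with the fitted objects and the written paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  else config <- validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- c("shrimpselect pipeline run",
                 paste0("package_version: ",
                        as.character(utils::packageVersion("shrimpselect"))),
                 paste0("seed: ", config$seed))
  paths <- character()

  ## standalone prediction mode: packaged reference models, no haul data
  if (isTRUE(config$use_reference_models)) {
    models <- reference_codend_models()
    log_lines <- c(log_lines, "models: packaged reference (no haul data)")
    pg <- config$prediction
    for (mt in names(models)) {
      pred <- suppressWarnings(predict(models[[mt]], data.frame(
        m = pg$mesh_sizes, w = pg$w, s = pg$s, p = pg$p)))
      .write_schema_csv(pred, out(paste0("predictions_", mt, ".csv")))
      iso <- suppressWarnings(retention_isolines(
        models[[mt]], pg$mesh_sizes, pg$r_levels, w = pg$w, s = pg$s,
        p = pg$p))
      .write_schema_csv(as.data.frame(iso), out(paste0("isolines_", mt, ".csv")))
      paths <- c(paths, out(paste0("predictions_", mt, ".csv")),
                 out(paste0("isolines_", mt, ".csv")))
    }
    nPop <- generate_population(population_spec(), seed = config$seed)
    ind <- suppressWarnings(indicator_table(
      models, mesh_sizes = pg$mesh_sizes, nPop = nPop, w = pg$w,
      mls = config$mls, at = config$at))
    .write_schema_csv(ind, out("indicators.csv"))
    writeLines(log_lines, out("run_log.txt"))
    paths <- c(paths, out("indicators.csv"), out("run_log.txt"))
    return(invisible(list(models = models, indicators = ind, paths = paths,
                          log = log_lines)))
  }

  ## stage 1: data
  if (!is.null(config$counts_file)) {
    hauls <- read_haul_tables(config$counts_file, config$meta_file)
    log_lines <- c(log_lines, paste0("input: ", config$counts_file))
  } else {
    sim_args <- config$simulate
    truth <- if (isTRUE(sim_args)) synthetic_truth()
             else do.call(synthetic_truth, sim_args)
    exper <- generate_experiment(truth, seed = config$seed)
    hauls <- exper$hauls
    write_haul_tables(hauls, out("haul_counts.csv"), out("haul_meta.csv"))
    .write_schema_csv(exper$truth_record, out("ground_truth.csv"))
    paths <- c(paths, out("haul_counts.csv"), out("haul_meta.csv"),
               out("ground_truth.csv"))
    log_lines <- c(log_lines, paste0("simulated hauls: ", length(hauls)))
  }

  ## stage 2: per-haul fits
  fits <- list()
  for (h in hauls) {
    f <- tryCatch(fit_haul(h), error = function(e) e)
    if (inherits(f, "error")) {
      log_lines <- c(log_lines, paste0("haul ", h$haul_id,
                                       " excluded: ", conditionMessage(f)))
    } else {
      if (!f$valid) {
        log_lines <- c(log_lines, paste0(
          "haul ", h$haul_id, " flagged invalid: ",
          if (!f$converged) "non-convergence"
          else "covariance matrix not positive definite"))
      }
      fits[[length(fits) + 1]] <- f
    }
  }
  if (!length(fits)) stop("[fit-hauls] no haul could be fitted", call. = FALSE)
  tab <- haul_fit_table(fits)
  .write_schema_csv(tab, out("per_haul_fits.csv"))
  paths <- c(paths, out("per_haul_fits.csv"))
  n_poor <- sum(tab$valid & !is.na(tab$p_value) & tab$p_value < 0.05)
  log_lines <- c(log_lines, paste0("hauls fitted: ", nrow(tab),
                                   "; valid: ", sum(tab$valid),
                                   "; p<0.05 retained (overdispersion check applies): ",
                                   n_poor))

  ## stage 3: meta-analysis per mesh type
  models <- list()
  for (mt in unique(tab$mesh_type)) {
    sub <- tab[tab$mesh_type == mt, , drop = FALSE]
    enum <- enumerate_structures(config$full_model, forced = config$forced)
    log_lines <- c(log_lines, paste0("mesh type ", mt, ": ",
                                     enum$n, " candidate structures"))
    sel <- tryCatch(
      select_best_model(sub, enum, D_type = config$D_type),
      error = function(e) stop("[meta] mesh type ", mt, ": ",
                               conditionMessage(e), call. = FALSE))
    models[[mt]] <- sel$best
    .write_schema_csv(sel$ranking, out(paste0("model_ranking_", mt, ".csv")))
    coef_tab <- data.frame(term = names(sel$best$coefficients),
                           value = sel$best$coefficients,
                           se = sel$best$se,
                           ci_lower = sel$best$ci_lower,
                           ci_upper = sel$best$ci_upper)
    coef_tab <- rbind(coef_tab, data.frame(
      term = c("D11", "D22", "D33"), value = diag(sel$best$D),
      se = NA, ci_lower = NA, ci_upper = NA))
    .write_schema_csv(coef_tab, out(paste0("selected_model_", mt, ".csv")))
    paths <- c(paths, out(paste0("model_ranking_", mt, ".csv")),
               out(paste0("selected_model_", mt, ".csv")))
  }

  ## stage 4: predictions and isolines
  pg <- config$prediction
  for (mt in names(models)) {
    pred <- suppressWarnings(predict(models[[mt]], data.frame(
      m = pg$mesh_sizes, w = pg$w, s = pg$s, p = pg$p)))
    .write_schema_csv(pred, out(paste0("predictions_", mt, ".csv")))
    iso <- suppressWarnings(retention_isolines(
      models[[mt]], pg$mesh_sizes, pg$r_levels, w = pg$w, s = pg$s, p = pg$p))
    .write_schema_csv(as.data.frame(iso), out(paste0("isolines_", mt, ".csv")))
    paths <- c(paths, out(paste0("predictions_", mt, ".csv")),
               out(paste0("isolines_", mt, ".csv")))
  }

  ## stage 5: usability indicators on the pooled population
  nPop <- pooled_population(hauls)
  ind <- suppressWarnings(indicator_table(
    models, mesh_sizes = pg$mesh_sizes, nPop = nPop, w = pg$w,
    mls = config$mls, at = config$at))
  .write_schema_csv(ind, out("indicators.csv"))
  paths <- c(paths, out("indicators.csv"))

  writeLines(log_lines, out("run_log.txt"))
  paths <- c(paths, out("run_log.txt"))
  invisible(list(hauls = hauls, haul_fits = tab, models = models,
                 indicators = ind, paths = paths, log = log_lines))
}
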