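#' @keywords internal
"_PACKAGE"

#' Read and validate a subject table
#'
#' Expects a CSV with a header naming the ten tract mTBFA columns by their
#' standard abbreviations (see [tract_names]) plus \code{age} and the four
#' WAIS-III indices \code{PO}, \code{PS}, \code{VC}, \code{WM}; an optional
#' \code{id} column is carried through.  Column matching is case-sensitive;
#' deviating deposited layouts can be mapped with \code{aliases}.
#'
#' Validation: every required column present and numeric, FA values inside
#' [0, 1] (violations are errors naming row and column), age inside
#' \code{age_range}; rows with missing values are dropped listwise with a
#' message.
#'
#' @param path CSV file path.
#' @param aliases named character vector mapping file column names to
#'   canonical names, e.g. \code{c(Age = "age")}.
#' @param age_range declared admissible age range.
#' @return validated data.frame; attribute \code{n_dropped} records the
#'   listwise deletions.
#' @export
read_study_table <- function(path, aliases = NULL, age_range = c(18, 69)) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(aliases)) {
    hit <- colnames(tab) %in% names(aliases)
    colnames(tab)[hit] <- aliases[colnames(tab)[hit]]
  }
  required <- c(tract_names, "age", wais_indices)
  miss <- setdiff(required, colnames(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if ("id" %in% colnames(tab) && anyDuplicated(tab$id))
    stop("duplicated subject ids")
  for (cl in required) {
    v <- tab[[cl]]
    if (is.character(v) || is.factor(v)) {
      v2 <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(!is.na(v) & nzchar(trimws(as.character(v))) & is.na(v2))
      if (length(bad))
        stop("non-numeric value in column '", cl, "', row ", bad[1L])
      tab[[cl]] <- v2
    }
  }
  for (cl in tract_names) {
    bad <- which(!is.na(tab[[cl]]) & (tab[[cl]] < 0 | tab[[cl]] > 1))
    if (length(bad))
      stop("FA out of [0, 1] in column '", cl, "', row ", bad[1L],
           " (value ", tab[[cl]][bad[1L]], ")")
  }
  bad_age <- which(!is.na(tab$age) &
                   (tab$age < age_range[1] | tab$age > age_range[2]))
  if (length(bad_age))
    warning("age outside [", age_range[1], ", ", age_range[2], "] in row ",
            paste(bad_age, collapse = ", "))
  keep <- stats::complete.cases(tab[, required])
  if (any(!keep))
    message(sum(!keep), " row(s) removed by listwise deletion")
  out <- tab[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Run the full watershed analysis pipeline
#'
#' Executes the study workflow on a subject table: one-factor CFA of the
#' four indices, two-factor (fluid/crystallized) CFA, BIC comparison,
#' elastic-net regularized MIMIC path over the lambda grid, BIC model
#' selection, and trajectory export.  A JSON report and a trajectory CSV
#' are written when \code{out_dir} is given.
#'
#' @param table subject table (data.frame, or a CSV path passed through
#'   [read_study_table()]); \code{NULL} simulates one from
#'   \code{sim_config}.
#' @param out_dir output directory (created if needed); \code{NULL}
#'   suppresses file output.
#' @param config a \code{reg_config} for the path stage.
#' @param sim_config a \code{sem_sim_config} used when \code{table} is
#'   \code{NULL}.
#' @param seed seed for the simulation stage.
#' @param verbose print per-stage progress.
#' @return report list: both CFA fits, the BIC comparison, the fitted path
#'   summary, selected lambda and edges; written as \code{report.json} and
#'   \code{trajectories.csv} under \code{out_dir}.
#' @export
run_pipeline <- function(table = NULL, out_dir = NULL,
                         config = reg_config(),
                         sim_config = sem_sim_config(), seed = 1L,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[wmimic] ", ...)
  stage <- "input"
  result <- tryCatch({
    if (is.null(table)) {
      say("simulating subject table (n = ", sim_config$n, ", seed = ",
          seed, ")")
      table <- simulate_subject_table(sim_config, seed = seed)
    } else if (is.character(table)) {
      say("reading subject table from ", table)
      table <- read_study_table(table)
    }
    stage <- "cfa"
    one <- mimic_spec(list(g = wais_indices))
    two <- mimic_spec(list(FI = c("PO", "PS"), CI = c("VC", "WM")))
    say("fitting one-factor CFA (df = ", count_df(one), ")")
    fit1 <- fit_mimic(table, one)
    say("fitting two-factor CFA (df = ", count_df(two), ")")
    fit2 <- fit_mimic(table, two)
    preferred <- if (fit2$bic < fit1$bic) "two_factor" else "one_factor"
    say("BIC comparison: one-factor ", round(fit1$bic, 3),
        " vs two-factor ", round(fit2$bic, 3), " -> ", preferred)
    stage <- "regularized_path"
    wspec <- build_watershed_spec()
    say("fitting elastic-net path over ", length(config$lambda),
        " lambda values")
    path <- fit_path(table, wspec, config)
    i <- path$selected_index
    say("selected lambda = ", round(path$lambda[i], 4), " with ",
        nrow(path$selected_edges), " surviving edge(s)")
    stage <- "export"
    traj <- export_trajectories(path)
    report <- list(
      n = nrow(table), seed = seed,
      one_factor = .fit_report(fit1), two_factor = .fit_report(fit2),
      preferred_measurement_model = preferred,
      selected_lambda = path$lambda[i],
      selected_bic_reg = path$entries[[i]]$bic_reg,
      selected_edges = path$selected_edges,
      lambda_grid = path$lambda)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.csv(traj, file.path(out_dir, "trajectories.csv"),
                       row.names = FALSE)
      say("wrote report.json and trajectories.csv to ", out_dir)
    }
    list(report = report, fits = list(one_factor = fit1, two_factor = fit2),
         path = path, trajectories = traj)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

.fit_report <- function(fit) {
  list(chi_square = fit$chi_square, df = fit$df, p_value = fit$p_value,
       rmsea = fit$rmsea[["point"]], rmsea_lo = fit$rmsea[["lo"]],
       rmsea_hi = fit$rmsea[["hi"]], cfi = fit$cfi, srmr = fit$srmr,
       bic = fit$bic, sb_scaling = fit$sb_c,
       r_squared = as.list(fit$r_squared), converged = fit$converged)
}
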