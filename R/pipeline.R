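# End-to-end orchestration: design + responses -> quadratic fits -> ANOVA
# -> desirability optimum -> optional neural-network comparison -> library
# annotation, with a machine-readable report.

PIPELINE_KEYS <- c("seed", "design_csv", "library_csv", "responses",
                   "goals", "ann", "optimizer", "tolerance_ppm", "out_dir")

pipeline_defaults <- function() {
  list(
    seed = 1L,
    design_csv = NULL,
    library_csv = NULL,
    responses = list(TPC = "tpc_exp", TFC = "tfc_exp"),
    goals = NULL,
    ann = list(enabled = FALSE, hidden = 5L,
               trainer = "levenberg_marquardt", seeds = 10L),
    optimizer = list(step = 0.01),
    tolerance_ppm = 5,
    out_dir = NULL
  )
}

#' Read a pipeline configuration file
#'
#' A plain-text YAML key-value file; unknown top-level keys are rejected
#' so that typos fail loudly. Missing keys fall back to the packaged
#' defaults (packaged study data, TPC/TFC responses, observed-range
#' maximize goals, no neural network).
#'
#' @param path YAML file path.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), PIPELINE_KEYS)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(pipeline_defaults(), raw)
  structure(cfg, class = "pipeline_config")
}

#' Run the full extraction-optimization pipeline
#'
#' Chains the analysis stages: load the design table and responses, fit
#' the quadratic response-surface model per response, assemble the ANOVA
#' panel, locate the joint desirability optimum, optionally train the
#' neural-network comparison and tabulate RSM-vs-ANN metrics, and annotate
#' the compound library. When `out_dir` is set, the machine-readable
#' report (JSON) and the table-shaped CSVs are written there.
#'
#' @param config A `pipeline_config`, a path to a YAML file, or `NULL` for
#'   the packaged defaults.
#' @return List of class `pipeline_result` with elements `design`, `fits`,
#'   `anova`, `optimum`, `ann` (or `NULL`), `comparison`, `library`.
#' @export
run_pipeline <- function(config = NULL) {
  if (is.null(config)) {
    config <- structure(pipeline_defaults(), class = "pipeline_config")
  } else if (is.character(config)) {
    config <- read_pipeline_config(config)
  }
  stopifnot(inherits(config, "pipeline_config"))

  if (is.null(config$design_csv)) {
    design <- ums_design()
    data <- ums_design_data()
  } else {
    design <- read_design_csv(config$design_csv)
    data <- as.data.frame(design)
  }
  responses <- lapply(config$responses, function(col) {
    if (!col %in% names(data)) {
      stop(sprintf("response column '%s' not found in the design table", col),
           call. = FALSE)
    }
    data[[col]]
  })

  fits <- lapply(names(responses), function(nm) {
    fit_quadratic(design, responses[[nm]], response = nm)
  })
  names(fits) <- names(responses)
  anovas <- lapply(fits, rsm_anova)

  goals <- if (is.null(config$goals)) {
    observed_range_goals(responses)
  } else {
    lapply(names(config$goals), function(nm) {
      g <- config$goals[[nm]]
      desirability_goal(nm, if (is.null(g$goal)) "maximize" else g$goal,
                        low = g$low, high = g$high,
                        weight = if (is.null(g$weight)) 1 else g$weight)
    }) |> stats::setNames(names(config$goals))
  }
  factors <- attr(design, "factors")
  optimum <- optimize_desirability(fits, goals, factors,
                                   step = config$optimizer$step)

  ann <- NULL
  comparison <- NULL
  if (isTRUE(config$ann$enabled)) {
    ann <- lapply(names(responses), function(nm) {
      cfg <- mlp_config(hidden = config$ann$hidden,
                        trainer = config$ann$trainer,
                        seed = config$seed)
      train_mlp_best(design, responses[[nm]], cfg,
                     seeds = config$seed + seq_len(config$ann$seeds) - 1L)
    })
    names(ann) <- names(responses)
    comparison <- lapply(names(responses), function(nm) {
      comparison_table(responses[[nm]],
                       list(rsm = fits[[nm]]$fitted,
                            ann = predict(ann[[nm]], design)))
    })
    names(comparison) <- names(responses)
  }

  library <- if (is.null(config$library_csv)) {
    ums_compound_library()
  } else {
    read_compound_library(config$library_csv)
  }
  library <- annotate_library(library)

  result <- structure(
    list(design = design, fits = fits, anova = anovas, optimum = optimum,
         ann = ann, comparison = comparison, library = library,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_models_json(result$fits, file.path(out_dir, "models.json"))
  for (nm in names(result$anova)) {
    utils::write.csv(anova_as_data_frame(result$anova[[nm]]),
                     file.path(out_dir, sprintf("anova_%s.csv", nm)),
                     row.names = FALSE)
  }
  opt <- result$optimum
  jsonlite::write_json(
    list(coded = opt$coded, actual = as.list(opt$actual),
         predicted = as.list(opt$predicted), d = as.list(opt$d), D = opt$D),
    file.path(out_dir, "optimum.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$comparison)) {
    for (nm in names(result$comparison)) {
      utils::write.csv(result$comparison[[nm]],
                       file.path(out_dir, sprintf("comparison_%s.csv", nm)),
                       row.names = FALSE)
    }
  }
  write_compound_library(result$library,
                         file.path(out_dir, "annotated_library.csv"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Extraction-optimization pipeline result\n")
  for (nm in names(x$fits)) {
    a <- x$anova[[nm]]
    cat(sprintf("  %s: R2 %.4f, model F %.2f, lack-of-fit p %.4f\n",
                nm, a$r2, a$model$f, a$lack_of_fit$p))
  }
  cat(sprintf("  optimum: %s (D = %.3f)\n",
              paste(sprintf("%s = %.2f", names(x$optimum$actual),
                            x$optimum$actual), collapse = ", "), x$optimum$D))
  cat(sprintf("  library: %d compounds annotated\n", nrow(x$library)))
  invisible(x)
}
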