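#' Configuration for a full modelling run
#'
#' @param input Path to a compound CSV (see \code{\link{read_qsar_table}}),
#'   or \code{NULL} to generate a synthetic table.
#' @param output_dir Directory for artifacts (created if absent).
#' @param mode \code{"mlr"} (least squares), \code{"svr"} (support vector
#'   regression) or \code{"published"} (frozen-equation prediction only).
#' @param n_train Training-set size; \code{NULL} selects the published
#'   proportion (139 of 274).
#' @param svr_params Named list \code{C}, \code{gamma}, \code{epsilon};
#'   the published optimum by default.
#' @param tune Run the genetic-algorithm tuner instead of using
#'   \code{svr_params}?
#' @param ga Optional \code{\link{ga_config}} when tuning.
#' @param synth Optional \code{\link{synth_config}} when no input file is
#'   given.
#' @param seed Integer seed for every stochastic stage.
#' @param verbose Print stage progress?
#' @return A \code{"run_config"} list.
#' @export
run_config <- function(input = NULL, output_dir = tempfile("skinperm_run_"),
                       mode = c("mlr", "svr", "published"), n_train = NULL,
                       svr_params = list(C = 7.2906, gamma = 1.7200,
                                         epsilon = 0.001),
                       tune = FALSE, ga = NULL, synth = NULL, seed = 1L,
                       verbose = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(input) && !file.exists(input)) {
    stop(sprintf("input file not found: %s", input), call. = FALSE)
  }
  structure(list(input = input, output_dir = output_dir, mode = mode,
                 n_train = n_train, svr_params = svr_params, tune = tune,
                 ga = ga, synth = synth, seed = as.integer(seed),
                 verbose = verbose),
            class = "run_config")
}

.stage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[%s]", name))
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("skinperm_stage_error", "error", "condition"),
                   list(message = sprintf("stage '%s' failed: %s", name,
                                          conditionMessage(e)),
                        call = NULL, stage = name)))
  })
}

#' Run the full modelling workflow
#'
#' Reads (or generates) a compound table, fills in descriptors when SMILES
#' are available and descriptor columns are not, performs the
#' Kennard-Stone split, fits the requested model on the training set,
#' validates on the test set (rms/R-squared and the Golbraikh-Tropsha
#' battery) and writes every artifact: the split compound table with
#' predictions and residuals, the fit report, the serialized model and
#' the validation report. Deterministic given the configuration.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list with the fitted model, validation report and
#'   artifact paths.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  ds <- .stage("read", v, {
    if (is.null(config$input)) {
      generate_dataset(config$synth %||% synth_config(seed = config$seed))
    } else {
      read_qsar_table(config$input)
    }
  })

  ds <- .stage("descriptors", v, {
    have <- all(c("cos2_alogp", "x3v", "neoplastic80") %in% names(ds))
    if (!have) {
      dt <- descriptor_table(ds$smiles, id = ds$id)
      ds$cos2_alogp <- dt$cos2_alogp
      ds$x3v <- dt$x3v
      ds$neoplastic80 <- dt$neoplastic80
    }
    ds
  })

  ds <- .stage("split", v, {
    n_train <- config$n_train %||% round(nrow(ds) * 139 / 274)
    split_dataset(ds, n_train = n_train)
  })
  train <- ds$split == "train"
  desc_cols <- c("cos2_alogp", "x3v", "neoplastic80")
  x <- as.matrix(as.data.frame(ds)[, desc_cols])
  y <- ds$logkp

  model <- .stage("fit", v, {
    switch(config$mode,
      mlr = ols_fit(x[train, , drop = FALSE], y[train]),
      svr = {
        params <- config$svr_params
        if (isTRUE(config$tune)) {
          ga_cfg <- config$ga %||% ga_config(seed = config$seed)
          tuned <- ga_optimize(x[train, , drop = FALSE], y[train], ga_cfg)
          params <- list(C = tuned$C, gamma = tuned$gamma,
                         epsilon = ga_cfg$epsilon)
        }
        svr_fit(x[train, , drop = FALSE], y[train], C = params$C,
                gamma = params$gamma, epsilon = params$epsilon)
      },
      published = NULL)
  })

  preds <- .stage("predict", v, {
    if (config$mode == "published") {
      predict_published("eq13", as.data.frame(ds))
    } else {
      predict(model, x)
    }
  })

  report <- .stage("validate", v, {
    golbraikh_tropsha(y[!train], preds[!train], mean(y[train]))
  })

  paths <- .stage("write", v, {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- file.path(config$output_dir,
                     c(table = "predictions.csv", fit = "fit_report.json",
                       model = "model.json", validation = "validation.json"))
    names(out) <- c("table", "fit", "model", "validation")
    tab <- as.data.frame(ds)
    tab$logkp_pred <- preds
    tab$residual <- y - preds
    write.csv(tab, out[["table"]], row.names = FALSE)
    fit_report <- switch(config$mode,
      mlr = list(schema = "skinperm/fit_mlr/1",
                 coefficients = as.list(model$coefficients),
                 diagnostics = model$coef_table,
                 stats = list(n = model$n, r = model$r, r2 = model$r2,
                              r2_adj = model$r2_adj, se = model$se,
                              F = model$F)),
      svr = list(schema = "skinperm/fit_svr/1",
                 C = model$C, gamma = model$gamma, epsilon = model$epsilon,
                 n_support = length(model$support),
                 train = rms_r2(y[train], preds[train])),
      published = list(schema = "skinperm/fit_published/1",
                       equation = "eq13"))
    jsonlite::write_json(fit_report, out[["fit"]], auto_unbox = TRUE,
                         digits = NA)
    if (config$mode == "svr") {
      svr_to_json(model, out[["model"]])
    } else {
      jsonlite::write_json(fit_report, out[["model"]], auto_unbox = TRUE,
                           digits = NA)
    }
    jsonlite::write_json(unclass(report), out[["validation"]],
                         auto_unbox = TRUE, digits = NA)
    out
  })

  invisible(list(dataset = ds, model = model, predictions = preds,
                 report = report, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
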