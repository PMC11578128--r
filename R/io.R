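## Dataset and configuration I/O plus a thin command-line surface.
##
## CSV dialect: comma-separated, '.' decimal, mandatory header.  BLQ is its
## own 0/1 column (not a DV sentinel).  Times are hours after the most
## recent dose, with the regimen carried in DOSE/TAU columns; dosing is at
## steady state, so no dose-event rows are written.  Compartment codes:
## 2 = plasma, 3 = milk, 4 = infant blood.

.cmt_codes <- c(plasma = 2L, milk = 3L, infant = 4L)

#' Write an observation table to NONMEM-style CSV
#'
#' @param table an observation table (e.g. from [simulate_study()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(table, path) {
  out <- data.frame(ID = table$ID, TIME = table$TIME, AMT = 0,
                    DV = table$DV, EVID = 0L, MDV = table$MDV,
                    CMT = .cmt_codes[table$MATRIX], BLQ = table$BLQ,
                    DOSE = table$DOSE, TAU = table$TAU,
                    GROUP = table$GROUP, VISIT = table$VISIT,
                    WT = table$WT, AGE = table$AGE, BMI = table$BMI,
                    CRCL = table$CRCL, VDAY = table$VDAY,
                    IWT = table$IWT)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a NONMEM-style CSV observation table
#'
#' Validates the schema (required columns `ID`, `TIME`, `DV`, `AMT`,
#' `EVID`, `MDV`, `CMT`, `BLQ`) and returns the package's observation
#' table.  Rows with `MDV = 1` are retained but excluded from any
#' likelihood.  Concentrations are in ng/mL.
#'
#' @param path CSV file path.
#' @return An observation table data.frame.
#' @export
read_pk_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ID", "TIME", "DV", "AMT", "EVID", "MDV", "CMT", "BLQ")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  obs <- raw$EVID == 0
  dv_num <- suppressWarnings(as.numeric(raw$DV))
  bad <- which(obs & raw$MDV == 0 & is.na(dv_num))
  if (length(bad))
    stop("non-numeric DV on observation row(s): line ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  mat <- names(.cmt_codes)[match(raw$CMT, .cmt_codes)]
  if (anyNA(mat[obs]))
    stop("unknown CMT code(s): ",
         paste(unique(raw$CMT[obs][is.na(mat[obs])]), collapse = ", "),
         call. = FALSE)
  tab <- data.frame(ID = raw$ID, VISIT = raw$VISIT %||% 1L, MATRIX = mat,
                    TIME = raw$TIME, DV = dv_num, BLQ = as.integer(raw$BLQ),
                    MDV = as.integer(raw$MDV), DOSE = raw$DOSE,
                    TAU = raw$TAU, GROUP = raw$GROUP %||% NA_character_,
                    WT = raw$WT %||% NA_real_, AGE = raw$AGE %||% NA_real_,
                    BMI = raw$BMI %||% NA_real_,
                    CRCL = raw$CRCL %||% NA_real_,
                    VDAY = raw$VDAY %||% NA_real_,
                    IWT = raw$IWT %||% NA_real_)
  tab[obs, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a run configuration
#'
#' A YAML file holding the study-design parameters, model initial values
#' and run settings; every pipeline run writes its resolved configuration
#' next to its outputs so any artifact is reproducible from config + seed.
#'
#' @param config a named list (see [default_run_config()]).
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the validated config list.
#' @export
write_run_config <- function(config, path) {
  .validate_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  .validate_config(config)
  config
}

#' Default run configuration
#'
#' @param seed integer seed recorded in the config.
#' @return A named list with `design`, `model`, `estimation` and
#'   `diagnostics` sections.
#' @export
default_run_config <- function(seed = 1L) {
  model <- lamivudine_model()
  list(design = unclass(study_design()),
       model = list(theta = as.list(unclass(model$theta)),
                    omega = lapply(seq_len(3), function(i) model$omega[i, ]),
                    sigma2 = as.list(model$sigma2)),
       estimation = list(method = "laplace", blq = "M1", se = FALSE),
       diagnostics = list(n_sim = 500L,
                          bins = c(0, 1, 3, 6, 10, 14, 18, 24)),
       seed = as.integer(seed))
}

.validate_config <- function(config) {
  need <- c("design", "model", "estimation", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing section(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(c("theta", "omega", "sigma2") %in% names(config$model)))
    stop("config$model needs theta, omega and sigma2", call. = FALSE)
  invisible(TRUE)
}

.config_design <- function(config) {
  d <- config$design
  do.call(study_design, d[intersect(names(d),
                                    names(formals(study_design)))])
}

.config_model <- function(config) {
  th <- config$model$theta
  om <- do.call(rbind, config$model$omega)
  pop_model(structural_params(th$ka, th$cl, th$vc, th$kcb, th$rcb),
            om, unlist(config$model$sigma2))
}

## ---- command-line surface -------------------------------------------------

.cli_usage <- function() {
  paste(
    "usage: lactpk <command> [--config FILE] [--seed N] [--data FILE]",
    "              [--out DIR] [--n N]",
    "commands:",
    "  simulate     generate a synthetic study dataset (CSV)",
    "  fit          fit the population model to a dataset (JSON + report)",
    "  vpc          fit, then prediction-corrected VPC (CSV + SVG)",
    "  bootstrap    nonparametric bootstrap CIs (CSV)",
    "  scm          stepwise covariate modelling (TSV trace)",
    "  infant-dose  per-pair infant exposure report (CSV)",
    sep = "\n")
}

.cli_parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--") || i == length(args)) return(NULL)
    flags[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  known <- c("config", "seed", "data", "out", "n")
  if (length(setdiff(names(flags), known))) return(NULL)
  flags
}

#' Command-line entry point
#'
#' A thin shell over the package pipeline; see `inst/cli/lactpk.R` for the
#' Rscript wrapper.  Every run writes its resolved configuration next to
#' its outputs.  Returns (not calls) the exit status: 0 on success, 1 on a
#' validation or convergence failure, 2 on a usage error.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
lactpk_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  commands <- c("simulate", "fit", "vpc", "bootstrap", "scm",
                "infant-dose")
  if (!length(args) || !args[1] %in% commands) {
    message(.cli_usage())
    return(invisible(2L))
  }
  cmd <- args[1]
  flags <- .cli_parse_flags(args[-1])
  if (is.null(flags)) {
    message(.cli_usage())
    return(invisible(2L))
  }
  status <- tryCatch({
    seed <- as.integer(flags$seed %||% 1L)
    out_dir <- flags$out %||% "."
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    config <- if (!is.null(flags$config)) read_run_config(flags$config)
              else default_run_config(seed)
    config$seed <- seed
    write_run_config(config,
                     file.path(out_dir, paste0(cmd, "-config.yaml")))
    design <- .config_design(config)
    model <- .config_model(config)
    load_data <- function() {
      if (is.null(flags$data))
        stop("--data is required for '", cmd, "'", call. = FALSE)
      read_pk_dataset(flags$data)
    }
    run_fit <- function(tab)
      fit_nlme(tab, model, method = config$estimation$method %||% "laplace",
               blq = config$estimation$blq %||% "M1",
               se = isTRUE(config$estimation$se))
    switch(cmd,
      simulate = {
        tab <- simulate_study(design, model, seed = seed)
        write_pk_dataset(tab, file.path(out_dir, "dataset.csv"))
        message("wrote ", file.path(out_dir, "dataset.csv"))
      },
      fit = {
        fit <- run_fit(load_data())
        .write_fit_json(fit, file.path(out_dir, "fit.json"))
        writeLines(utils::capture.output(print(summary(fit))),
                   file.path(out_dir, "fit-report.txt"))
        message("wrote ", file.path(out_dir, "fit.json"))
      },
      vpc = {
        fit <- run_fit(load_data())
        v <- pc_vpc(fit, n_sim = config$diagnostics$n_sim %||% 500L,
                    seed = seed,
                    bins = unlist(config$diagnostics$bins %||%
                                    c(0, 1, 3, 6, 10, 14, 18, 24)))
        utils::write.csv(v$table, file.path(out_dir, "vpc.csv"),
                         row.names = FALSE)
        grDevices::svg(file.path(out_dir, "vpc.svg"), width = 9,
                       height = 4.5)
        plot(v)
        grDevices::dev.off()
        message("wrote ", file.path(out_dir, "vpc.csv"))
      },
      bootstrap = {
        b <- bootstrap_ci(load_data(), model,
                          n_resamples = as.integer(flags$n %||% 1000L),
                          seed = seed)
        utils::write.csv(b$table, file.path(out_dir, "bootstrap.csv"),
                         row.names = FALSE)
        message("wrote ", file.path(out_dir, "bootstrap.csv"))
      },
      scm = {
        s <- scm(load_data(), model)
        utils::write.table(s$trace, file.path(out_dir, "scm-trace.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        message("wrote ", file.path(out_dir, "scm-trace.tsv"))
      },
      `infant-dose` = {
        fit <- run_fit(load_data())
        rep <- infant_exposure(fit)
        utils::write.csv(rep, file.path(out_dir, "infant-exposure.csv"),
                         row.names = FALSE)
        message("wrote ", file.path(out_dir, "infant-exposure.csv"))
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.write_fit_json <- function(fit, path) {
  obj <- list(coefficients = as.list(coef(fit)),
              theta = as.list(unclass(fit$theta)),
              omega = lapply(seq_len(3), function(i) fit$omega[i, ]),
              sigma2 = as.list(fit$sigma2),
              ofv = fit$ofv,
              se = if (!is.null(fit$se)) as.list(fit$se) else NULL,
              shrinkage = as.list(fit$shrinkage),
              convergence = fit$convergence, message = fit$message,
              method = fit$method, blq = fit$blq,
              n_subjects = fit$n_subjects, n_obs = fit$n_obs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
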