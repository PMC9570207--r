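# Dataset files and the analysis pipeline.
#
# File layout: event-oriented delimited text, one row per event, in the
# convention of population-PK datasets: exactly one dosing row per subject
# at time 0 (amount set, concentration empty) followed by observation rows
# (concentration set, amount empty). Columns:
#   subject_id, group, body_weight, time, event, amount, conc

.DS_COLUMNS <- c("subject_id", "group", "body_weight", "time", "event",
                 "amount", "conc")

# full-precision, locale-independent numeric formatting (lossless round trip)
#' @keywords internal
fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write a dataset to delimited text
#'
#' Deterministic column and row order (subject in dataset order, dose row
#' first, then observations by time); identical datasets produce
#' byte-identical files.
#'
#' @param dataset [mi_dataset()].
#' @param path output file; extension `.tsv` selects tabs, anything else
#'   commas.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "mi_dataset"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  rows <- lapply(dataset$subjects, function(s) {
    rbind(
      data.frame(subject_id = s$subject_id, group = s$group,
                 body_weight = fmt_num(s$body_weight), time = fmt_num(0),
                 event = "dose", amount = fmt_num(s$dose$amount), conc = "",
                 stringsAsFactors = FALSE),
      data.frame(subject_id = s$subject_id, group = s$group,
                 body_weight = fmt_num(s$body_weight), time = fmt_num(s$times),
                 event = "observation", amount = "", conc = fmt_num(s$conc),
                 stringsAsFactors = FALSE))
  })
  tab <- do.call(rbind, rows)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.DS_COLUMNS, collapse = sep), con)
  writeLines(do.call(paste, c(unname(as.list(tab)), list(sep = sep))), con)
  invisible(path)
}

#' Read a dataset from delimited text
#'
#' Parses the event-oriented layout written by [write_dataset()] (comma or
#' tab delimited, auto-detected from the header line), validates its
#' invariants, converts declared units and returns an [mi_dataset()].
#' Error messages cite file line numbers.
#'
#' @param path input file with a header row.
#' @param units declared units: `concentration` is `"mg/L"` (default) or the
#'   alias `"ug/mL"`/`"µg/mL"`; `weight` is `"g"` (default) or `"kg"`.
#' @param study study label for the metadata.
#' @return An [mi_dataset()] in mg/L and g.
#' @export
read_dataset <- function(path, units = list(concentration = "mg/L",
                                            weight = "g"),
                         study = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = "",
                           colClasses = c(subject_id = "character",
                                          group = "character"))
  miss <- setdiff(.DS_COLUMNS, names(tab))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  tab$line <- seq_len(nrow(tab)) + 1L  # header is line 1

  cunit <- units$concentration %||% "mg/L"
  if (!cunit %in% c("mg/L", "ug/mL", "µg/mL"))
    stop("unsupported concentration unit: ", cunit, call. = FALSE)
  wunit <- units$weight %||% "g"
  wfac <- switch(wunit, g = 1, kg = 1000,
                 stop("unsupported weight unit: ", wunit, call. = FALSE))

  bad_ev <- tab$line[!tab$event %in% c("dose", "observation")]
  if (length(bad_ev) > 0)
    stop("invalid event flag at line(s) ", paste(bad_ev, collapse = ", "),
         call. = FALSE)

  subjects <- list()
  for (id in unique(tab$subject_id)) {
    st <- tab[tab$subject_id == id, , drop = FALSE]
    dr <- st[st$event == "dose", , drop = FALSE]
    if (nrow(dr) != 1L)
      stop("subject '", id, "' must have exactly one dosing row, found ",
           nrow(dr), " (line(s) ",
           paste(dr$line, collapse = ", "), ")", call. = FALSE)
    if (dr$time != 0)
      stop("subject '", id, "': dosing row must be at time 0 (line ",
           dr$line, ")", call. = FALSE)
    if (!is.na(dr$conc))
      stop("subject '", id, "': dosing row carries a concentration (line ",
           dr$line, ")", call. = FALSE)
    ob <- st[st$event == "observation", , drop = FALSE]
    if (nrow(ob) == 0)
      stop("subject '", id, "' has no observation rows", call. = FALSE)
    if (any(!is.na(ob$amount)))
      stop("subject '", id, "': observation row carries an amount (line(s) ",
           paste(ob$line[!is.na(ob$amount)], collapse = ", "), ")",
           call. = FALSE)
    if (any(is.na(ob$conc) | ob$conc <= 0))
      stop("subject '", id, "': non-positive or missing concentration ",
           "(line(s) ",
           paste(ob$line[is.na(ob$conc) | ob$conc <= 0], collapse = ", "),
           ")", call. = FALSE)
    if (is.unsorted(ob$time, strictly = TRUE)) {
      off <- ob$line[c(FALSE, diff(ob$time) <= 0)]
      stop("subject '", id, "': observation times not strictly increasing ",
           "(line(s) ", paste(off, collapse = ", "), ")", call. = FALSE)
    }
    subjects[[length(subjects) + 1L]] <-
      subject_record(id, dr$body_weight * wfac,
                     dose_event(amount = dr$amount),
                     ob$time, ob$conc, group = dr$group)
  }
  mi_dataset(subjects, study = study)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small polynomial string hash (fingerprint for the run manifest)
#' @keywords internal
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @keywords internal
pipeline_config_defaults <- function(config) {
  utils::modifyList(list(
    seed = 1L,
    model = list(ka = 1.89, cl_f = 0.853, v_f = 5.1, c0 = 10, sigma = 0.243),
    design = "builtin",
    data = NULL,
    simulate = TRUE,
    fit = list(enabled = TRUE, mode = "pooled", n_starts = 8),
    output = list(dir = "mipk-run")
  ), config)
}

#' Run the full simulate/fit/report pipeline
#'
#' Executes (optionally) simulate -> fit -> secondary parameters -> report
#' and writes a deterministic report bundle: the dataset (if simulated), a
#' parameter table with estimates, CV% and secondary parameters, an
#' observed-vs-predicted table per subject, and a run manifest carrying the
#' seed, a config fingerprint and the package version. Identical
#' config + seed yields byte-identical outputs. Any stage failure aborts
#' with the stage name and removes partial outputs.
#'
#' @param config a named list, or the path to a YAML file, with sections
#'   `model` (ka, cl_f, v_f, c0, sigma), `design` (`"builtin"` for the
#'   nine-rat design), `data` (path to an existing dataset file; overrides
#'   simulation), `simulate` (logical), `fit` (`enabled`, `mode`,
#'   `n_starts`), `output` (`dir`) and `seed`. Missing entries take
#'   defaults.
#' @param out_dir overrides `config$output$dir`.
#' @return Invisibly, a list with the dataset, fit, secondary parameters,
#'   report tables and manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_config_defaults(config)
  dir <- out_dir %||% cfg$output$dir
  created <- character(0)
  stage <- "setup"
  emit <- function(name, writer) {
    p <- file.path(dir, name)
    writer(p)
    created <<- c(created, p)
    p
  }
  bundle <- tryCatch({
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

    stage <- "input"
    if (!is.null(cfg$data)) {
      ds <- read_dataset(cfg$data)
    } else if (isTRUE(cfg$simulate)) {
      stage <- "simulate"
      params <- structural_params(cfg$model$ka, cfg$model$cl_f, cfg$model$v_f,
                                  cfg$model$c0, cfg$model$sigma)
      design <- if (identical(cfg$design, "builtin")) rat_study_design()
        else stop("unknown design '", cfg$design, "'", call. = FALSE)
      ds <- simulate_study(params, design, seed = cfg$seed)
      emit("dataset.csv", function(p) write_dataset(ds, p))
    } else stop("no input: set 'data' or simulate: true", call. = FALSE)

    fit <- NULL; sec <- NULL; par_tab <- NULL; op_tab <- NULL
    if (isTRUE(cfg$fit$enabled)) {
      stage <- "fit"
      fit <- mi_fit(ds, mode = cfg$fit$mode %||% "pooled",
                    n_starts = cfg$fit$n_starts %||% 8)
      stage <- "secondary"
      dpk <- cfg$dose_per_kg %||% 2
      sec <- secondary_parameters(fit$estimates, dose_per_kg = dpk)
      est <- fit$estimates; cv <- fit$cv_percent
      par_tab <- data.frame(
        parameter = c("V/F", "CL/F", "ka", "C0", "sigma2",
                      "k_el", "t_half", "k_in", "AUC"),
        unit = c("L", "L/h", "1/h", "mg/L", "-",
                 "1/h", "h", "mg/h", "(g/kg)/(L/h)"),
        estimate = c(est$v_f, est$cl_f, est$ka, est$c0, est$sigma^2,
                     sec$k_el, sec$t_half, sec$k_in, sec$auc),
        cv_percent = c(cv[["v_f"]], cv[["cl_f"]], cv[["ka"]], cv[["c0"]],
                       cv[["sigma2"]], NA, NA, NA, NA))
      stage <- "report"
      ot <- obs_table(ds)
      ot$predicted <- unlist(lapply(ds$subjects, function(s)
        predict(fit, s$subject_id)))
      op_tab <- ot[, c("subject_id", "group", "time", "conc", "predicted")]
      names(op_tab)[4] <- "observed"
      emit("parameters.csv", function(p)
        utils::write.csv(format(par_tab, digits = 15, trim = TRUE), p,
                         row.names = FALSE, quote = FALSE))
      emit("obs_pred.csv", function(p)
        utils::write.csv(format(op_tab, digits = 15, trim = TRUE), p,
                         row.names = FALSE, quote = FALSE))
    }

    stage <- "manifest"
    manifest <- list(seed = cfg$seed,
                     config_hash = config_hash(cfg),
                     package_version =
                       as.character(utils::packageVersion("mipk")),
                     n_subjects = length(ds$subjects),
                     n_observations = n_observations(ds),
                     converged = if (is.null(fit)) NA else fit$converged)
    emit("manifest.json", function(p)
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))

    list(dataset = ds, fit = fit, secondary = sec, parameters = par_tab,
         obs_pred = op_tab, manifest = manifest, dir = dir)
  }, error = function(e) {
    unlink(created)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(bundle)
}
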