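# Parameters whose table-printed unit is percent; they are stored internally
# as proportions and converted exactly once, here at the I/O boundary.
PERCENT_PARAMS <- c("bni_prob", "complication_rate", "recurrence_rate_7y",
                    "retreat_fraction")

#' Serialize a treatment arm's parameters to a row table
#'
#' Flat representation with columns `treatment, parameter, level_or_name,
#' mean, sd, source`, mirrored by the CSV and JSON formats.  Outcome
#' probabilities (`bni_prob`, `complication_rate`, `recurrence_rate_7y`,
#' `retreat_fraction`) are written on the percent scale, as in the source
#' tables; utilities, itemized incidences, medication values, the modality
#' mix and timing constants are written as stored.
#'
#' @param params a [treatment_params()].
#' @return data.frame in the parameter-file schema.
#' @export
params_to_table <- function(params) {
  stopifnot(inherits(params, "treatment_params"))
  rows <- list()
  add <- function(parameter, level_or_name, mean, sd = NA_real_, source = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      treatment = params$treatment, parameter = parameter,
      level_or_name = level_or_name, mean = mean, sd = sd, source = source,
      stringsAsFactors = FALSE)
  }
  pct <- function(x) x * 100
  for (lvl in BNI_LEVELS) {
    e <- params$bni_dist[[lvl]]
    add("bni_prob", lvl, pct(e$mean), pct(e$sd), e$label)
  }
  for (nm in c("complication_rate", "recurrence_rate_7y", "retreat_fraction")) {
    e <- params[[nm]]
    add(nm, "", pct(e$mean), pct(e$sd), e$label)
  }
  for (ce in params$complications) {
    add("complication_incidence", ce$name, ce$incidence$mean, ce$incidence$sd,
        ce$incidence$label)
    add("complication_utility", ce$name, ce$utility$mean, ce$utility$sd,
        ce$utility$label)
    if (length(ce$compound_with)) {
      add("complication_compound", ce$name, NA_real_, NA_real_,
          paste(ce$compound_with, collapse = ";"))
    }
  }
  for (lvl in BNI_LEVELS) {
    e <- params$bni_utility[[lvl]]
    add("bni_utility", lvl, e$mean, e$sd, e$label)
  }
  for (cat in names(params$medication$probs)) {
    e <- params$medication$probs[[cat]]
    add("medication_probability", cat, e$mean * params$medication$raw_sum,
        e$sd, e$label)
    u <- params$medication$utilities[[cat]]
    add("medication_utility", cat, u$mean, u$sd, u$label)
  }
  for (nm in c("response_delay_months", "retreat_delay_months",
               "complication_onset_months")) {
    add(nm, "", params[[nm]])
  }
  for (m in c("MVD", "SRS")) {
    add("retreat_modality_mix", m, unname(params$retreat_modality_mix[m]))
  }
  do.call(rbind, rows)
}

#' Write treatment parameters to CSV or JSON
#'
#' @param params a [treatment_params()], or a list of them (e.g. both arms).
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return the path, invisibly.
#' @export
write_parameters <- function(params, path) {
  if (inherits(params, "treatment_params")) params <- list(params)
  tab <- do.call(rbind, lapply(params, params_to_table))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, digits = NA, na = "null")
  } else {
    utils::write.csv(format_num_cols(tab), path, row.names = FALSE,
                     quote = TRUE)
  }
  invisible(path)
}

format_num_cols <- function(tab) {
  for (col in c("mean", "sd")) {
    tab[[col]] <- ifelse(is.na(tab[[col]]), "",
                         sprintf("%.15g", tab[[col]]))
  }
  tab
}

#' Load validated parameter records from file
#'
#' Reads one of the documented schemas and returns a fully validated typed
#' record with percent fields divided by 100 and renormalizations applied:
#'
#' * `"treatment_params"`: the row-table CSV/JSON of [write_parameters()];
#'   returns a named list of [treatment_params()], one per treatment present.
#' * `"medication"`: the same table restricted to the medication rows;
#'   returns a [medication_model()].
#' * `"config"`: a YAML file of [model_config()] fields.
#'
#' Malformed files raise a schema error naming the offending row or field;
#' estimates violating the beta-feasibility bound `sd^2 < mean (1 - mean)`
#' raise a validation error naming the field.
#'
#' @param path file path.
#' @param schema one of `"treatment_params"`, `"medication"`, `"config"`.
#' @return see above.
#' @export
load_parameters <- function(path,
                            schema = c("treatment_params", "medication",
                                       "config")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path)
  if (schema == "config") {
    cfg <- yaml::read_yaml(path)
    known <- names(formals(model_config))
    bad <- setdiff(names(cfg), known)
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    return(do.call(model_config, cfg))
  }
  tab <- read_param_table(path)
  if (schema == "medication") {
    tr <- unique(tab$treatment)
    if (length(tr) != 1L) stop("medication schema expects a single treatment")
    return(medication_from_table(tab))
  }
  out <- lapply(split(tab, tab$treatment), params_from_table)
  out[intersect(c("MVD", "SRS"), names(out))]
}

read_param_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tab <- jsonlite::read_json(path, simplifyVector = TRUE)
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  }
  need <- c("treatment", "parameter", "level_or_name", "mean", "sd", "source")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("parameter file missing column(s): ", paste(miss, collapse = ", "))
  }
  tab$mean <- suppressWarnings(as.numeric(tab$mean))
  tab$sd <- suppressWarnings(as.numeric(tab$sd))
  if (is.null(tab$level_or_name)) tab$level_or_name <- ""
  tab$level_or_name[is.na(tab$level_or_name)] <- ""
  tab$source[is.na(tab$source)] <- ""
  tab
}

table_estimate <- function(tab, parameter, level_or_name = "", kind,
                           required = TRUE) {
  row <- tab[tab$parameter == parameter & tab$level_or_name == level_or_name, ]
  field <- if (nzchar(level_or_name)) {
    paste0(parameter, "[", level_or_name, "]")
  } else {
    parameter
  }
  if (nrow(row) == 0L) {
    if (!required) return(NULL)
    stop("parameter file: missing row for field ", field)
  }
  if (nrow(row) > 1L) stop("parameter file: duplicate rows for field ", field)
  if (is.na(row$mean)) stop("parameter file: non-numeric mean in field ", field)
  mean <- row$mean
  sd <- if (is.na(row$sd)) 0 else row$sd
  if (parameter %in% PERCENT_PARAMS) {
    # snap to 15 significant digits so the decimal shift is exact and
    # write -> load round-trips bit-identically
    mean <- as.numeric(sprintf("%.15g", mean / 100))
    sd <- as.numeric(sprintf("%.15g", sd / 100))
  }
  est <- tryCatch(
    new_estimate(mean, sd, if (nzchar(row$source)) row$source else field, kind),
    error = function(e) stop("parameter file, field ", field, ": ",
                             conditionMessage(e), call. = FALSE))
  if (est$sd > 0 && est$sd^2 >= est$mean * (1 - est$mean)) {
    stop(sprintf(
      "parameter file, field %s: sd^2 = %.4g violates beta-feasibility bound mean*(1-mean) = %.4g",
      field, est$sd^2, est$mean * (1 - est$mean)))
  }
  est
}

table_scalar <- function(tab, parameter, level_or_name = "") {
  row <- tab[tab$parameter == parameter & tab$level_or_name == level_or_name, ]
  if (nrow(row) != 1L || is.na(row$mean)) {
    stop("parameter file: missing or non-numeric field ", parameter)
  }
  row$mean
}

medication_from_table <- function(tab) {
  cats <- c("none", "mild_moderate", "severe")
  probs <- lapply(cats, function(cat) {
    table_estimate(tab, "medication_probability", cat, "probability")
  })
  utilities <- lapply(cats, function(cat) {
    table_estimate(tab, "medication_utility", cat, "utility")
  })
  names(probs) <- names(utilities) <- cats
  medication_model(probs, utilities)
}

params_from_table <- function(tab) {
  treatment <- unique(tab$treatment)
  stopifnot(length(treatment) == 1L)
  bni_dist <- lapply(BNI_LEVELS, function(lvl) {
    table_estimate(tab, "bni_prob", lvl, "probability")
  })
  names(bni_dist) <- BNI_LEVELS
  bni_utility <- lapply(BNI_LEVELS, function(lvl) {
    table_estimate(tab, "bni_utility", lvl, "utility")
  })
  names(bni_utility) <- BNI_LEVELS
  comp_names <- unique(tab$level_or_name[tab$parameter == "complication_incidence"])
  complications <- lapply(comp_names, function(nm) {
    comp_row <- tab[tab$parameter == "complication_compound" &
                      tab$level_or_name == nm, ]
    compound <- if (nrow(comp_row) == 1L && nzchar(comp_row$source)) {
      strsplit(comp_row$source, ";", fixed = TRUE)[[1L]]
    } else {
      character()
    }
    complication_entry(
      nm,
      table_estimate(tab, "complication_incidence", nm, "probability"),
      table_estimate(tab, "complication_utility", nm, "utility"),
      compound_with = compound)
  })
  mix <- c(MVD = table_scalar(tab, "retreat_modality_mix", "MVD"),
           SRS = table_scalar(tab, "retreat_modality_mix", "SRS"))
  treatment_params(
    treatment = treatment,
    bni_dist = bni_dist,
    complication_rate = table_estimate(tab, "complication_rate", "", "probability"),
    recurrence_rate_7y = table_estimate(tab, "recurrence_rate_7y", "", "probability"),
    retreat_fraction = table_estimate(tab, "retreat_fraction", "", "probability"),
    complications = complications,
    bni_utility = bni_utility,
    medication = medication_from_table(tab),
    response_delay_months = table_scalar(tab, "response_delay_months"),
    retreat_delay_months = table_scalar(tab, "retreat_delay_months"),
    complication_onset_months = table_scalar(tab, "complication_onset_months"),
    retreat_modality_mix = mix)
}

#' Path to the packaged default parameter file
#'
#' CSV transcription of the pooled default parameters for both arms, as
#' produced by [write_parameters()] from [default_parameters()].
#'
#' @return file path within the installed package.
#' @export
packaged_parameters_path <- function() {
  system.file("extdata", "treatment_params.csv", package = "tndecide",
              mustWork = TRUE)
}

#' Write a model configuration to YAML
#'
#' @param config a [model_config()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
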