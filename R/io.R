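# Configuration input/output and report rendering.
#
# The canonical on-disk format is a hierarchical YAML (or JSON) document:
# strategy fields at the top level, with optional `dialysis` and
# `rate_irr_per_usd` entries alongside.  All numbers are unformatted
# integers on disk; thousands separators exist only in rendered tables.
# Unknown fields are rejected with a message naming the field and where
# it sits, so typos never silently drop an input.

config_fields <- list(
  top = c("name", "cohort", "hospitalization", "maintenance",
          "adverse_events", "misc", "dialysis", "rate_irr_per_usd"),
  cohort = c("n_patients", "horizon_days", "patient_weight_kg"),
  hospitalization = c("k_value", "multiplier"),
  line = c("drug", "dosage_form", "units_per_day", "unit_price",
           "n_eligible", "duration_days", "cohort_daily_cost"),
  ae = c("name", "probability", "items"),
  item = c("kind", "label", "unit_price", "duration", "units_per_day"),
  dialysis = c("session_tariff", "sessions_per_year",
               "adjunct_annual_per_patient")
)

check_fields <- function(x, allowed, where) {
  if (!is.list(x)) stop("`", where, "` must be a mapping", call. = FALSE)
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop("unknown field(s) ", paste0("`", extra, "`", collapse = ", "),
         " in ", where, call. = FALSE)
  }
  invisible(x)
}

need <- function(x, field, where) {
  if (is.null(x[[field]])) {
    stop("missing required field `", field, "` in ", where, call. = FALSE)
  }
  x[[field]]
}

parse_line <- function(x, where) {
  check_fields(x, config_fields$line, where)
  regimen_line(
    drug = need(x, "drug", where),
    dosage_form = x$dosage_form %||% "",
    units_per_day = x$units_per_day %||% 0,
    unit_price = x$unit_price %||% 0,
    n_eligible = x$n_eligible %||% 0,
    duration_days = need(x, "duration_days", where),
    cohort_daily_cost = x$cohort_daily_cost
  )
}

parse_item <- function(x, where) {
  check_fields(x, config_fields$item, where)
  treatment_item(
    kind = need(x, "kind", where),
    label = need(x, "label", where),
    unit_price = need(x, "unit_price", where),
    duration = x$duration %||% 0,
    units_per_day = x$units_per_day %||% 0
  )
}

parse_ae <- function(x, where) {
  check_fields(x, config_fields$ae, where)
  items <- x$items %||% list()
  adverse_event_profile(
    name = need(x, "name", where),
    probability = need(x, "probability", where),
    items = lapply(seq_along(items), function(j) {
      parse_item(items[[j]], paste0(where, "$items[", j, "]"))
    })
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a full configuration document
#'
#' Parses and validates a YAML or JSON strategy configuration, including
#' the optional hemodialysis comparator and exchange rate.  Format is
#' chosen by file extension (`.yaml`/`.yml`/`.json`).
#'
#' @param path Path to the configuration file.
#' @return A list with `strategy` (a [strategy_definition()]), `dialysis`
#'   (a [dialysis_arm()] or `NULL`) and `rate` (IRR per USD, or `NULL`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  check_fields(raw, config_fields$top, basename(path))

  cohort_raw <- need(raw, "cohort", basename(path))
  check_fields(cohort_raw, config_fields$cohort, "cohort")
  cohort <- cohort_spec(
    n_patients = need(cohort_raw, "n_patients", "cohort"),
    horizon_days = cohort_raw$horizon_days %||% 365,
    patient_weight_kg = cohort_raw$patient_weight_kg %||% 70
  )

  hosp <- NULL
  if (!is.null(raw$hospitalization)) {
    check_fields(raw$hospitalization, config_fields$hospitalization,
                 "hospitalization")
    hosp <- global_tariff(
      k_value = need(raw$hospitalization, "k_value", "hospitalization"),
      multiplier = need(raw$hospitalization, "multiplier", "hospitalization")
    )
  }

  parse_lines <- function(field) {
    entries <- raw[[field]] %||% list()
    lapply(seq_along(entries), function(i) {
      parse_line(entries[[i]], paste0(field, "[", i, "]"))
    })
  }
  aes <- {
    entries <- raw$adverse_events %||% list()
    lapply(seq_along(entries), function(i) {
      parse_ae(entries[[i]], paste0("adverse_events[", i, "]"))
    })
  }

  strategy <- strategy_definition(
    name = raw$name %||% "unnamed",
    cohort = cohort, hospitalization = hosp,
    maintenance = parse_lines("maintenance"),
    adverse_events = aes,
    misc = parse_lines("misc")
  )

  dialysis <- NULL
  if (!is.null(raw$dialysis)) {
    check_fields(raw$dialysis, config_fields$dialysis, "dialysis")
    dialysis <- dialysis_arm(
      session_tariff = need(raw$dialysis, "session_tariff", "dialysis"),
      sessions_per_year = raw$dialysis$sessions_per_year %||% 156,
      adjunct_annual_per_patient =
        need(raw$dialysis, "adjunct_annual_per_patient", "dialysis"),
      cohort = cohort
    )
  }

  list(strategy = strategy, dialysis = dialysis,
       rate = if (is.null(raw$rate_irr_per_usd)) NULL else
         as.numeric(raw$rate_irr_per_usd))
}

#' Read a therapy strategy from a configuration file
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A fully validated [strategy_definition()].
#' @seealso [read_config()] for the dialysis arm and rate.
#' @export
read_strategy <- function(path) {
  read_config(path)$strategy
}

line_to_list <- function(l) {
  out <- list(drug = l$drug, dosage_form = l$dosage_form,
              units_per_day = l$units_per_day, unit_price = l$unit_price,
              n_eligible = l$n_eligible, duration_days = l$duration_days)
  if (!is.null(l$cohort_daily_cost)) {
    out$cohort_daily_cost <- l$cohort_daily_cost
  }
  out
}

strategy_to_list <- function(s, dialysis = NULL, rate = NULL) {
  stopifnot(inherits(s, "strategy_definition"))
  out <- list(
    name = s$name,
    cohort = list(n_patients = s$cohort$n_patients,
                  horizon_days = s$cohort$horizon_days,
                  patient_weight_kg = s$cohort$patient_weight_kg)
  )
  if (!is.null(rate)) out$rate_irr_per_usd <- rate
  if (!is.null(s$hospitalization)) {
    out$hospitalization <- list(k_value = s$hospitalization$k_value,
                                multiplier = s$hospitalization$multiplier)
  }
  out$maintenance <- lapply(s$maintenance, line_to_list)
  out$adverse_events <- lapply(s$adverse_events, function(a) {
    list(name = a$name, probability = a$probability,
         items = lapply(a$items, function(it) {
           list(kind = it$kind, label = it$label,
                unit_price = it$unit_price, duration = it$duration,
                units_per_day = it$units_per_day)
         }))
  })
  out$misc <- lapply(s$misc, line_to_list)
  if (!is.null(dialysis)) {
    out$dialysis <- list(
      session_tariff = dialysis$session_tariff,
      sessions_per_year = dialysis$sessions_per_year,
      adjunct_annual_per_patient = dialysis$adjunct_annual_per_patient
    )
  }
  out
}

#' Write a strategy configuration to disk
#'
#' Serializes a strategy (optionally with a dialysis arm and exchange
#' rate) to the canonical YAML or JSON configuration format; format is
#' chosen by file extension.  `read_config()` of the written file
#' reproduces the inputs exactly.
#'
#' @param s A [strategy_definition()].
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @param dialysis Optional [dialysis_arm()] to include.
#' @param rate Optional exchange rate (IRR per USD) to include.
#' @return `path`, invisibly.
#' @export
write_strategy <- function(s, path, dialysis = NULL, rate = NULL) {
  out <- strategy_to_list(s, dialysis = dialysis, rate = rate)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(out, precision = 15), path)
  }
  invisible(path)
}

#' Format whole Rials with thousands separators
#'
#' @param x Integer-valued numeric vector.
#' @return Character vector like `"170,718,326,900"`.
#' @export
format_irr <- function(x) {
  formatC(x, format = "f", digits = 0, big.mark = ",")
}

# ---- rendering -------------------------------------------------------------

render_block <- function(title, header, rows, format) {
  if (format == "tsv") {
    body <- vapply(rows, paste, character(1), collapse = "\t")
    return(paste(c(title, paste(header, collapse = "\t"), body),
                 collapse = "\n"))
  }
  mat <- do.call(rbind, c(list(header), rows))
  widths <- apply(nchar(mat), 2, max)
  fmt_row <- function(r) {
    paste0(formatC(r[1], width = -widths[1]),
           paste(mapply(formatC, r[-1], width = widths[-1]),
                 collapse = "  "),
           collapse = "")
  }
  lines <- apply(mat, 1, fmt_row)
  paste(c(title, strrep("-", max(nchar(lines))), lines), collapse = "\n")
}

# named atomic vectors must become lists to survive JSON as objects
json_ready <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, json_ready))
  if (is.numeric(x) && !is.null(names(x))) return(as.list(x))
  x
}

#' Render a report as text or JSON
#'
#' Deterministic rendering of a cost report, simulation result or
#' comparison report.  `"plain"` produces aligned tables with thousands
#' separators in the style of published cost tables; `"tsv"` the same
#' content tab-separated with raw integers; `"json"` a schema-stable JSON
#' document that parses back to the same numbers.
#'
#' @param x A `cost_report`, `simulation_result` or `comparison_report`.
#' @param format One of `"plain"`, `"tsv"`, `"json"`.
#' @return A single character string.
#' @export
render_report <- function(x, format = c("plain", "tsv", "json")) {
  format <- match.arg(format)
  UseMethod("render_report")
}

#' @export
render_report.cost_report <- function(x, format = c("plain", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(json_ready(unclass(x)), auto_unbox = TRUE,
                                         digits = NA, dataframe = "rows")))
  }
  num <- if (format == "plain") format_irr else function(v) {
    formatC(v, format = "f", digits = 0)
  }
  comp_rows <- lapply(names(x$components_irr), function(nm) {
    c(nm, num(x$components_irr[[nm]]), num(x$components_usd[[nm]]))
  })
  rows <- c(comp_rows, list(
    c("Total", num(x$total_irr), num(x$total_usd)),
    c("Per patient", num(x$per_patient_irr), num(x$per_patient_usd))
  ))
  blocks <- render_block(
    sprintf("Cost report: %s (n = %s patients, %s IRR/USD)", x$strategy,
            num(x$n_patients), num(x$rate)),
    c("Component", "IRR", "USD"), rows, format)
  if (nrow(x$ae_breakdown) > 0) {
    b <- x$ae_breakdown
    ae_rows <- lapply(seq_len(nrow(b)), function(i) {
      c(b$event[i], format(b$probability[i]), num(b$unit_cost_irr[i]),
        num(b$expected_per_patient_irr[i]), num(b$cohort_total_irr[i]),
        num(b$cohort_total_usd[i]))
    })
    ae_rows <- c(ae_rows, list(c(
      "Total", "", "", num(x$ae_per_patient_total_display),
      num(x$components_irr[["adverse_events"]]),
      num(x$components_usd[["adverse_events"]]))))
    blocks <- paste(blocks, render_block(
      "Adverse events (expected cost)",
      c("Event", "Prob.", "Unit cost/patient", "Expected/patient",
        "Cohort total IRR", "Cohort total USD"),
      ae_rows, format), sep = "\n\n")
  }
  blocks
}

#' @export
render_report.simulation_result <- function(x, format = c("plain", "tsv",
                                                          "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(json_ready(unclass(x)), auto_unbox = TRUE,
                                         digits = NA)))
  }
  num <- if (format == "plain") format_irr else function(v) {
    formatC(v, format = "f", digits = 0)
  }
  rows <- list(
    c("Replicates", formatC(x$n_replicates)),
    c("Patients per cohort", formatC(x$n_patients)),
    c("Seed", formatC(x$seed)),
    c("Grand mean AE cost/patient (IRR)", num(round_half_away(x$grand_mean))),
    c("Min replicate mean", num(round_half_away(x$min))),
    c("Max replicate mean", num(round_half_away(x$max))),
    c("SD of replicate means", num(round_half_away(x$sd))),
    c("Analytic expectation (IRR)",
      formatC(x$analytic_expectation, format = "f", digits = 1,
              big.mark = if (format == "plain") "," else ""))
  )
  render_block("Monte Carlo simulation of adverse-event cost",
               c("Quantity", "Value"), rows, format)
}

#' @export
render_report.comparison_report <- function(x, format = c("plain", "tsv",
                                                          "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(json_ready(unclass(x)), auto_unbox = TRUE,
                                         digits = NA)))
  }
  num <- if (format == "plain") format_irr else function(v) {
    formatC(v, format = "f", digits = 0)
  }
  rows <- list(
    c("Total IRR", num(x$total_irr[["a"]]), num(x$total_irr[["b"]]),
      num(x$incremental_total_irr)),
    c("Total USD", num(x$total_usd[["a"]]), num(x$total_usd[["b"]]),
      num(x$incremental_total_usd)),
    c("Per patient IRR", num(x$per_patient_irr[["a"]]),
      num(x$per_patient_irr[["b"]]), num(x$incremental_per_patient_irr)),
    c("Per patient USD", num(x$per_patient_usd[["a"]]),
      num(x$per_patient_usd[["b"]]), "")
  )
  delta_rows <- lapply(names(x$delta_components_irr), function(nm) {
    c(paste0("Delta ", nm), "", "", num(x$delta_components_irr[[nm]]))
  })
  ratio_line <- if (is.na(x$per_patient_ratio$value)) "" else
    sprintf("\nPer-patient cost ratio (B/A): %.4f", x$per_patient_ratio$value)
  paste0(render_block(
    sprintf("Comparison: %s (A) vs %s (B)", x$arm_a, x$arm_b),
    c("Quantity", paste0("A: ", x$arm_a), paste0("B: ", x$arm_b),
      "B - A"),
    c(rows, delta_rows), format), ratio_line)
}

#' Write the component-share breakdown as CSV
#'
#' One row per cost component with its share of the strategy total, for a
#' pie-chart style breakdown of where the budget goes.
#'
#' @param report A `cost_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_component_shares <- function(report, path) {
  stopifnot(inherits(report, "cost_report"))
  df <- data.frame(component = names(report$components_irr),
                   cost_irr = unname(report$components_irr),
                   share = unname(report$shares))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cost_report <- function(x, ...) {
  cat(render_report(x, "plain"), "\n")
  invisible(x)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(render_report(x, "plain"), "\n")
  invisible(x)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(render_report(x, "plain"), "\n")
  invisible(x)
}

#' @export
print.strategy_definition <- function(x, ...) {
  cat(sprintf(
    "<strategy_definition> %s: n = %d patients, %s, %d maintenance line(s), %d adverse event(s), %d misc line(s)\n",
    x$name, x$cohort$n_patients,
    if (is.null(x$hospitalization)) "no hospitalization tariff" else
      sprintf("tariff %d x %s IRR", x$hospitalization$multiplier,
              format_irr(x$hospitalization$k_value)),
    length(x$maintenance), length(x$adverse_events), length(x$misc)))
  invisible(x)
}
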