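# End-to-end pipeline, tabular I/O, and report writing.

#' Round half away from zero
#'
#' Report-time rounding convention (base R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places, default 0.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format GBP amounts for reports
#'
#' Whole pounds, half away from zero, thousands separator, leading minus for
#' negatives: `format_gbp(-735512.4)` is `"-£735,512"`.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_gbp <- function(x) {
  r <- round_half_away(x)
  paste0(ifelse(r < 0, "-", ""), "£",
         formatC(abs(r), format = "f", digits = 0, big.mark = ","))
}

#' Write / read a cohort as delimited files
#'
#' One row per patient plus a long-format companion event table
#' (id, kind, day), the package's patient-level interchange format.
#'
#' @param cohort A [vw_cohort()].
#' @param patients_path,events_path CSV file paths.
#' @return For `write_cohort`, the paths invisibly; for `read_cohort`, a
#'   validated `vw_cohort`.
#' @export
write_cohort <- function(cohort, patients_path, events_path) {
  stopifnot(inherits(cohort, "vw_cohort"))
  utils::write.csv(cohort$patients, patients_path, row.names = FALSE)
  utils::write.csv(cohort$events, events_path, row.names = FALSE)
  invisible(c(patients_path, events_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(patients_path, events_path) {
  vw_cohort(utils::read.csv(patients_path, stringsAsFactors = FALSE),
            utils::read.csv(events_path, stringsAsFactors = FALSE))
}

write_table3 <- function(inc, path) {
  df <- data.frame(
    summary = c("Total annual costs per population",
                "Total annual costs per patient"),
    virtual_ward = c(inc$vw$population_total, inc$vw$per_patient_total),
    standard_care = c(inc$sc$population_total, inc$sc$per_patient_total),
    incremental = c(inc$incremental_population, inc$incremental_per_patient)
  )
  utils::write.csv(df, path, row.names = FALSE)
  df
}

write_table4 <- function(inc, path) {
  df <- data.frame(
    cost_type = c("Total one-off set-up costs",
                  "Total on-going annual fixed costs",
                  "Total annual variable costs"),
    virtual_ward = c(inc$vw$setup_total, inc$vw$fixed_total,
                     inc$vw$variable_total),
    standard_care = c(inc$sc$setup_total, inc$sc$fixed_total,
                      inc$sc$variable_total)
  )
  df$incremental <- df$virtual_ward - df$standard_care
  utils::write.csv(df, path, row.names = FALSE)
  df
}

summary_text <- function(inc) {
  rows <- rbind(
    c("Summary results (including set-up costs)", "Virtual ward",
      "Standard care", "Incremental"),
    c("Total annual costs per population",
      format_gbp(inc$vw$population_total),
      format_gbp(inc$sc$population_total),
      format_gbp(inc$incremental_population)),
    c("Total annual costs per patient",
      format_gbp(inc$vw$per_patient_total),
      format_gbp(inc$sc$per_patient_total),
      format_gbp(inc$incremental_per_patient))
  )
  widths <- apply(nchar(rows), 2, max)
  apply(rows, 1, function(r) {
    paste0(formatC(r[1], width = -widths[1]), "  ",
           formatC(r[2], width = widths[2]), "  ",
           formatC(r[3], width = widths[3]), "  ",
           formatC(r[4], width = widths[4]))
  })
}

#' Run the full cost-comparison pipeline
#'
#' generate -> match -> horizon -> cost -> summarize -> sensitivity ->
#' break-even, writing `table3_summary.csv`, `table4_cost_types.csv`,
#' `table5_components.csv`, `tornado.csv`, `pairs.csv`, `balance.csv`,
#' `summary.txt` and `manifest.json` into `out_dir`. Structured progress
#' lines go to standard error. Outputs are deterministic given the
#' configuration and seed.
#'
#' @param config_path Path to a JSON configuration (see [load_config()]).
#' @param out_dir Writable output directory (created if absent).
#' @param seed Integer seed for cohort generation.
#' @param horizon_days,dsa_fraction,months_observed Optional overrides of the
#'   configured values.
#' @param log_level `"info"` (stage lines to stderr) or `"quiet"`.
#' @return The run manifest (list: config path and md5 hash, seed, stages
#'   executed, output paths, timestamp, headline results), invisibly.
#' @export
run_pipeline <- function(config_path, out_dir, seed,
                         horizon_days = NULL, dsa_fraction = NULL,
                         months_observed = NULL, log_level = "info") {
  log_line <- function(stage, msg) {
    if (identical(log_level, "info")) {
      message(sprintf("[vwcost] stage=%s %s", stage, msg))
    }
  }
  stage <- "load_config"
  manifest <- list(config = config_path,
                   config_md5 = unname(tools::md5sum(config_path)),
                   seed = as.integer(seed), stages = character(),
                   outputs = character(), timestamp = format(Sys.time()))
  run_stage <- function(name, expr) {
    stage <<- name
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    res
  }

  inputs <- run_stage("load_config", load_config(config_path))
  if (!is.null(horizon_days)) inputs$horizon_days <- as.numeric(horizon_days)
  if (!is.null(dsa_fraction)) inputs$dsa_fraction <- as.numeric(dsa_fraction)
  if (!is.null(months_observed)) {
    inputs$cohort$observed_months <- as.numeric(months_observed)
  }
  log_line("load_config", paste0("config=", config_path))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  gen <- run_stage("generate", generate_cohort(inputs, seed = seed))
  log_line("generate", sprintf("n_treated=%d n_controls=%d",
                               nrow(gen$vw$patients),
                               nrow(gen$controls$patients)))

  mr <- run_stage("match", {
    ps <- estimate_propensity(gen$vw$patients, gen$controls$patients)
    match_1to1(ps$treated_scores, ps$control_scores,
               treated = gen$vw$patients, controls = gen$controls$patients)
  })
  log_line("match", sprintf("pairs=%d unmatched=%d", nrow(mr$pairs),
                            length(mr$unmatched_treated)))

  sc_arm <- run_stage("build_sc_arm", build_sc_arm(mr, gen$vw, gen$controls))
  vw_arm <- gen$vw
  if (length(mr$unmatched_treated)) {
    keep <- !(vw_arm$patients$id %in% mr$unmatched_treated)
    vw_arm <- vw_cohort(vw_arm$patients[keep, , drop = FALSE],
                        vw_arm$events[vw_arm$events$id %in%
                                        vw_arm$patients$id[keep], , drop = FALSE])
    warning(length(mr$unmatched_treated),
            " unmatched treated patient(s) dropped from both arms")
  }

  hz <- inputs$horizon_days
  vw_f <- run_stage("horizon", apply_horizon(vw_arm, hz))
  sc_f <- apply_horizon(sc_arm, hz)

  ann <- annualize(vw_f, inputs$cohort$observed_months)
  bd <- run_stage("cost", list(
    vw = cost_cohort(vw_f, inputs, "vw", n_annual = ann$n_annual),
    sc = cost_cohort(sc_f, inputs, "sc")
  ))

  inc <- run_stage("summarize", {
    s_vw <- summarize_arm(bd$vw, inputs, "vw", scale = ann$factor)
    s_sc <- summarize_arm(bd$sc, inputs, "sc", scale = ann$factor)
    incremental(s_vw, s_sc)
  })
  log_line("summarize", sprintf("incremental_per_patient=%.2f",
                                inc$incremental_per_patient))
  dec <- decompose(bd$vw, bd$sc)

  dsa <- run_stage("dsa", one_way_dsa(inputs))
  be <- run_stage("breakeven", breakeven(inputs))
  log_line("breakeven", if (be$reachable) sprintf("threshold=%d", be$threshold)
           else "unreachable")

  out <- function(name) file.path(out_dir, name)
  write_table3(inc, out("table3_summary.csv"))
  write_table4(inc, out("table4_cost_types.csv"))
  utils::write.csv(dec, out("table5_components.csv"), row.names = FALSE)
  utils::write.csv(dsa[, c("parameter", "base", "low", "high",
                           "incr_low", "incr_high", "spread")],
                   out("tornado.csv"), row.names = FALSE)
  utils::write.csv(mr$pairs, out("pairs.csv"), row.names = FALSE)
  utils::write.csv(mr$balance, out("balance.csv"), row.names = FALSE)
  writeLines(summary_text(inc), out("summary.txt"))

  manifest$outputs <- vapply(
    c("table3_summary.csv", "table4_cost_types.csv", "table5_components.csv",
      "tornado.csv", "pairs.csv", "balance.csv", "summary.txt"),
    out, character(1))
  manifest$complete <- all(file.exists(manifest$outputs))
  manifest$results <- list(
    vw_population_total = inc$vw$population_total,
    sc_population_total = inc$sc$population_total,
    incremental_population = inc$incremental_population,
    incremental_per_patient = inc$incremental_per_patient,
    breakeven_threshold = be$threshold
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest$outputs <- c(manifest$outputs, out("manifest.json"))
  log_line("done", paste0("out=", out_dir))
  invisible(manifest)
}
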