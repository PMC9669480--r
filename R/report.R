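# Tabular reporting mirroring the published results table, plus a small
# run manifest for the command-line pipeline. CSV outputs always carry
# full precision; display rounding happens only here.

.fmt_icer <- function(x) ifelse(is.na(x), "-", sprintf("%.0f", x))

#' Render the base-case / scenario results table
#'
#' Builds the two-row-per-analysis results table (cost, incremental
#' cost, effectiveness in QALYs and life-years, incremental
#' effectiveness, ICER per QALY and per life-year) with the publication's
#' display rounding: costs and ICERs to whole USD, effectiveness to two
#' decimals. Dominant scenarios keep their negative ICER, flagged in the
#' `note` column.
#'
#' @param base A `pfo_cea` for the base case.
#' @param scenarios Named list of `pfo_cea` objects for scenario analyses.
#' @return A tibble with one row per strategy per analysis.
#' @export
render_table3 <- function(base, scenarios = list()) {
  one <- function(cmp, label) {
    i <- cmp$intervention
    c <- cmp$comparator
    tibble::tibble(
      analysis = label,
      strategy = c("Medical therapy", "PFO closure"),
      cost = round(c(c$cost_discounted, i$cost_discounted)),
      incre_cost = c(NA, round(cmp$d_cost)),
      eff_qaly = round(c(c$qaly_discounted, i$qaly_discounted), 2),
      incre_eff_qaly = c(NA, round(cmp$d_qaly, 2)),
      icer_per_qaly = c(NA_character_, .fmt_icer(cmp$icer_per_qaly)),
      eff_ly = round(c(c$ly_discounted, i$ly_discounted), 2),
      incre_eff_ly = c(NA, round(cmp$d_ly, 2)),
      icer_per_ly = c(NA_character_, .fmt_icer(cmp$icer_per_ly)),
      note = c("", if (cmp$dominance == "none") "" else cmp$dominance)
    )
  }
  out <- one(base, "Base case")
  for (nm in names(scenarios)) {
    out <- dplyr::bind_rows(out, one(scenarios[[nm]], nm))
  }
  out
}

#' Run the full base-case and scenario analysis
#'
#' Convenience wrapper: runs both arms for the base case and each
#' requested scenario and renders the combined results table.
#'
#' @param params A `pfo_params` object.
#' @param scenarios Character vector of scenario ids.
#' @return A list with `comparisons` (named `pfo_cea` list, base first)
#'   and `table` (the rendered tibble).
#' @export
run_scenario_table <- function(params,
                               scenarios = c("warfarin", "dabigatran",
                                             "rivaroxaban", "sf6d", "eq5d")) {
  run_one <- function(id) {
    sc <- apply_scenario(params, id)
    cl <- run_cohort(sc$closure, sc$params, keep_trace = FALSE)
    me <- run_cohort(sc$medical, sc$params, keep_trace = FALSE)
    cea_compare(cl, me, params = sc$params)
  }
  base <- run_one("base")
  scs <- setNames(lapply(scenarios, run_one), scenarios)
  list(comparisons = c(list(base = base), scs), table = render_table3(base, scs))
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records the command, configuration file hash, seeds, package version,
#' timestamp and output files as JSON next to the outputs.
#'
#' @param path Manifest file path (JSON).
#' @param command Command or subcommand name.
#' @param config_path Configuration file used (hashed if it exists).
#' @param seed Seed(s) used, if any.
#' @param outputs Character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config_path = NULL, seed = NULL,
                           outputs = character()) {
  cfg_hash <- if (!is.null(config_path) && file.exists(config_path)) {
    # content hash without extra dependencies: length + sum of bytes
    bytes <- readBin(config_path, "raw", file.info(config_path)$size)
    sprintf("size%d-sum%.0f", length(bytes), sum(as.integer(bytes)))
  } else {
    NULL
  }
  manifest <- list(
    command = command,
    config = config_path,
    config_hash = cfg_hash,
    seed = seed,
    package_version = as.character(utils::packageVersion("pfocea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
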