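#' Bundle an enzyme's characterization values
#'
#' Container for the per-enzyme summary quantities the comparison report
#' consumes. Any field may be left `NA`; comparisons omit missing fields
#' rather than defaulting them.
#'
#' @param name Enzyme label (e.g. `"WT"`, `"N130D"`).
#' @param specific_activity IU/mg.
#' @param optimal_temperature Degrees C.
#' @param t_half Half-life at the stress temperature, minutes.
#' @param tm Unfolding midpoint, degrees C.
#' @param km umol/L.
#' @param kcat 1/s.
#' @param efficiency L/(mmol*s); computed from `kcat`/`km` when absent.
#' @return List of class `enzyme_characterization`.
#' @export
enzyme_characterization <- function(name, specific_activity = NA_real_,
                                    optimal_temperature = NA_real_,
                                    t_half = NA_real_, tm = NA_real_,
                                    km = NA_real_, kcat = NA_real_,
                                    efficiency = NA_real_) {
  if (is.na(efficiency) && !is.na(kcat) && !is.na(km))
    efficiency <- catalytic_efficiency(kcat, km)
  structure(list(name = name, specific_activity = specific_activity,
                 optimal_temperature = optimal_temperature,
                 t_half = t_half, tm = tm, km = km, kcat = kcat,
                 efficiency = efficiency),
            class = "enzyme_characterization")
}

ratio_field <- function(mut, wt, field) {
  m <- mut[[field]]; w <- wt[[field]]
  if (is.na(m) || is.na(w)) return(NA_real_)
  if (w == 0) stop("wild-type ", field, " is zero; fold change undefined")
  m / w
}

#' Wild-type-relative comparison report
#'
#' Fold changes and deltas in the conventions of enzyme-engineering
#' tables: half-life, specific-activity and efficiency as mutant/WT
#' folds rounded to 1 decimal; Tm and optimal-temperature shifts as
#' differences (Tm to 2 decimals); Km as percent decrease and kcat as
#' percent increase, both rounded to integers. Fields missing in either
#' characterization are reported `NA`.
#'
#' @param wild_type,mutant [enzyme_characterization()] objects.
#' @return List of class `comparison_report`: `wild_type`, `mutant`,
#'   `fold_t_half`, `delta_tm`, `delta_t_opt`, `pct_change_km`
#'   (positive = decrease), `pct_change_kcat` (positive = increase),
#'   `fold_specific_activity`, `fold_efficiency`.
#' @export
compare_characterizations <- function(wild_type, mutant) {
  stopifnot(inherits(wild_type, "enzyme_characterization"),
            inherits(mutant, "enzyme_characterization"))
  delta <- function(field) {
    m <- mutant[[field]]; w <- wild_type[[field]]
    if (is.na(m) || is.na(w)) NA_real_ else m - w
  }
  pct <- function(field, direction) {
    m <- mutant[[field]]; w <- wild_type[[field]]
    if (is.na(m) || is.na(w)) return(NA_real_)
    if (w == 0) stop("wild-type ", field, " is zero; percent change undefined")
    round(direction * (m - w) / w * 100)
  }
  rnd1 <- function(x) if (is.na(x)) NA_real_ else round(x, 1)
  structure(list(
    wild_type = wild_type$name, mutant = mutant$name,
    fold_t_half = rnd1(ratio_field(mutant, wild_type, "t_half")),
    delta_tm = if (is.na(delta("tm"))) NA_real_ else round(delta("tm"), 2),
    delta_t_opt = delta("optimal_temperature"),
    pct_change_km = pct("km", -1),
    pct_change_kcat = pct("kcat", +1),
    fold_specific_activity = rnd1(ratio_field(mutant, wild_type, "specific_activity")),
    fold_efficiency = rnd1(ratio_field(mutant, wild_type, "efficiency"))
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("%s vs %s:\n", x$mutant, x$wild_type))
  cat(sprintf("  half-life fold: %s\n", format(x$fold_t_half)))
  cat(sprintf("  delta Tm: %s C, delta Topt: %s C\n",
              format(x$delta_tm), format(x$delta_t_opt)))
  cat(sprintf("  Km change: %s%% decrease, kcat change: %s%% increase\n",
              format(x$pct_change_km), format(x$pct_change_kcat)))
  cat(sprintf("  specific activity fold: %s, efficiency fold: %s\n",
              format(x$fold_specific_activity), format(x$fold_efficiency)))
  invisible(x)
}

read_series_csv <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(basename(path), " is missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read assay series CSVs
#'
#' Header-validated readers for the three assay series: inactivation
#' (`time`, `residual_activity`), melting (`temperature`, `signal`) and
#' rate (`substrate`, `rate`).
#'
#' @param path CSV path.
#' @return Data frame with the validated columns.
#' @export
read_decay_csv <- function(path) read_series_csv(path, c("time", "residual_activity"))

#' @rdname read_decay_csv
#' @export
read_melt_csv <- function(path) read_series_csv(path, c("temperature", "signal"))

#' @rdname read_decay_csv
#' @export
read_rates_csv <- function(path) read_series_csv(path, c("substrate", "rate"))

#' Write a characterization or comparison report
#'
#' @param x An `enzyme_characterization` or `comparison_report`.
#' @param path Output path; `.json` switches to JSON, otherwise CSV.
#' @export
write_report <- function(x, path) {
  flat <- x[!vapply(x, is.list, logical(1))]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.csv(as.data.frame(flat, stringsAsFactors = FALSE), path,
                     row.names = FALSE)
  }
  invisible(path)
}
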