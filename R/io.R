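#' Read a patient configuration file
#'
#' Reads a YAML or JSON file with keys mirroring [valve_measurements()]
#' (plus an optional `material` block with `c1`, `c2`, `A_ref`).  Missing
#' keys fall back to the package defaults with a warning; unknown keys and
#' out-of-range values raise errors naming the offending key, so unit
#' mistakes (e.g. centimetres) are caught by the plausibility bounds.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [valve_measurements()] object.
#' @export
read_patient_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop(sprintf("unsupported config format '.%s' (use yaml or json)", ext),
         call. = FALSE))
  if (!is.list(raw)) stop("config must be a key-value mapping", call. = FALSE)
  known <- c(names(.meas_bounds), "material")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  mat_raw <- raw$material
  raw$material <- NULL
  missing_keys <- setdiff(names(.meas_bounds), names(raw))
  if (length(missing_keys))
    warning(sprintf("config keys missing, defaults applied: %s",
                    paste(missing_keys, collapse = ", ")), call. = FALSE)
  material <- if (is.null(mat_raw)) chorda_material() else {
    bad <- setdiff(names(mat_raw), c("c1", "c2", "A_ref"))
    if (length(bad))
      stop(sprintf("unknown material key(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    do.call(chorda_material, modifyList(
      list(c1 = 352.4, c2 = 0.1907, A_ref = 0.197), mat_raw))
  }
  do.call(valve_measurements, c(raw, list(material = material)))
}

#' Default cohort sampling distributions
#'
#' Mean and standard deviation per measurement, from the reference cohort
#' statistics.  Constitutive parameters are treated as fixed constants
#' (std 0).
#'
#' @return A data frame with columns `key`, `mean`, `sd`.
#' @export
cohort_distributions <- function() {
  data.frame(
    key = c("MAD_pre", "IPD_pre", "TH_pre", "TH_opt", "delta_a", "delta_p",
            "h_a", "h_p", "l_a", "l_p", "B"),
    mean = c(40, 44.6, 12.4, 6.8, 32.6, 56.8, 45, 28, 18, 13, 500),
    sd = c(1.9, 0.39, 0.13, 0, 2.5, 5.2, 8.6, 8.1, 0, 0, 0))
}

#' Generate a synthetic patient cohort
#'
#' Independent truncated-normal draws per measurement (truncated at the
#' plausibility bounds and, for `TH_opt`, below `TH_pre`), deterministic
#' given the seed.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed.
#' @param distributions A data frame as returned by
#'   [cohort_distributions()] (columns `key`, `mean`, `sd`).
#' @param material A [chorda_material()] shared by the cohort.
#' @return A list of [valve_measurements()] objects.
#' @export
generate_cohort <- function(n_patients, seed,
                            distributions = cohort_distributions(),
                            material = chorda_material()) {
  stopifnot(n_patients >= 1, all(distributions$sd >= 0))
  set.seed(seed)
  draw_trunc <- function(mean, sd, lo, hi) {
    if (sd == 0) return(min(max(mean, lo), hi))
    for (i in 1:1000) {
      x <- rnorm(1, mean, sd)
      if (x > lo && x < hi) return(x)
    }
    min(max(mean, lo), hi)
  }
  lapply(seq_len(n_patients), function(i) {
    vals <- list()
    for (j in seq_len(nrow(distributions))) {
      key <- distributions$key[j]
      b <- .meas_bounds[[key]]
      vals[[key]] <- draw_trunc(distributions$mean[j], distributions$sd[j],
                                b[1] + 1e-6, b[2] - 1e-6)
    }
    # keep the coaptation target strictly below the tenting height
    if (vals$TH_opt >= vals$TH_pre) vals$TH_opt <- 0.55 * vals$TH_pre
    do.call(valve_measurements, c(vals, list(material = material)))
  })
}

#' Build a run report
#'
#' Collects inputs, the preoperative summary, per-scenario postoperative
#' summaries and the indicator table into one serializable structure.
#' The timestamp lives in a sidecar field excluded from the canonical
#' content so that identical runs serialize identically.
#'
#' @param preop A `preop_configuration`.
#' @param comparison A [compare_scenarios()] result (or `NULL`).
#' @return An object of class `run_report`.
#' @export
make_run_report <- function(preop, comparison = NULL) {
  meas <- preop$measurements
  sols <- attr(comparison, "solutions")
  postop_summary <- lapply(sols, function(s) list(
    scenario = s$scenario, r = s$surgical$r, MAD_po = s$MAD_po,
    IPD_po = s$IPD_po, h_a_po = s$h_po[["a"]], h_p_po = s$h_po[["p"]],
    T_po = as.list(s$T_po), lam_po = as.list(s$lam_po),
    M_po = as.list(s$M_po), residual_norm = s$residual_norm))
  ind_cols <- c("scenario", "Mr_a", "Mr_p", "Tr_a", "Tr_p", "lr_a", "lr_p")
  ind <- if (is.null(comparison)) NULL else
    as.data.frame(comparison[comparison$converged, ind_cols])
  structure(list(
    inputs = list(
      MAD_pre = meas$MAD_pre, IPD_pre = meas$IPD_pre, TH_pre = meas$TH_pre,
      TH_opt = meas$TH_opt, delta_a = meas$delta_a, delta_p = meas$delta_p,
      h_a = meas$h_a, h_p = meas$h_p, l_a = meas$l_a, l_p = meas$l_p,
      B = meas$B, material = unclass(meas$material)),
    preop = list(
      P_pre = as.list(preop$P_pre), lam_pre = as.list(preop$lam_pre),
      L_c = as.list(preop$L_c), M_pre = as.list(preop$M_pre),
      T_pre = as.list(preop$T_pre),
      tip_a = preop$system$b_a, tip_p = preop$system$b_p,
      m_a = preop$system$m_a, m_p = preop$system$m_p,
      IPD = preop$system$d,
      provenance = preop$provenance),
    postop = postop_summary,
    indicators = ind,
    software = list(package = "mvelastica",
                    version = as.character(utils::packageVersion("mvelastica"))),
    timestamp = format(Sys.time(), tz = "UTC")
  ), class = "run_report")
}

#' Write a run report
#'
#' JSON (canonical field order, timestamp excluded) or CSV (the indicator
#' table, one row per scenario).
#'
#' @param report A [make_run_report()] object.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  stopifnot(inherits(report, "run_report"))
  format <- match.arg(format)
  if (format == "json") {
    canonical <- report[setdiff(names(report), "timestamp")]
    ok <- tryCatch({
      jsonlite::write_json(canonical, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
      TRUE
    }, error = function(e)
      stop(sprintf("failed to write report to '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  } else {
    if (is.null(report$indicators))
      stop("report has no indicator table to write as CSV", call. = FALSE)
    write.csv(report$indicators, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON run report
#' @param path Path written by [write_report()].
#' @return The parsed report (plain list).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
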