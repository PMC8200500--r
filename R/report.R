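## Tolerance evaluation, JSON reports, contingency tables and the
## error-injection sensitivity study.

#' Default QA tolerances
#'
#' Junction statistic +/-0.3 (30\% of the in-field intensity), VMAT
#' band +/-1.5\%, picket-fence leaf position 1 mm, light-rad inner BB
#' deviation 2 mm, gamma pass rate 95\%, Winston-Lutz offset 1 mm.
#' Institutions can override any entry.
#'
#' @return Named list of tolerances.
#' @export
qaTolerances <- function() {
  list(junction = 0.3, vmat_band_pct = 1.5, picket_leaf_mm = 1,
       lightrad_mm = 2, gamma_pass_pct = 95, winston_lutz_mm = 1)
}

.payload_of <- function(result) {
  switch(class(result),
    JunctionResult = list(values = as.list(result@values),
                          worst = result@worst),
    LightRadResult = list(inner_distances_mm = result@innerDistances,
                          deviations_mm = result@deviations,
                          detected_count = result@detectedCount),
    PicketFenceResult = list(
      deviations_mm = as.vector(result@deviation[result@detected]),
      per_gap_spacing_mm = result@perGapSpacing,
      max_single_leaf_deviation_mm = result@maxSingleLeafDeviation,
      percent_passing = result@percentPassing),
    VMATBandResult = list(corrected = result@corrected,
                          percent_diff = result@percentDiff,
                          diff_abs = result@diffAbs),
    GammaResult = list(pass_rate_pct = result@passRate,
                       dd_pct = result@ddPct, dta_mm = result@dtaMm),
    WinstonLutzResult = list(offset_mm = result@offset,
                             magnitude_mm = result@magnitude),
    stop("unsupported result type: ", class(result), call. = FALSE))
}

.test_of_result <- function(result) {
  switch(class(result),
    JunctionResult = "junction", LightRadResult = "lightrad",
    PicketFenceResult = "picketfence", VMATBandResult = "vmat",
    GammaResult = "gamma", WinstonLutzResult = "winston_lutz")
}

.pass_from_payload <- function(test, payload, tol) {
  switch(test,
    junction = all(abs(unlist(payload$values)) <= tol$junction),
    lightrad = length(payload$deviations_mm) > 0 &&
      all(abs(payload$deviations_mm) <= tol$lightrad_mm),
    picketfence = all(abs(payload$deviations_mm) <= tol$picket_leaf_mm),
    vmat = all(abs(payload$percent_diff) <= tol$vmat_band_pct),
    gamma = payload$pass_rate_pct >= tol$gamma_pass_pct,
    winston_lutz = payload$magnitude_mm <= tol$winston_lutz_mm,
    stop("unknown test '", test, "'", call. = FALSE))
}

#' Evaluate a test result against configured tolerances
#'
#' Recomputes the pass flag of a measured result from a tolerance
#' configuration (defaults \code{\link{qaTolerances}}) and wraps it in a
#' serializable \code{\linkS4class{QAReport}}.  Also accepts an
#' existing \code{QAReport}, whose payload is re-evaluated -- the
#' operation is idempotent.
#'
#' @param result a test result object or a \code{QAReport}.
#' @param tolerances tolerance configuration list.
#' @param machine machine label.
#' @param date ISO date string.
#' @return A \code{\linkS4class{QAReport}}.
#' @export
evaluateTolerances <- function(result, tolerances = qaTolerances(),
                               machine = "LINAC1",
                               date = format(Sys.Date())) {
  tol <- utils::modifyList(qaTolerances(), tolerances)
  if (is(result, "QAReport")) {
    pass <- .pass_from_payload(result@testType, result@payload, tol)
    return(new("QAReport", testType = result@testType,
               machine = result@machine, date = result@date,
               payload = result@payload, tolerances = tol, pass = pass))
  }
  test <- .test_of_result(result)
  payload <- .payload_of(result)
  new("QAReport", testType = test, machine = machine, date = date,
      payload = payload, tolerances = tol,
      pass = .pass_from_payload(test, payload, tol))
}

#' Write a QA report as JSON
#'
#' @param report a \code{\linkS4class{QAReport}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeQAReport <- function(report, path) {
  jsonlite::write_json(list(
    schema_version = "1.0", test_type = report@testType,
    machine = report@machine, date = report@date,
    payload = report@payload, tolerances = report@tolerances,
    pass = report@pass), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a QA report from JSON
#'
#' @param path a report written by \code{\link{writeQAReport}}.
#' @return A \code{\linkS4class{QAReport}}.
#' @export
readQAReport <- function(path) {
  r <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(r$test_type))
    stop("format error: not a QA report", call. = FALSE)
  new("QAReport", testType = r$test_type, machine = r$machine,
      date = r$date, payload = r$payload, tolerances = r$tolerances,
      pass = r$pass)
}

#' Pass/fail contingency table with sensitivity
#'
#' Failing is the positive class: \code{sensitivity} is the percentage
#' of ground-truth failures that the measured analysis also flags.
#'
#' @param truthPass logical vector: ground-truth pass flags.
#' @param measuredPass logical vector: measured pass flags, paired.
#' @return A \code{\linkS4class{ContingencyTable}}.
#' @examples
#' contingencyTable(c(TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE))
#' @export
contingencyTable <- function(truthPass, measuredPass) {
  if (length(truthPass) == 0)
    stop("empty pass/fail lists", call. = FALSE)
  if (length(truthPass) != length(measuredPass))
    stop("pass/fail lists must be paired (equal length)", call. = FALSE)
  tf <- !truthPass; mf <- !measuredPass
  counts <- c(tp = sum(tf & mf), fn = sum(tf & !mf),
              fp = sum(!tf & mf), tn = sum(!tf & !mf))
  sens <- if (sum(tf) == 0) NA_real_ else 100 * counts[["tp"]] / sum(tf)
  new("ContingencyTable", counts = counts, sensitivity = sens)
}

#' Error-injection sensitivity study
#'
#' Re-creates the synthetic analogue of the error-injection protocol:
#' junction plans delivered with gaps/overlaps of 2 and 4 mm, and the
#' light-rad phantom set up at SSDs from 95 to 105 cm.  Ground truth is
#' the analyzer verdict on the noiseless render; the measured verdict
#' comes from renders at \code{noiseSigma}.  Returns per-test
#' contingency tables plus the pooled table.
#'
#' @param config a \code{\link{RenderConfig}}.
#' @param noiseSigma relative noise for the measured arm.
#' @param seed RNG seed.
#' @param junctionErrorsMm injected junction errors (signed mm).
#' @param ssdMm injected phantom SSDs (mm).
#' @return list with elements \code{junction}, \code{lightrad},
#'   \code{overall} (\code{\linkS4class{ContingencyTable}}s) and
#'   \code{details} (data.frame of injected values and verdicts).
#' @export
runSensitivityStudy <- function(config = RenderConfig(), noiseSigma = 0.01,
                                seed = 1,
                                junctionErrorsMm = c(-4, -2, 0, 2, 4),
                                ssdMm = c(950, 975, 990, 1000, 1010,
                                          1025, 1050)) {
  details <- data.frame()
  jplan <- buildJunctionPlan()
  for (i in seq_along(junctionErrorsMm)) {
    e <- junctionErrorsMm[i]
    ideal <- analyzeJunction(renderJunctionImage(jplan, config,
      ErrorModel(junctionError = e)), jplan)
    meas <- analyzeJunction(renderJunctionImage(jplan, config,
      ErrorModel(junctionError = e, noiseSigma = noiseSigma,
                 seed = seed + i)), jplan)
    details <- rbind(details, data.frame(test = "junction", injected = e,
      truth_pass = isPass(ideal), measured_pass = isPass(meas)))
  }
  lplan <- buildLightRadPlan()
  for (i in seq_along(ssdMm)) {
    s <- ssdMm[i]
    ideal <- analyzeLightRad(renderLightRadImage(lplan, config,
      ErrorModel(ssd = s)), lplan)
    meas <- analyzeLightRad(renderLightRadImage(lplan, config,
      ErrorModel(ssd = s, noiseSigma = noiseSigma, seed = seed + 100 + i)),
      lplan)
    details <- rbind(details, data.frame(test = "lightrad", injected = s,
      truth_pass = isPass(ideal), measured_pass = isPass(meas)))
  }
  jd <- details[details$test == "junction", ]
  ld <- details[details$test == "lightrad", ]
  list(
    junction = contingencyTable(jd$truth_pass, jd$measured_pass),
    lightrad = contingencyTable(ld$truth_pass, ld$measured_pass),
    overall = contingencyTable(details$truth_pass, details$measured_pass),
    details = details)
}
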