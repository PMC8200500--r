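## JSON "field parameter instruction" format: a small, versioned schema
## from which any builder plan can be constructed without R code.
##
## {
##   "schema_version": "1.0",
##   "test_type": "picketfence",          # any QAPlan test type
##   "energy": "6X", "machine": "LINAC1",
##   # EITHER parametric descriptors, e.g.
##   "picketfence": {"n_pickets": 9, "spacing_mm": 15, "gap_mm": 2,
##                    "leaf_offsets_mm": 0},
##   "junction":    {"axes": [...], "junction_error_mm": 0, "field_mm": 120},
##   "open":        {"field_mm": [100, 100], "gantry_deg": 0},
##   "lightrad":    {"field_mm": 100, "inner_inset_mm": 5, "outer_inset_mm": 25},
##   "winston_lutz":{"combos": [{"gantry":0,"collimator":0,"couch":0}, ...]},
##   "vmat":        {"family": "t2_doserate_gantry", "band_count": 7,
##                    "inject_mlc_errors": false},
##   "dlg":         {"gap_widths_mm": [2,4,6,10,14,16,20]},
##   # OR an explicit beam table:
##   "beams": [{"name": "B1", "mu": 100, "control_points": [
##       {"meterset_weight": 0, "gantry_deg": 0, "collimator_deg": 0,
##        "couch_deg": 0, "jaws": {"X1":-50,"X2":50,"Y1":-50,"Y2":50},
##        "mlc_a": [...], "mlc_b": [...]}, ...]}],
##   "mlc_boundaries_mm": [...]            # with explicit beams only
## }

#' Load a QA plan from JSON field instructions
#'
#' Parametric instruction blocks produce exactly the plan the
#' corresponding \code{build*Plan()} call would; an explicit
#' \code{beams} table is reproduced verbatim.
#'
#' @param path JSON instruction file.
#' @return A \code{\linkS4class{QAPlan}}.
#' @seealso The schema sketch in the package source; \code{\link{buildPicketFencePlan}}.
#' @export
loadFieldInstructions <- function(path) {
  ins <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e)
                    stop("schema error: unparseable JSON: ",
                         conditionMessage(e), call. = FALSE))
  need <- function(key) {
    if (is.null(ins[[key]]))
      stop("schema error: missing key '", key, "'", call. = FALSE)
    ins[[key]]
  }
  ttype <- need("test_type")
  if (!ttype %in% .qa_test_types)
    stop("schema error: unknown test_type '", ttype, "'", call. = FALSE)
  energy <- ins$energy %||% "6X"
  machine <- ins$machine %||% "LINAC1"

  if (!is.null(ins$beams)) {
    beams_raw <- ins$beams
    if (length(beams_raw) == 0)
      stop("schema error: key 'beams' must be a non-empty list",
           call. = FALSE)
    mlc <- if (is.null(ins$mlc_boundaries_mm)) millennium120() else
      MLCModel(ins$mlc_boundaries_mm, name = ins$mlc_name %||% "custom")
    bms <- lapply(beams_raw, function(b) {
      cps_raw <- b$control_points
      if (is.null(cps_raw) || length(cps_raw) < 2)
        stop("schema error: each beam needs >= 2 control_points",
             call. = FALSE)
      cps <- lapply(cps_raw, function(cp) {
        if (is.null(cp$jaws))
          stop("schema error: control point missing key 'jaws'", call. = FALSE)
        controlPoint(cp$meterset_weight %||%
                       stop("schema error: missing key 'meterset_weight'"),
          unlist(cp$jaws)[c("X1", "X2", "Y1", "Y2")],
          unlist(cp$mlc_a), unlist(cp$mlc_b),
          gantry_deg = cp$gantry_deg %||% 0,
          collimator_deg = cp$collimator_deg %||% 0,
          couch_deg = cp$couch_deg %||% 0)
      })
      list(name = b$name %||% "BEAM", mu = b$mu %||% 100,
           control_points = cps)
    })
    return(QAPlan(ttype, beams = bms, mlc = mlc, machineName = machine,
                  energy = energy, meta = .restore_meta(ins$meta %||% list())))
  }

  switch(ttype,
    open = {
      p <- ins$open %||% list()
      buildOpenFieldPlan(p$field_mm %||% c(100, 100), energy,
                         p$gantry_deg %||% 0, machine)
    },
    junction = {
      p <- ins$junction %||% list()
      buildJunctionPlan(p$axes %||% c("vertical", "horizontal"),
                        p$junction_error_mm %||% 0, p$field_mm %||% 120,
                        energy, p$gantry_deg %||% 0, machine)
    },
    lightrad = {
      p <- ins$lightrad %||% list()
      buildLightRadPlan(p$field_mm %||% 100, p$inner_inset_mm %||% 5,
                        p$outer_inset_mm %||% 25, energy,
                        p$gantry_deg %||% 0, machine)
    },
    picketfence = {
      p <- ins$picketfence %||% list()
      spec <- PicketFenceSpec(p$n_pickets %||% 9, p$spacing_mm %||% 15,
                              p$gap_mm %||% 2,
                              as.integer(p$active_pairs %||% integer(0)))
      buildPicketFencePlan(spec, p$leaf_offsets_mm %||% 0,
                           p$y_aperture_mm %||% c(-100, 100), energy,
                           p$gantry_deg %||% 0, machine)
    },
    winston_lutz = {
      p <- ins$winston_lutz %||% list()
      combos <- if (is.null(p$combos))
        data.frame(gantry = c(0, 90, 180, 270), collimator = 0, couch = 0)
      else do.call(rbind, lapply(p$combos, as.data.frame))
      buildWinstonLutzPlan(combos, p$field_mm %||% 20, energy, machine)
    },
    dlg = {
      p <- ins$dlg %||% list()
      buildDlgPlan(p$gap_widths_mm %||% c(2, 4, 6, 10, 14, 16, 20),
                   energy, machine)
    },
    {
      ## vmat_t1 / t2 / t3
      p <- ins$vmat %||% list()
      fam <- p$family %||% switch(ttype,
        vmat_t1 = "t1_static_dmlc", vmat_t2 = "t2_doserate_gantry",
        vmat_t3 = "t3_mlc_speed")
      buildVmatPlan(fam, p$band_count, isTRUE(p$inject_mlc_errors),
                    energy, machine)
    })
}

#' Write JSON field instructions for a plan
#'
#' Serializes the explicit beam table (always reproducible, if verbose);
#' the parametric blocks are meant to be authored by hand.
#'
#' @param plan a \code{\linkS4class{QAPlan}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeFieldInstructions <- function(plan, path) {
  validObject(plan)
  bms <- lapply(plan@beams, function(b) list(
    name = b$name, mu = b$mu,
    control_points = lapply(b$control_points, function(cp) list(
      meterset_weight = cp$meterset_weight, gantry_deg = cp$gantry_deg,
      collimator_deg = cp$collimator_deg, couch_deg = cp$couch_deg,
      jaws = as.list(cp$jaws), mlc_a = cp$mlc_a, mlc_b = cp$mlc_b))))
  jsonlite::write_json(list(
    schema_version = "1.0", test_type = plan@testType,
    energy = plan@energy, machine = plan@machineName,
    mlc_boundaries_mm = leafBoundaries(plan@mlc),
    mlc_name = plan@mlc@name,
    beams = bms, meta = plan@meta), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
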