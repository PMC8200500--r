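## Minimal DICOM codec: explicit VR little endian, the subset of the
## RT-Plan / RT-Image modules this package emits.  Deterministic UIDs so
## repeated writes of the same plan are byte-identical.

.uid_ts_explicit_le <- "1.2.840.10008.1.2.1"
.uid_rtplan <- "1.2.840.10008.5.1.4.1.1.481.5"
.uid_rtimage <- "1.2.840.10008.5.1.4.1.1.481.1"
.uid_root <- "2.25.876543"

.uid <- function(seed, k) sprintf("%s.%d.%d", .uid_root, as.integer(seed), k)

.u16le <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
.u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.el <- function(group, elem, vr, value) {
  hdr <- c(.u16le(group), .u16le(elem), charToRaw(vr))
  if (vr %in% .long_vrs)
    c(hdr, as.raw(c(0, 0)), .u32le(length(value)), value)
  else c(hdr, .u16le(length(value)), value)
}

.pad <- function(r, fill = as.raw(0x20)) if (length(r) %% 2) c(r, fill) else r
.vstr <- function(s) .pad(charToRaw(as.character(s)))
.vui <- function(s) .pad(charToRaw(as.character(s)), as.raw(0))

.fmtDS <- function(x) {
  s <- formatC(x, digits = 10, format = "g")
  if (nchar(s) > 16) s <- formatC(x, digits = 8, format = "g")
  s
}
.vds <- function(x) .vstr(paste(vapply(x, .fmtDS, character(1)), collapse = "\\"))
.vis <- function(x) .vstr(paste(as.integer(round(x)), collapse = "\\"))
.vus <- function(x) do.call(c, lapply(as.integer(x), .u16le))

.item <- function(content) c(.u16le(0xFFFE), .u16le(0xE000),
                             .u32le(length(content)), content)
.sq <- function(group, elem, items)
  .el(group, elem, "SQ", do.call(c, c(items, list(raw(0)))))

.file_meta <- function(sop_class, sop_instance) {
  body <- c(
    .el(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .el(0x0002, 0x0002, "UI", .vui(sop_class)),
    .el(0x0002, 0x0003, "UI", .vui(sop_instance)),
    .el(0x0002, 0x0010, "UI", .vui(.uid_ts_explicit_le)),
    .el(0x0002, 0x0012, "UI", .vui(paste0(.uid_root, ".1"))))
  c(raw(128), charToRaw("DICM"),
    .el(0x0002, 0x0000, "UL", .u32le(length(body))), body)
}

## ---- writer: RT-Plan ---------------------------------------------------

.bld_seq <- function(mlc) {
  np <- nPairs(mlc)
  .sq(0x300A, 0x00B6, list(
    .item(c(.el(0x300A, 0x00B8, "CS", .vstr("ASYMX")),
            .el(0x300A, 0x00BC, "IS", .vis(1)))),
    .item(c(.el(0x300A, 0x00B8, "CS", .vstr("ASYMY")),
            .el(0x300A, 0x00BC, "IS", .vis(1)))),
    .item(c(.el(0x300A, 0x00B8, "CS", .vstr("MLCX")),
            .el(0x300A, 0x00BC, "IS", .vis(np)),
            .el(0x300A, 0x00BE, "DS", .vds(leafBoundaries(mlc)))))))
}

.cp_item <- function(cp, idx) {
  pos <- .sq(0x300A, 0x011A, list(
    .item(c(.el(0x300A, 0x00B8, "CS", .vstr("ASYMX")),
            .el(0x300A, 0x011C, "DS", .vds(cp$jaws[c("X1", "X2")])))),
    .item(c(.el(0x300A, 0x00B8, "CS", .vstr("ASYMY")),
            .el(0x300A, 0x011C, "DS", .vds(cp$jaws[c("Y1", "Y2")])))),
    .item(c(.el(0x300A, 0x00B8, "CS", .vstr("MLCX")),
            .el(0x300A, 0x011C, "DS", .vds(c(cp$mlc_a, cp$mlc_b)))))))
  .item(c(
    .el(0x300A, 0x0112, "IS", .vis(idx)),
    pos,
    .el(0x300A, 0x011E, "DS", .vds(cp$gantry_deg)),
    .el(0x300A, 0x0120, "DS", .vds(cp$collimator_deg)),
    .el(0x300A, 0x0122, "DS", .vds(cp$couch_deg)),
    .el(0x300A, 0x0134, "DS", .vds(cp$meterset_weight))))
}

.beam_item <- function(bm, num, plan) {
  cps <- bm$control_points
  dynamic <- length(cps) > 2 ||
    !isTRUE(all.equal(cps[[1]]$mlc_a, cps[[length(cps)]]$mlc_a))
  .item(c(
    .el(0x300A, 0x00B2, "SH", .vstr(plan@machineName)),
    .bld_seq(plan@mlc),
    .el(0x300A, 0x00C0, "IS", .vis(num)),
    .el(0x300A, 0x00C2, "LO", .vstr(bm$name)),
    .el(0x300A, 0x00C3, "ST", .vstr(plan@energy)),
    .el(0x300A, 0x00C4, "CS", .vstr(if (dynamic) "DYNAMIC" else "STATIC")),
    .el(0x300A, 0x00C6, "CS", .vstr("PHOTON")),
    .el(0x300A, 0x00CE, "CS", .vstr("TREATMENT")),
    .el(0x300A, 0x0110, "IS", .vis(length(cps))),
    .sq(0x300A, 0x0111,
        lapply(seq_along(cps), function(i) .cp_item(cps[[i]], i - 1)))))
}

#' Write a QA plan as a DICOM RT-Plan
#'
#' Emits an explicit-VR little-endian RT-Plan: BeamSequence with
#' per-beam leaf/jaw boundary tables and full ControlPointSequence, and
#' a FractionGroupSequence carrying beam metersets.  Analyzer metadata
#' (\code{planMeta}) is serialized as JSON into RTPlanDescription so
#' plans round-trip losslessly.  Output is deterministic for a given
#' \code{seed} (UID generation).
#'
#' @param plan a valid \code{\linkS4class{QAPlan}}.
#' @param path output file path.
#' @param seed integer controlling UID generation.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readRTPlan}}
#' @export
writeRTPlan <- function(plan, path, seed = 1) {
  validObject(plan)
  sop <- .uid(seed, 3)
  desc <- jsonlite::toJSON(list(mlc_name = plan@mlc@name, meta = plan@meta),
                           auto_unbox = TRUE, digits = NA)
  frac_items <- lapply(seq_along(plan@beams), function(i)
    .item(c(.el(0x300A, 0x0086, "DS", .vds(plan@beams[[i]]$mu)),
            .el(0x300C, 0x0006, "IS", .vis(i)))))
  ds <- c(
    .el(0x0008, 0x0016, "UI", .vui(.uid_rtplan)),
    .el(0x0008, 0x0018, "UI", .vui(sop)),
    .el(0x0008, 0x0020, "DA", .vstr("20260101")),
    .el(0x0008, 0x0030, "TM", .vstr("000000")),
    .el(0x0008, 0x0060, "CS", .vstr("RTPLAN")),
    .el(0x0008, 0x0070, "LO", .vstr("epidqa")),
    .el(0x0010, 0x0010, "PN", .vstr("QA^EPIDQA")),
    .el(0x0010, 0x0020, "LO", .vstr("QA001")),
    .el(0x0020, 0x000D, "UI", .vui(.uid(seed, 1))),
    .el(0x0020, 0x000E, "UI", .vui(.uid(seed, 2))),
    .el(0x300A, 0x0002, "SH", .vstr(plan@testType)),
    .el(0x300A, 0x0003, "LO", .vstr(paste0("EPIDQA-", toupper(plan@testType)))),
    .el(0x300A, 0x0004, "ST", .vstr(desc)),
    .el(0x300A, 0x000C, "CS", .vstr("TREATMENT_DEVICE")),
    .sq(0x300A, 0x0070, list(.item(c(
      .el(0x300A, 0x0071, "IS", .vis(1)),
      .el(0x300A, 0x0078, "IS", .vis(1)),
      .el(0x300A, 0x0080, "IS", .vis(length(plan@beams))),
      .sq(0x300C, 0x0004, frac_items))))),
    .sq(0x300A, 0x00B0, lapply(seq_along(plan@beams), function(i)
      .beam_item(plan@beams[[i]], i, plan))))
  writeBin(c(.file_meta(.uid_rtplan, sop), ds), path)
  invisible(path)
}

## ---- parser ------------------------------------------------------------

.rd_u16 <- function(r, pos)
  readBin(r[pos:(pos + 1)], "integer", size = 2, endian = "little",
          signed = FALSE)
.rd_u32 <- function(r, pos)
  sum(as.integer(r[pos:(pos + 3)]) * c(1, 256, 65536, 16777216))

## parse a dataset from raw bytes; returns named list keyed "GGGGEEEE".
## SQ values are lists of child datasets; other values raw vectors.
.parse_ds <- function(r, pos, end) {
  out <- list()
  while (pos + 7 <= end + 1 && pos < end) {
    g <- .rd_u16(r, pos); e <- .rd_u16(r, pos + 2)
    if (g == 0xFFFE) {  # item/sequence delimiter bubbles up to caller
      break
    }
    vr <- rawToChar(r[(pos + 4):(pos + 5)])
    if (vr %in% .long_vrs) {
      len <- .rd_u32(r, pos + 8); vpos <- pos + 12
    } else {
      len <- .rd_u16(r, pos + 6); vpos <- pos + 8
    }
    key <- sprintf("%04X%04X", g, e)
    if (vr == "SQ") {
      if (len == 0xFFFFFFFF) {
        parsed <- .parse_sq_undef(r, vpos)
      } else {
        parsed <- .parse_sq(r, vpos, vpos + len - 1)
        parsed$pos <- vpos + len
      }
      out[[key]] <- list(vr = vr, value = parsed$items)
      pos <- parsed$pos
    } else {
      if (len == 0xFFFFFFFF)
        stop("undefined length outside a sequence is not supported")
      out[[key]] <- list(vr = vr,
        value = if (len > 0) r[vpos:(vpos + len - 1)] else raw(0))
      pos <- vpos + len
    }
  }
  list(elements = out, pos = pos)
}

.parse_sq <- function(r, pos, end) {
  items <- list()
  while (pos + 7 <= end + 1 && pos < end) {
    g <- .rd_u16(r, pos); e <- .rd_u16(r, pos + 2)
    len <- .rd_u32(r, pos + 4)
    if (g == 0xFFFE && e == 0xE0DD) { pos <- pos + 8; break }
    if (!(g == 0xFFFE && e == 0xE000)) stop("malformed sequence item")
    if (len == 0xFFFFFFFF) {
      sub <- .parse_ds(r, pos + 8, length(r))
      items <- c(items, list(sub$elements))
      pos <- sub$pos + 8  # skip item delimiter
    } else {
      sub <- .parse_ds(r, pos + 8, pos + 8 + len - 1)
      items <- c(items, list(sub$elements))
      pos <- pos + 8 + len
    }
  }
  list(items = items, pos = pos)
}

.parse_sq_undef <- function(r, pos) {
  items <- list()
  repeat {
    g <- .rd_u16(r, pos); e <- .rd_u16(r, pos + 2)
    len <- .rd_u32(r, pos + 4)
    if (g == 0xFFFE && e == 0xE0DD) { pos <- pos + 8; break }
    if (!(g == 0xFFFE && e == 0xE000)) stop("malformed sequence item")
    if (len == 0xFFFFFFFF) {
      sub <- .parse_ds(r, pos + 8, length(r))
      items <- c(items, list(sub$elements))
      pos <- sub$pos + 8
    } else {
      sub <- .parse_ds(r, pos + 8, pos + 8 + len - 1)
      items <- c(items, list(sub$elements))
      pos <- pos + 8 + len
    }
  }
  list(items = items, pos = pos)
}

.dcm_read_file <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n < 140) stop("unreadable or truncated file: ", path,
                                call. = FALSE)
  r <- readBin(path, raw(), n)
  if (rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  meta <- .parse_ds(r, 133, 133 + 8 + .rd_u32(r, 141) - 1)
  ts <- .str_of(meta$elements[["00020010"]])
  if (!identical(ts, .uid_ts_explicit_le))
    stop("unsupported transfer syntax: ", ts, call. = FALSE)
  .parse_ds(r, meta$pos, n)$elements
}

.str_of <- function(el) {
  if (is.null(el)) return(NULL)
  v <- el$value
  while (length(v) && v[length(v)] %in% as.raw(c(0x00, 0x20)))
    v <- v[-length(v)]
  rawToChar(v)
}
.num_of <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(.str_of(el), "\\\\")[[1]])
}
.us_of <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", n = length(el$value) / 2, size = 2,
          endian = "little", signed = FALSE)
}

## ---- reader: RT-Plan ---------------------------------------------------

#' Read a DICOM RT-Plan as a QA plan
#'
#' Reconstructs the beam and control-point structure written by
#' \code{\link{writeRTPlan}}; also accepts RT-Plans from other sources
#' using the explicit-VR little-endian transfer syntax with photon
#' beams.  Plans whose label is not a known QA test type are read as
#' \code{"open"} with a warning.
#'
#' @param path an RT-Plan file.
#' @return A \code{\linkS4class{QAPlan}}.
#' @export
readRTPlan <- function(path) {
  ds <- .dcm_read_file(path)
  bs <- ds[["300A00B0"]]
  if (is.null(bs)) stop("format error: RT-Plan has no BeamSequence",
                        call. = FALSE)
  ttype <- .str_of(ds[["300A0002"]])
  if (is.null(ttype) || !ttype %in% .qa_test_types) {
    warning("unknown test type '", ttype, "'; reading as 'open'")
    ttype <- "open"
  }
  meta <- list(); mlc_name <- "from-dicom"
  desc <- .str_of(ds[["300A0004"]])
  if (!is.null(desc) && nzchar(desc)) {
    parsed <- tryCatch(jsonlite::fromJSON(desc, simplifyVector = TRUE,
                                          simplifyDataFrame = TRUE,
                                          simplifyMatrix = FALSE),
                       error = function(e) NULL)
    if (!is.null(parsed)) {
      if (!is.null(parsed$mlc_name)) mlc_name <- parsed$mlc_name
      if (!is.null(parsed$meta)) meta <- parsed$meta
    }
  }
  mu <- numeric(0)
  fg <- ds[["300A0070"]]
  if (!is.null(fg) && length(fg$value)) {
    rb <- fg$value[[1]][["300C0004"]]
    if (!is.null(rb)) {
      for (it in rb$value) {
        bn <- .num_of(it[["300C0006"]])
        mu[bn] <- .num_of(it[["300A0086"]])
      }
    }
  }
  mlc <- NULL
  bms <- lapply(seq_along(bs$value), function(i) {
    bi <- bs$value[[i]]
    rt <- .str_of(bi[["300A00C6"]])
    dt <- .str_of(bi[["300A00CE"]])
    if (!is.null(rt) && rt != "PHOTON")
      stop("unsupported beam: radiation type ", rt, call. = FALSE)
    if (!is.null(dt) && dt != "TREATMENT")
      stop("unsupported beam: delivery type ", dt, call. = FALSE)
    for (bld in bi[["300A00B6"]]$value) {
      if (identical(.str_of(bld[["300A00B8"]]), "MLCX")) {
        bounds <- .num_of(bld[["300A00BE"]])
        if (is.null(mlc)) mlc <<- MLCModel(bounds, name = mlc_name)
      }
    }
    np <- nPairs(mlc)
    cps <- lapply(bi[["300A0111"]]$value, function(ci) {
      jx <- c(-200, 200); jy <- c(-200, 200)
      a <- rep(-200, np); b2 <- rep(200, np)
      for (p in ci[["300A011A"]]$value) {
        ty <- .str_of(p[["300A00B8"]])
        v <- .num_of(p[["300A011C"]])
        if (ty == "ASYMX") jx <- v
        else if (ty == "ASYMY") jy <- v
        else if (ty == "MLCX") { a <- v[1:np]; b2 <- v[(np + 1):(2 * np)] }
      }
      controlPoint(.num_of(ci[["300A0134"]]),
        c(X1 = jx[1], X2 = jx[2], Y1 = jy[1], Y2 = jy[2]), a, b2,
        gantry_deg = .num_of(ci[["300A011E"]]) %||% 0,
        collimator_deg = .num_of(ci[["300A0120"]]) %||% 0,
        couch_deg = .num_of(ci[["300A0122"]]) %||% 0)
    })
    list(name = .str_of(bi[["300A00C2"]]) %||% sprintf("BEAM%d", i),
         mu = if (length(mu) >= i && !is.na(mu[i])) mu[i] else 100,
         control_points = cps)
  })
  energy <- .str_of(bs$value[[1]][["300A00C3"]]) %||% "6X"
  machine <- .str_of(bs$value[[1]][["300A00B2"]]) %||% "LINAC1"
  QAPlan(ttype, beams = bms, mlc = mlc, machineName = machine,
         energy = energy, meta = .restore_meta(meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## jsonlite deserializes data frames / matrices faithfully but drops
## integer-ness; normalize the few meta fields analyzers index with.
.restore_meta <- function(meta) {
  if (!is.null(meta$picket$active_pairs))
    meta$picket$active_pairs <- as.integer(meta$picket$active_pairs)
  for (fld in c("rois", "bounds")) {
    if (!is.null(meta$bands[[fld]]) && is.list(meta$bands[[fld]]))
      meta$bands[[fld]] <- lapply(meta$bands[[fld]], function(r) {
        v <- unlist(r)
        names(v) <- c("x1", "x2", "y1", "y2"); v
      })
  }
  if (!is.null(meta$bands$count)) meta$bands$count <- as.integer(meta$bands$count)
  if (!is.null(meta$mlc_error$pairs))
    meta$mlc_error$pairs <- as.integer(meta$mlc_error$pairs)
  if (!is.null(meta$mlc_error$beam))
    meta$mlc_error$beam <- as.integer(meta$mlc_error$beam)
  for (j in names(meta$junctions))
    meta$junctions[[j]]$beams <- as.integer(meta$junctions[[j]]$beams)
  meta
}
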