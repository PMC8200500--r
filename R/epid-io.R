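## EPID image file surfaces: DICOM RT-Image (16-bit, rescale slope) and
## a plain-text sidecar pair for DICOM-free fixture authoring:
##   <stem>.json  geometry header (shape, spacing, SID/SAD, CAX, meta)
##   <stem>.txt   whitespace-separated float rows, row-major

#' Write an EPID image
#'
#' \code{format = "dicom"} emits an RT-Image: pixels are scaled to
#' 16 bits with a rescale slope, so values round-trip to about 1e-5 of
#' the image maximum.  \code{format = "sidecar"} writes the plain-text
#' header + grid pair (exact to 9 significant digits).
#'
#' @param image an \code{\linkS4class{EPIDImage}}.
#' @param path output path (for sidecar, the \code{.json} header path).
#' @param format \code{"dicom"} or \code{"sidecar"}.
#' @param seed UID seed for DICOM output.
#' @return \code{path}, invisibly.
#' @export
writeEPIDImage <- function(image, path, format = c("dicom", "sidecar"),
                           seed = 1) {
  format <- match.arg(format)
  validObject(image)
  if (format == "sidecar") return(.write_sidecar(image, path))
  px <- image@pixels
  mx <- max(px)
  slope <- if (mx > 0) mx / 65535 else 1
  stored <- matrix(as.integer(round(px / slope)), nrow(px))
  sop <- .uid(seed, 13)
  ## RTImagePosition: (x, y) of the first (top-left) pixel center, mm in
  ## the receptor plane, x along +columns, y along -rows.
  rip <- c(-(image@cax[2] - 1) * image@pixelSpacing[2],
           (image@cax[1] - 1) * image@pixelSpacing[1])
  meta_json <- jsonlite::toJSON(image@meta, auto_unbox = TRUE, digits = NA)
  gantry <- image@meta$gantry_deg %||% 0
  label <- substr(image@meta$test_type %||% "epid", 1, 16)
  ds <- c(
    .el(0x0008, 0x0016, "UI", .vui(.uid_rtimage)),
    .el(0x0008, 0x0018, "UI", .vui(sop)),
    .el(0x0008, 0x0060, "CS", .vstr("RTIMAGE")),
    .el(0x0008, 0x0070, "LO", .vstr("epidqa")),
    .el(0x0008, 0x1090, "LO", .vstr(image@meta$machine %||% "LINAC1")),
    .el(0x0020, 0x000D, "UI", .vui(.uid(seed, 11))),
    .el(0x0020, 0x000E, "UI", .vui(.uid(seed, 12))),
    .el(0x0028, 0x0002, "US", .vus(1)),
    .el(0x0028, 0x0004, "CS", .vstr("MONOCHROME2")),
    .el(0x0028, 0x0010, "US", .vus(nrow(px))),
    .el(0x0028, 0x0011, "US", .vus(ncol(px))),
    .el(0x0028, 0x0100, "US", .vus(16)),
    .el(0x0028, 0x0101, "US", .vus(16)),
    .el(0x0028, 0x0102, "US", .vus(15)),
    .el(0x0028, 0x0103, "US", .vus(0)),
    .el(0x0028, 0x1052, "DS", .vds(0)),
    .el(0x0028, 0x1053, "DS", .vds(slope)),
    .el(0x3002, 0x0002, "SH", .vstr(label)),
    .el(0x3002, 0x0004, "ST", .vstr(meta_json)),
    .el(0x3002, 0x000C, "CS", .vstr("NORMAL")),
    .el(0x3002, 0x0011, "DS", .vds(image@pixelSpacing)),
    .el(0x3002, 0x0012, "DS", .vds(rip)),
    .el(0x3002, 0x0022, "DS", .vds(image@sad)),
    .el(0x3002, 0x0026, "DS", .vds(image@sid)),
    .el(0x300A, 0x011E, "DS", .vds(gantry)),
    .el(0x7FE0, 0x0010, "OW",
        writeBin(as.vector(t(stored)), raw(), size = 2, endian = "little")))
  writeBin(c(.file_meta(.uid_rtimage, sop), ds), path)
  invisible(path)
}

.write_sidecar <- function(image, path) {
  if (!grepl("\\.json$", path))
    stop("sidecar header path must end in .json", call. = FALSE)
  grid_path <- sub("\\.json$", ".txt", path)
  hdr <- list(
    format = "epidqa-grid", version = "1.0",
    shape = dim(image@pixels),
    pixel_spacing_mm = image@pixelSpacing,
    sid_mm = image@sid, sad_mm = image@sad,
    cax_pixel = image@cax,
    grid_file = basename(grid_path),
    meta = image@meta)
  jsonlite::write_json(hdr, path, auto_unbox = TRUE, digits = NA)
  con <- file(grid_path, "w")
  on.exit(close(con))
  writeLines(apply(format(image@pixels, digits = 9, scientific = TRUE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an EPID image
#'
#' Accepts a DICOM RT-Image or the plain-text sidecar format written by
#' \code{\link{writeEPIDImage}} (dispatch on file content/extension).
#' Missing SID/SAD fall back to 1500/1000 mm and are flagged in
#' \code{imageMeta(image)$defaults_applied}; a missing pixel spacing is
#' a metadata error.
#'
#' @param path input file (DICOM file, or sidecar \code{.json} header).
#' @return An \code{\linkS4class{EPIDImage}}.
#' @export
readEPIDImage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path)) return(.read_sidecar(path))
  ds <- .dcm_read_file(path)
  rows <- .us_of(ds[["00280010"]])
  cols <- .us_of(ds[["00280011"]])
  pdata <- ds[["7FE00010"]]
  if (is.null(rows) || is.null(cols) || is.null(pdata))
    stop("format error: not an RT-Image (no pixel data)", call. = FALSE)
  spacing <- .num_of(ds[["30020011"]])
  if (is.null(spacing))
    stop("metadata error: RT-Image lacks ImagePlanePixelSpacing",
         call. = FALSE)
  slope <- .num_of(ds[["00281053"]]) %||% 1
  icept <- .num_of(ds[["00281052"]]) %||% 0
  stored <- readBin(pdata$value, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = FALSE)
  px <- matrix(stored * slope + icept, nrow = rows, ncol = cols, byrow = TRUE)
  defaults <- character(0)
  sid <- .num_of(ds[["30020026"]])
  if (is.null(sid)) { sid <- 1500; defaults <- c(defaults, "sid_mm") }
  sad <- .num_of(ds[["30020022"]])
  if (is.null(sad)) { sad <- 1000; defaults <- c(defaults, "sad_mm") }
  rip <- .num_of(ds[["30020012"]])
  cax <- if (is.null(rip)) (c(rows, cols) + 1) / 2 else
    c(rip[2] / spacing[1] + 1, -rip[1] / spacing[2] + 1)
  meta <- list()
  mj <- .str_of(ds[["30020004"]])
  if (!is.null(mj) && nzchar(mj))
    meta <- tryCatch(jsonlite::fromJSON(mj, simplifyVector = TRUE),
                     error = function(e) list())
  if (length(defaults)) meta$defaults_applied <- defaults
  EPIDImage(px, spacing, sid = sid, sad = sad, cax = cax, meta = meta)
}

.read_sidecar <- function(path) {
  hdr <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(hdr$format, "epidqa-grid"))
    stop("format error: not an epidqa sidecar header", call. = FALSE)
  if (is.null(hdr$pixel_spacing_mm))
    stop("metadata error: sidecar lacks pixel_spacing_mm", call. = FALSE)
  grid_path <- file.path(dirname(path), hdr$grid_file)
  px <- as.matrix(utils::read.table(grid_path))
  dimnames(px) <- NULL
  if (!all(dim(px) == hdr$shape))
    stop("format error: grid shape does not match header", call. = FALSE)
  defaults <- character(0)
  sid <- hdr$sid_mm; sad <- hdr$sad_mm
  if (is.null(sid)) { sid <- 1500; defaults <- c(defaults, "sid_mm") }
  if (is.null(sad)) { sad <- 1000; defaults <- c(defaults, "sad_mm") }
  meta <- if (is.null(hdr$meta)) list() else hdr$meta
  if (length(defaults)) meta$defaults_applied <- defaults
  EPIDImage(px, hdr$pixel_spacing_mm, sid = sid, sad = sad,
            cax = hdr$cax_pixel, meta = meta)
}
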