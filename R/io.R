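read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Write a projection stack to disk
#'
#' `"raw"` stores little-endian float32 (u fastest, then v, then view) plus
#' a JSON sidecar `<path>.json` with the layout.  `"tiff"` stores a
#' multi-page 32-bit TIFF; because TIFF pages here hold values in `[0, 1]`,
#' the data are affinely rescaled and the scale/offset recorded in the
#' sidecar (lossless after de-scaling at float32 precision).
#'
#' @param proj a [projection_set()].
#' @param path output file.
#' @param format `"raw"` or `"tiff"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_projections <- function(proj, path, format = NULL) {
  stopifnot(inherits(proj, "projection_set"))
  if (is.null(format))
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
  format <- match.arg(format, c("raw", "tiff"))
  d <- dim(proj$data)
  meta <- list(format = format, views = d[3], nv = d[2], nu = d[1],
               dtype = "float32", endian = "little", stage = proj$stage)
  if (format == "raw") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(proj$data), con, size = 4L, endian = "little")
  } else {
    lo <- min(proj$data); hi <- max(proj$data)
    scale <- if (hi > lo) hi - lo else 1
    meta$tiff_offset <- lo
    meta$tiff_scale <- scale
    pages <- lapply(seq_len(d[3]), function(k)
      t((proj$data[, , k] - lo) / scale))  # TIFF rows = v
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  }
  write_sidecar(path, meta)
  invisible(path)
}

#' Read a projection stack from disk
#'
#' Reads the formats written by [write_projections()] and binds the result
#' to a scan geometry.  The stored layout must match the geometry's
#' detector and view counts.
#'
#' @param path file written by [write_projections()] (sidecar required for
#'   raw files; optional `layout` overrides it).
#' @param geometry a [scan_geometry()].
#' @param layout optional list with `views`, `nv`, `nu` (and `tiff_scale`,
#'   `tiff_offset` for TIFF) replacing the sidecar.
#' @param stage stage tag of the returned set (default `"raw"`).
#' @return A [projection_set()].
#' @export
read_projections <- function(path, geometry, layout = NULL, stage = "raw") {
  stopifnot(file.exists(path), inherits(geometry, "scan_geometry"))
  meta <- if (is.null(layout)) read_sidecar(path) else layout
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (is.null(meta) && !is_tiff)
    stop("no layout sidecar found for ", path)
  if (is_tiff) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
    data <- array(0, d)
    for (k in seq_along(pages)) data[, , k] <- t(pages[[k]])
    if (!is.null(meta$tiff_scale))
      data <- data * meta$tiff_scale + meta$tiff_offset
  } else {
    d <- c(meta$nu, meta$nv, meta$views)
    n <- prod(d)
    con <- file(path, "rb")
    on.exit(close(con))
    data <- readBin(con, "numeric", n = n + 1L, size = 4L, endian = "little")
    if (length(data) != n)
      stop(sprintf("raw projection file holds %d values, layout needs %d",
                   length(data), n))
    dim(data) <- d
  }
  expect <- c(geometry$det_nu, geometry$det_nv, length(geometry$angles))
  if (!all(d == expect))
    stop(sprintf(paste0("projection file has %d views of %d x %d but the ",
                        "geometry declares %d views of %d x %d"),
                 d[3], d[1], d[2], expect[3], expect[1], expect[2]))
  if (!all(is.finite(data))) {
    bad <- which(apply(!is.finite(data), 3L, any))
    stop("non-finite values in view(s): ", paste(bad, collapse = ", "))
  }
  projection_set(data, geometry, stage = stage)
}

#' Write a volume to disk
#'
#' Formats: MetaImage (`.mha`, header + raw float32 in one file), NIfTI
#' (`.nii` / `.nii.gz` via RNifti), or raw float32 with a JSON sidecar.
#' Spacing and origin are stored in the format's own header where it has
#' one; the unit tag travels in a JSON sidecar.
#'
#' @param vol a [ct_volume()].
#' @param path output file; extension selects the format unless `format`
#'   is given.
#' @param format `"mha"`, `"nifti"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  if (is.null(format)) {
    format <- if (grepl("\\.mha$", path)) "mha"
    else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
    else "raw"
  }
  format <- match.arg(format, c("mha", "nifti", "raw"))
  d <- dim(vol$data)
  if (format == "mha") {
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False", "CompressedData = False",
             "TransformMatrix = 1 0 0 0 1 0 0 0 1",
             paste("Offset =", paste(vol$origin, collapse = " ")),
             paste("ElementSpacing =", paste(vol$spacing, collapse = " ")),
             paste("DimSize =", paste(d, collapse = " ")),
             "ElementType = MET_FLOAT", "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
    write_sidecar(path, list(unit = vol$unit))
  } else if (format == "nifti") {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
    write_sidecar(path, list(unit = vol$unit, origin = vol$origin))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
    write_sidecar(path, list(dims = d, spacing = vol$spacing,
                             origin = vol$origin, unit = vol$unit,
                             dtype = "float32", endian = "little"))
  }
  invisible(path)
}

#' Read a volume from disk
#'
#' Counterpart of [write_volume()]; the format is inferred from the
#' extension.  Truncated or malformed files raise an error without
#' returning a partial volume.
#'
#' @param path file written by [write_volume()].
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  stopifnot(file.exists(path))
  sc <- read_sidecar(path)
  unit <- if (!is.null(sc$unit)) sc$unit else "mu_mm^-1"
  if (grepl("\\.mha$", path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- list()
    repeat {
      line <- readLines(con, n = 1L)
      if (length(line) == 0L) stop("corrupted MetaImage header: no data tag")
      kv <- strsplit(line, "\\s*=\\s*")[[1]]
      if (length(kv) != 2L) stop("corrupted MetaImage header line: ", line)
      hdr[[kv[1]]] <- kv[2]
      if (kv[1] == "ElementDataFile") break
    }
    if (!identical(hdr$ElementType, "MET_FLOAT"))
      stop("unsupported MetaImage element type: ", hdr$ElementType)
    d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
    n <- prod(d)
    data <- readBin(con, "numeric", n = n + 1L, size = 4L, endian = "little")
    if (length(data) != n)
      stop(sprintf("truncated MetaImage: %d of %d values", length(data), n))
    dim(data) <- d
    ct_volume(data, as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]),
              as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]), unit = unit)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    origin <- if (!is.null(sc$origin)) sc$origin else NULL
    ct_volume(array(as.numeric(img), dim(img)), RNifti::pixdim(img),
              origin, unit = unit)
  } else {
    if (is.null(sc)) stop("no sidecar found for raw volume ", path)
    n <- prod(sc$dims)
    con <- file(path, "rb")
    on.exit(close(con))
    data <- readBin(con, "numeric", n = n + 1L, size = 4L, endian = "little")
    if (length(data) != n)
      stop(sprintf("truncated raw volume: %d of %d values", length(data), n))
    dim(data) <- sc$dims
    ct_volume(data, sc$spacing, sc$origin, unit = unit)
  }
}
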