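#' Read a label volume from a multi-page TIFF stack
#'
#' Reads an instance-label volume stored as a multi-page (grayscale) TIFF,
#' one z-slice per page, into a [LabelVolume-class]. Voxel size is resolved
#' in priority order: the explicit \code{voxelSizeNm} argument (a warning is
#' emitted if it disagrees with file metadata), the JSON sidecar written by
#' [writeLabelVolume()], OME-XML \code{PhysicalSize} attributes found in the
#' TIFF description, and otherwise an error.
#'
#' @param path path to a .tif/.tiff file. HDF5 containers are not supported
#'   by this build and are rejected with an informative error.
#' @param voxelSizeNm optional voxel size override in nm (1 or 3 values).
#' @param name volume name; defaults to the file name.
#' @return A [LabelVolume-class].
#' @seealso [writeLabelVolume()]
#' @export
readLabelVolume <- function(path, voxelSizeNm = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE))
    stop("HDF5 containers are not supported; supply a multi-page TIFF")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lab <- .pagesToLabels(pages)

  meta_vs <- .sidecarVoxelSize(path)
  if (is.null(meta_vs)) meta_vs <- .omeVoxelSize(attr(pages[[1]], "description"))
  if (!is.null(voxelSizeNm)) {
    vs <- if (length(voxelSizeNm) == 1L) rep(voxelSizeNm, 3L) else voxelSizeNm
    if (!is.null(meta_vs) && any(abs(vs - meta_vs) > 1e-9))
      warning("voxel size argument (", paste(vs, collapse = "x"),
              " nm) overrides file metadata (", paste(meta_vs, collapse = "x"),
              " nm)")
  } else if (!is.null(meta_vs)) {
    vs <- meta_vs
  } else {
    stop("no voxel size available for ", path,
         ": none in metadata and none supplied")
  }
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  LabelVolume(lab, voxelSize = vs, name = name)
}

#' Write a label volume to a multi-page TIFF stack with a JSON sidecar
#'
#' Labels are stored losslessly (16-bit pages when the maximum id fits,
#' 32-bit otherwise; ids above 2^24 are rejected as beyond the exact range
#' of the container path). A sidecar \code{<path>.json} records voxel size,
#' name, label count, software version and an optional seed, so a
#' round-trip read restores both grid and metadata.
#'
#' @param vol a [LabelVolume-class].
#' @param path output .tif path; the parent directory must exist.
#' @param seed optional integer recorded in the sidecar for provenance.
#' @return Invisibly, the sidecar path.
#' @export
writeLabelVolume <- function(vol, path, seed = NULL) {
  stopifnot(is(vol, "LabelVolume"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  d <- vol@data
  mxlab <- max(0L, d)
  if (mxlab > 2^24 - 1) stop("label ids above 2^24 cannot be stored exactly")
  bits <- if (mxlab <= 65535) 16L else 32L
  mx <- 2^bits - 1
  pages <- lapply(seq_len(dim(d)[1]), function(z) d[z, , ] / mx)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                            compression = "LZW"), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write ", path)
  side <- list(voxel_size_nm = vol@voxelSize, name = vol@name,
               max_label = mxlab, axis_order = "zyx",
               software = paste0("orgContact ",
                                 as.character(utils::packageVersion("orgContact"))))
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(path, ".json"))
}


# Stack TIFF pages to a (z, y, x) integer label array. Unsigned-integer
# samples come back from readTIFF scaled to [0, 1] and are rescaled by
# 2^bits - 1; floating-point samples are taken verbatim. Fractional label
# values are a contract violation.
.pagesToLabels <- function(pages) {
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
  fmt <- attr(pages[[1]], "sample.format") %||% "uint"
  arr <- vapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate greyscale+alpha
    p
  }, matrix(0, nrow(pages[[1]]), ncol(pages[[1]])))
  # vapply gives (y, x, z); reorder to (z, y, x)
  arr <- aperm(arr, c(3L, 1L, 2L))
  lab <- if (grepl("float", fmt, ignore.case = TRUE)) arr
         else arr * (2^bits - 1)
  if (max(abs(lab - round(lab))) > 1e-3) stop("non-integer labels")
  round(lab)
}

.sidecarVoxelSize <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) return(NULL)
  meta <- try(jsonlite::read_json(sc, simplifyVector = TRUE), silent = TRUE)
  if (inherits(meta, "try-error") || is.null(meta$voxel_size_nm)) return(NULL)
  vs <- as.numeric(meta$voxel_size_nm)
  if (length(vs) == 1L) vs <- rep(vs, 3L)
  vs
}

# Parse PhysicalSizeX/Y/Z (assumed micrometre unless a *Unit attribute says
# nm) from an OME-XML TIFF description.
.omeVoxelSize <- function(desc) {
  if (is.null(desc) || !nzchar(desc) || !grepl("PhysicalSize", desc)) return(NULL)
  getv <- function(axis) {
    m <- regmatches(desc, regexpr(paste0('PhysicalSize', axis, '="[0-9.eE+-]+"'), desc))
    if (!length(m)) return(NA_real_)
    v <- as.numeric(sub('.*="([0-9.eE+-]+)"', "\\1", m))
    u <- regmatches(desc,
      regexpr(paste0('PhysicalSize', axis, 'Unit="[^"]*"'), desc))
    unit <- if (length(u)) sub('.*="([^"]*)"', "\\1", u) else "µm"
    if (unit %in% c("nm", "nanometer", "nanometre")) v else v * 1000
  }
  vs <- c(getv("Z"), getv("Y"), getv("X"))
  if (anyNA(vs)) return(NULL)
  vs
}

#' Write a result table to CSV or JSON
#'
#' Column order and row order are preserved; a CSV round trip through
#' [readTable()] restores values.
#'
#' @param table a data.frame.
#' @param path output path.
#' @param format "csv" or "json".
#' @return Invisibly, \code{path}.
#' @export
writeTable <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(table))
  if (format == "csv") {
    utils::write.csv(table, path, row.names = FALSE)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read a table written by [writeTable()]
#'
#' @param path input path.
#' @param format "csv" or "json"; guessed from the extension by default.
#' @return A data.frame.
#' @export
readTable <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") utils::read.csv(path)
  else as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
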