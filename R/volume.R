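#' CT volume container
#'
#' A light container for a CT volume: a 3D array of attenuation values in
#' Hounsfield units (HU), the voxel spacing in mm, a physical origin and an
#' optional binary lung mask of identical shape. Axis order is
#' (x = left-right, y = anterior-posterior, z = inferior-superior); array
#' indices are R's native 1-based indices (annotation *files* use 0-based
#' indices, see [read_annotations()]).
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing numeric length-3, voxel spacing in mm (strictly positive).
#' @param origin numeric length-3 physical offset in mm.
#' @param lung_mask optional logical/0-1 array, same shape as `voxels`;
#'   nonzero marks lung.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      lung_mask = NULL) {
  if (length(dim(voxels)) != 3L)
    stop_lungtex("voxels must be a 3D array", "lungtex_format_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_lungtex("spacing must be 3 strictly positive values (mm)",
                 "lungtex_metadata_error")
  if (!is.null(lung_mask)) {
    if (!identical(dim(lung_mask), dim(voxels)))
      stop_lungtex("lung_mask shape must match voxels",
                   "lungtex_format_error")
    storage.mode(lung_mask) <- "integer"
    lung_mask <- (lung_mask != 0L) * 1L
    dim(lung_mask) <- dim(voxels)
  }
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), lung_mask = lung_mask),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.0f, %.0f]%s\n", min(x$voxels), max(x$voxels),
              if (is.null(x$lung_mask)) "" else
                sprintf(", lung mask: %d voxels", sum(x$lung_mask))))
  invisible(x)
}

infer_volume_format <- function(path) {
  if (dir.exists(path)) return("dicom_dir")
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.nrrd$", low)) return("nrrd")
  stop_lungtex(sprintf("cannot infer volume format from '%s'", path),
               "lungtex_format_error")
}

#' Read and write CT volumes
#'
#' Volumes are read into HU with spacing taken from the file header. NIfTI
#' files are handled by the RNifti package; NRRD by a minimal built-in
#' reader (raw and gzip encodings, detached headers not supported). DICOM
#' series directories are not supported by this build and raise a format
#' error.
#'
#' @param path file path (or directory for a DICOM series).
#' @param format one of `"nifti"`, `"nrrd"`, `"dicom_dir"`; inferred from
#'   the file extension when omitted.
#' @param lung_mask optional path to a mask volume in the same raster format.
#' @return [read_volume()] returns a [ct_volume]; [write_volume()] returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, format = NULL, lung_mask = NULL) {
  format <- format %||% infer_volume_format(path)
  format <- match.arg(format, c("nifti", "nrrd", "dicom_dir"))
  if (format == "dicom_dir")
    stop_lungtex(paste0(
      "DICOM series input is not supported by this build; convert the series",
      " to NIfTI or NRRD first"), "lungtex_format_error")
  if (!file.exists(path))
    stop_lungtex(sprintf("file not found: %s", path), "lungtex_format_error")
  vol <- switch(format,
    nifti = read_nifti_volume(path),
    nrrd  = read_nrrd_volume(path))
  if (!is.null(lung_mask)) {
    m <- read_volume(lung_mask)
    vol$lung_mask <- (m$voxels != 0) * 1L
    dim(vol$lung_mask) <- dim(vol$voxels)
    if (!identical(dim(m$voxels), dim(vol$voxels)))
      stop_lungtex("lung mask shape does not match volume",
                   "lungtex_format_error")
  }
  vol
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  if (is.null(pd) || length(pd) < 3 || any(!is.finite(pd[1:3])) ||
      any(pd[1:3] <= 0))
    stop_lungtex("NIfTI header has no usable voxel spacing",
                 "lungtex_metadata_error")
  vox <- array(as.numeric(img), dim = dim(img))
  ct_volume(vox, spacing = pd[1:3])
}

#' @rdname read_volume
#' @param vol a [ct_volume].
#' @export
write_volume <- function(vol, path, format = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  format <- format %||% infer_volume_format(path)
  format <- match.arg(format, c("nifti", "nrrd"))
  if (format == "nifti") {
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else {
    write_nrrd_volume(vol, path)
  }
  invisible(path)
}

# --- minimal NRRD support (text header + raw/gzip block) ---------------------

write_nrrd_volume <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(vol$voxels)
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.9g %.9g %.9g",
                   vol$spacing[1], vol$spacing[2], vol$spacing[3]),
           "endian: little",
           "encoding: raw",
           "")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.numeric(vol$voxels), con, size = 8, endian = "little")
  invisible(path)
}

read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L)
      stop_lungtex("truncated NRRD header", "lungtex_format_error")
    if (ln == "") break
    lines <- c(lines, ln)
  }
  if (!grepl("^NRRD", lines[1]))
    stop_lungtex("not an NRRD file", "lungtex_format_error")
  fields <- lines[grepl(":", lines, fixed = TRUE)]
  kv <- do.call(rbind, lapply(strsplit(fields, ":\\s*"), function(p)
    c(tolower(trimws(p[1])), trimws(paste(p[-1], collapse = ":")))))
  get <- function(k) {
    i <- match(k, kv[, 1])
    if (is.na(i)) NULL else kv[i, 2]
  }
  sizes <- as.integer(strsplit(get("sizes") %||%
    stop_lungtex("NRRD header missing sizes", "lungtex_metadata_error"),
    "\\s+")[[1]])
  sp <- get("spacings")
  if (is.null(sp)) {
    sd <- get("space directions")
    if (!is.null(sd)) {
      vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1]]
      sp3 <- vapply(vecs, function(v) {
        comp <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
        sqrt(sum(comp^2))
      }, numeric(1))
      sp <- paste(sp3, collapse = " ")
    }
  }
  if (is.null(sp))
    stop_lungtex("NRRD header has no voxel spacing information",
                 "lungtex_metadata_error")
  spacing <- as.numeric(strsplit(sp, "\\s+")[[1]])
  type <- get("type") %||% "double"
  encoding <- tolower(get("encoding") %||% "raw")
  endian <- tolower(get("endian") %||% "little")
  n <- prod(sizes)
  rsize <- switch(type,
    "double" = 8L, "float" = 4L,
    "short" = 2L, "int16" = 2L, "signed short" = 2L,
    "int" = 4L, "int32" = 4L,
    "uchar" = 1L, "uint8" = 1L, "unsigned char" = 1L,
    stop_lungtex(sprintf("unsupported NRRD type '%s'", type),
                 "lungtex_format_error"))
  what <- if (rsize >= 4L && type %in% c("double", "float")) "double" else "integer"
  rcon <- con
  if (encoding == "gzip") {
    blob <- readBin(con, "raw", n = file.info(path)$size)
    rcon <- gzcon(rawConnection(blob))
    on.exit(close(rcon), add = TRUE)
  } else if (encoding != "raw") {
    stop_lungtex(sprintf("unsupported NRRD encoding '%s'", encoding),
                 "lungtex_format_error")
  }
  vox <- readBin(rcon, what, n = n, size = rsize, endian = endian,
                 signed = !(rsize == 1L))
  if (length(vox) != n)
    stop_lungtex("NRRD data block shorter than header sizes promise",
                 "lungtex_format_error")
  dim(vox) <- sizes
  ct_volume(array(as.numeric(vox), dim = sizes), spacing = spacing)
}

# --- point annotations -------------------------------------------------------

#' Read and write point annotations
#'
#' Annotation files are CSV or TSV with header
#' `scan_id,subject_id,i,j,k,label,kernel`. On disk, `i,j,k` are 0-based voxel
#' indices (axis order x,y,z); in R they are converted to 1-based indices.
#' Labels are validated against the 8-class enumeration (see
#' [tissue_classes()]) and kernels against `B35`/`B50`; an unknown label
#' raises a validation error naming the offending rows.
#'
#' @param path delimited text file; the separator (comma or tab) is detected
#'   from the header line.
#' @return A `data.frame` with columns `scan_id`, `subject_id`, `i`, `j`,
#'   `k` (1-based integers), `label` (factor over the 8 codes), `kernel`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    stop_lungtex(sprintf("file not found: %s", path), "lungtex_format_error")
  hdr <- readLines(path, n = 1L, warn = FALSE)
  if (length(hdr) == 0L || !nzchar(hdr)) {
    warning("empty annotation file: ", path)
    return(empty_annotations())
  }
  sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  req <- c("scan_id", "subject_id", "i", "j", "k", "label", "kernel")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop_lungtex(sprintf("annotation file missing column(s): %s",
                         paste(miss, collapse = ", ")),
                 "lungtex_validation_error")
  if (nrow(df) == 0L) {
    warning("annotation file has a header but no rows: ", path)
    return(empty_annotations())
  }
  df$label <- as_tissue_factor(df$label)
  badk <- which(!(df$kernel %in% c("B35", "B50")))
  if (length(badk) > 0)
    stop_lungtex(sprintf("unknown kernel tag(s) %s at row(s) %s (expected B35/B50)",
                         paste(unique(df$kernel[badk]), collapse = ", "),
                         paste(head(badk, 10L), collapse = ", ")),
                 "lungtex_validation_error")
  for (col in c("i", "j", "k")) df[[col]] <- as.integer(df[[col]]) + 1L
  df[req]
}

empty_annotations <- function() {
  data.frame(scan_id = character(), subject_id = character(),
             i = integer(), j = integer(), k = integer(),
             label = factor(character(), levels = tissue_classes()),
             kernel = character(), stringsAsFactors = FALSE)
}

#' @rdname read_annotations
#' @param points annotation `data.frame` (1-based indices, as returned by
#'   [read_annotations()]).
#' @param sep field separator for writing.
#' @export
write_annotations <- function(points, path, sep = ",") {
  out <- points
  for (col in c("i", "j", "k")) out[[col]] <- as.integer(out[[col]]) - 1L
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check annotation coordinates against a volume
#'
#' Reports (rather than silently drops) annotated points whose patch
#' neighbourhood exceeds the volume bounds.
#'
#' @param points annotation data.frame.
#' @param vol a [ct_volume] (or an integer dim vector).
#' @param margin required clearance in voxels per axis (e.g. half the ROI
#'   size); 0 checks only that the point is inside the volume.
#' @return Logical vector, `TRUE` where the point violates the bound; rows
#'   are also reported via a warning.
#' @export
check_annotation_bounds <- function(points, vol, margin = 0L) {
  d <- if (inherits(vol, "ct_volume")) dim(vol$voxels) else as.integer(vol)
  bad <- points$i <= margin | points$i > d[1] - margin |
         points$j <= margin | points$j > d[2] - margin |
         points$k <= margin | points$k > d[3] - margin
  if (any(bad))
    warning(sprintf("%d annotated point(s) out of bounds (rows %s)",
                    sum(bad), paste(head(which(bad), 10L), collapse = ", ")))
  bad
}
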