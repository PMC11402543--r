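# Volumetric mask I/O. NIfTI-1 goes through RNifti; NRRD is read and written
# directly (raw and gzip encodings) since no installed R package handles it.
# Only axis-aligned volumes with positive spacing are accepted: the analysis
# is intra-patient on co-registered grids and direction cosines beyond that
# are deliberately out of scope.

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  stop(sprintf("cannot infer volume format from '%s' (use .nii/.nii.gz/.nrrd)",
               basename(path)), call. = FALSE)
}

#' Read a binary mask from a volumetric file
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and NRRD (`.nrrd`, raw or gzip
#' encoded). Any non-zero voxel becomes foreground; spacing and origin are
#' taken from the file header. Files with non-axis-aligned orientation (or
#' flipped axes) are rejected.
#'
#' @param path Path to an existing file.
#' @param format `"auto"` (from the extension), `"nifti"` or `"nrrd"`.
#' @return A [binary_mask()]; array axis order is (slice, row, col).
#' @seealso [write_mask()]
#' @export
read_mask <- function(path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  switch(format, nifti = read_mask_nifti(path), nrrd = read_mask_nrrd(path))
}

#' Write a binary mask to a volumetric file
#'
#' Foreground is stored as 1, background as 0, in an 8-bit integer payload.
#' `read_mask(write_mask(m, path))` reproduces `m` exactly (geometry to
#' within 1e-6 mm).
#'
#' @param mask A [binary_mask()].
#' @param path Output path; parent directory must exist.
#' @param format `"auto"`, `"nifti"` or `"nrrd"`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)), call. = FALSE)
  switch(format,
         nifti = write_mask_nifti(mask, path),
         nrrd = write_mask_nrrd(mask, path))
  invisible(path)
}

# ---- NIfTI ------------------------------------------------------------------

read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s': expected a 3D volume, got %dD", basename(path),
                 length(dim(img))), call. = FALSE)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (max(abs(rot[row(rot) != col(rot)])) > 1e-4)
    stop(sprintf("'%s': non-axis-aligned orientation is not supported",
                 basename(path)), call. = FALSE)
  sp_xyz <- diag(rot)
  if (any(sp_xyz <= 0))
    stop(sprintf("'%s': flipped or degenerate axis spacing in header",
                 basename(path)), call. = FALSE)
  or_xyz <- xf[1:3, 4]
  grid <- voxel_grid(rev(dim(img)), rev(sp_xyz), rev(or_xyz))
  binary_mask(aperm(as.array(img) != 0, c(3, 2, 1)), grid)
}

write_mask_nifti <- function(mask, path) {
  arr <- aperm(array(as.integer(mask$values), dim = mask$grid$shape), c(3, 2, 1))
  sp <- rev(mask$grid$spacing_mm)   # (x, y, z)
  or <- rev(mask$grid$origin_mm)
  attr(arr, "pixdim") <- sp
  img <- RNifti::asNifti(arr, datatype = "uint8", internal = FALSE)
  xf <- diag(c(sp, 1))
  xf[1:3, 4] <- or
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path, datatype = "uint8")
}

# ---- NRRD -------------------------------------------------------------------

nrrd_types <- list(
  "uint8" = list(what = "integer", size = 1L, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1L, signed = FALSE),
  "uchar" = list(what = "integer", size = 1L, signed = FALSE),
  "int8" = list(what = "integer", size = 1L, signed = TRUE),
  "signed char" = list(what = "integer", size = 1L, signed = TRUE),
  "short" = list(what = "integer", size = 2L, signed = TRUE),
  "int16" = list(what = "integer", size = 2L, signed = TRUE),
  "ushort" = list(what = "integer", size = 2L, signed = FALSE),
  "uint16" = list(what = "integer", size = 2L, signed = FALSE),
  "unsigned short" = list(what = "integer", size = 2L, signed = FALSE),
  "int" = list(what = "integer", size = 4L, signed = TRUE),
  "int32" = list(what = "integer", size = 4L, signed = TRUE),
  "float" = list(what = "double", size = 4L, signed = TRUE),
  "double" = list(what = "double", size = 8L, signed = TRUE))

parse_nrrd_vectors <- function(value) {
  # "(a,b,c) (d,e,f) ..." -> list of numeric vectors; "none" entries dropped
  toks <- regmatches(value, gregexpr("\\(([^)]*)\\)", value))[[1L]]
  lapply(toks, function(t)
    as.numeric(strsplit(gsub("[()]", "", t), ",")[[1L]]))
}

read_mask_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw_all == as.raw(10L))
  # header ends at the first blank line
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    line_len <- p - prev - 1L
    if (line_len == 0L || (line_len == 1L && raw_all[prev + 1L] == as.raw(13L))) {
      hdr_end <- p; break
    }
    prev <- p
  }
  if (is.na(hdr_end)) stop(sprintf("'%s': missing NRRD header terminator",
                                   basename(path)), call. = FALSE)
  hdr_lines <- strsplit(rawToChar(raw_all[seq_len(hdr_end - 1L)]), "\r?\n")[[1L]]
  if (!grepl("^NRRD000", hdr_lines[1L]))
    stop(sprintf("'%s': not an NRRD file", basename(path)), call. = FALSE)
  fields <- list()
  for (ln in hdr_lines[-1L]) {
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    kv <- regmatches(ln, regexec("^([^:]+):=?\\s*(.*)$", ln))[[1L]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2L]))]] <- trimws(kv[3L])
  }
  need <- function(key) {
    if (is.null(fields[[key]]))
      stop(sprintf("'%s': NRRD header missing field '%s'", basename(path), key),
           call. = FALSE)
    fields[[key]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop(sprintf("'%s': expected a 3D volume", basename(path)), call. = FALSE)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1L]])
  ty <- nrrd_types[[tolower(need("type"))]]
  if (is.null(ty))
    stop(sprintf("'%s': unsupported NRRD type '%s'", basename(path),
                 fields$type), call. = FALSE)
  # spacing: either "space directions" (must be diagonal) or "spacings"
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    if (length(dirs) != 3L || any(lengths(dirs) != 3L))
      stop(sprintf("'%s': malformed 'space directions'", basename(path)),
           call. = FALSE)
    dirm <- do.call(cbind, dirs)
    if (max(abs(dirm[row(dirm) != col(dirm)])) > 1e-6 || any(diag(dirm) <= 0))
      stop(sprintf("'%s': non-axis-aligned 'space directions' not supported",
                   basename(path)), call. = FALSE)
    sp_xyz <- diag(dirm)
  } else if (!is.null(fields[["spacings"]])) {
    sp_xyz <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1L]])
  } else {
    stop(sprintf("'%s': NRRD header missing field 'space directions'",
                 basename(path)), call. = FALSE)
  }
  or_xyz <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    or_xyz <- parse_nrrd_vectors(fields[["space origin"]])[[1L]]
  enc <- tolower(if (is.null(fields$encoding)) "raw" else fields$encoding)
  payload <- raw_all[(hdr_end + 1L):length(raw_all)]
  if (enc %in% c("gzip", "gz")) payload <- memDecompress(payload, type = "gzip")
  else if (enc != "raw")
    stop(sprintf("'%s': unsupported NRRD encoding '%s'", basename(path), enc),
         call. = FALSE)
  n <- prod(sizes)
  endian <- if (!is.null(fields$endian) && tolower(fields$endian) == "big")
    "big" else "little"
  vals <- readBin(payload, ty$what, n = n, size = ty$size, signed = ty$signed,
                  endian = endian)
  if (length(vals) < n)
    stop(sprintf("'%s': truncated NRRD payload", basename(path)), call. = FALSE)
  arr <- array(vals, dim = sizes)                     # x fastest
  grid <- voxel_grid(rev(sizes), rev(sp_xyz), rev(or_xyz))
  binary_mask(aperm(arr != 0, c(3, 2, 1)), grid)
}

write_mask_nrrd <- function(mask, path) {
  sp <- rev(mask$grid$spacing_mm)
  or <- rev(mask$grid$origin_mm)
  sizes <- rev(mask$grid$shape)
  fmt <- function(v) paste(formatC(v, format = "fg", digits = 17), collapse = ",")
  hdr <- c(
    "NRRD0004",
    "type: uint8",
    "dimension: 3",
    "space dimension: 3",
    sprintf("sizes: %s", paste(sizes, collapse = " ")),
    sprintf("space directions: (%s,0,0) (0,%s,0) (0,0,%s)",
            formatC(sp[1], format = "fg", digits = 17),
            formatC(sp[2], format = "fg", digits = 17),
            formatC(sp[3], format = "fg", digits = 17)),
    sprintf("space origin: (%s)", fmt(or)),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  arr <- aperm(array(as.integer(mask$values), dim = mask$grid$shape), c(3, 2, 1))
  writeBin(as.raw(arr), con)
  invisible(path)
}
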