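# Volume IO. MetaImage (.mha/.mhd) is written/read directly (plain key=value
# header + raw little-endian data); NIfTI goes through RNifti. Only
# axis-aligned geometries are supported: direction matrices other than the
# identity are rejected.

met_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer", MET_SHORT = "integer",
               MET_USHORT = "integer", MET_INT = "integer", MET_UINT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
met_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
               MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

fmt_num <- function(x) paste(formatC(x, format = "g", digits = 17), collapse = " ")

write_meta_header <- function(con, size, origin, spacing, type, nchannels, datafile) {
  writeLines(c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", fmt_num(origin)),
    paste("CenterOfRotation =", fmt_num(c(0, 0, 0))),
    paste("ElementSpacing =", fmt_num(spacing)),
    paste("DimSize =", paste(size, collapse = " ")),
    if (nchannels > 1L) paste("ElementNumberOfChannels =", nchannels),
    paste("ElementType =", type),
    paste("ElementDataFile =", datafile)
  ), con)
}

write_meta_raw <- function(path, values, size, origin, spacing,
                           type = "MET_DOUBLE", nchannels = 1L) {
  ext <- tolower(tools::file_ext(path))
  esize <- met_sizes[[type]]
  what <- met_types[[type]]
  if (ext == "mha") {
    con <- file(path, "wb")
    on.exit(close(con))
    hcon <- textConnection("hdr", "w", local = TRUE)
    write_meta_header(hcon, size, origin, spacing, type, nchannels, "LOCAL")
    close(hcon)
    writChar <- paste0(paste(hdr, collapse = "\n"), "\n")
    writeBin(charToRaw(writChar), con)
  } else if (ext == "mhd") {
    rawname <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
    con0 <- file(path, "w")
    write_meta_header(con0, size, origin, spacing, type, nchannels, rawname)
    close(con0)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
  } else stop("unsupported MetaImage extension: .", ext)
  if (what == "integer") {
    writeBin(as.integer(round(values)), con, size = esize, endian = "little")
  } else {
    writeBin(as.double(values), con, size = esize, endian = "little")
  }
  invisible(path)
}

parse_meta_header <- function(lines) {
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", lines))
  h <- list()
  for (m in kv) if (length(m) == 3) h[[m[2]]] <- trimws(m[3])
  h
}

read_meta_raw <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mha") {
    raw <- readBin(path, "raw", n = file.info(path)$size)
    # header ends at the newline after the ElementDataFile line; locate it
    # at the byte level (the data section is binary)
    pat <- charToRaw("ElementDataFile")
    limit <- min(length(raw), 8192L)
    hits <- which(raw[seq_len(limit)] == pat[1])
    start <- NA_integer_
    for (s in hits) {
      if (s + length(pat) - 1L <= limit &&
          identical(raw[s:(s + length(pat) - 1L)], pat)) { start <- s; break }
    }
    if (is.na(start)) stop("malformed MetaImage header (no ElementDataFile): ", path)
    nls <- which(raw == as.raw(10L))
    offset <- nls[nls > start][1]
    if (is.na(offset)) stop("malformed MetaImage header: ", path)
    hdr_lines <- strsplit(rawToChar(raw[seq_len(offset - 1L)]), "\n",
                          fixed = TRUE)[[1]]
    h <- parse_meta_header(hdr_lines)
    data_raw <- raw[(offset + 1L):length(raw)]
  } else if (ext == "mhd") {
    hdr_lines <- readLines(path, warn = FALSE)
    h <- parse_meta_header(hdr_lines)
    rawpath <- file.path(dirname(path), h$ElementDataFile)
    if (!file.exists(rawpath)) stop("MetaImage data file not found: ", rawpath)
    data_raw <- readBin(rawpath, "raw", n = file.info(rawpath)$size)
  } else stop("unsupported MetaImage extension: .", ext)
  if (!is.null(h$CompressedData) && toupper(h$CompressedData) == "TRUE")
    stop("compressed MetaImage not supported: ", path)
  if (!is.null(h$TransformMatrix)) {
    tm <- as.numeric(strsplit(h$TransformMatrix, "\\s+")[[1]])
    if (max(abs(tm - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-9)
      stop("only identity direction matrices are supported")
  }
  size <- as.integer(strsplit(h$DimSize, "\\s+")[[1]])
  origin <- as.numeric(strsplit(h$Offset, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(h$ElementSpacing, "\\s+")[[1]])
  type <- h$ElementType
  if (!type %in% names(met_types)) stop("unsupported ElementType: ", type)
  nch <- if (!is.null(h$ElementNumberOfChannels))
    as.integer(h$ElementNumberOfChannels) else 1L
  n <- prod(size) * nch
  esize <- met_sizes[[type]]
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  vals <- readBin(data_raw, met_types[[type]], n = n, size = esize,
                  endian = "little", signed = if (esize <= 2) signed else TRUE)
  list(values = as.double(vals), size = size, origin = origin,
       spacing = spacing, nchannels = nch)
}

#' Write an image volume
#'
#' Format chosen from the extension: `.mha`/`.mhd` (MetaImage, raw
#' little-endian doubles) or `.nii`/`.nii.gz` (NIfTI via RNifti). Origin and
#' spacing round-trip exactly for MetaImage (printed at full precision).
#'
#' @param grid a [scalar_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("mha", "mhd")) {
    write_meta_raw(path, grid$values, grid$size, grid$origin, grid$spacing)
  } else if (ext == "nii") {
    img <- RNifti::asNifti(grid$values)
    RNifti::pixdim(img) <- grid$spacing
    aff <- diag(c(grid$spacing, 1))
    aff[1:3, 4] <- grid$origin
    img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path)
  } else stop("unsupported volume extension: .", ext)
  invisible(path)
}

#' Read an image volume
#'
#' @param path `.mha`, `.mhd`, `.nii` or `.nii.gz` file.
#' @param unit_tag unit tag to stamp on the result.
#' @return A [scalar_grid()].
#' @export
read_volume <- function(path, unit_tag = "unitless") {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("mha", "mhd")) {
    m <- read_meta_raw(path)
    if (m$nchannels != 1L) stop("expected scalar volume, got ", m$nchannels, " channels")
    scalar_grid(m$values, m$origin, m$spacing, size = m$size, unit_tag = unit_tag)
  } else if (ext == "nii") {
    img <- RNifti::readNifti(path)
    aff <- RNifti::xform(img)
    if (max(abs(aff[1:3, 1:3] - diag(RNifti::pixdim(img)[1:3]))) > 1e-4)
      stop("only axis-aligned NIfTI volumes with positive spacing are supported")
    scalar_grid(array(as.double(img), dim = dim(img)), origin = aff[1:3, 4],
                spacing = RNifti::pixdim(img)[1:3], unit_tag = unit_tag)
  } else stop("unsupported volume extension: .", ext)
}

#' Write a displacement field as a 3-channel MetaImage
#'
#' @param field a [vector_field()].
#' @param path `.mha` or `.mhd` output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  n <- prod(field$size)
  inter <- numeric(3 * n)
  inter[seq(1, by = 3, length.out = n)] <- field$dx
  inter[seq(2, by = 3, length.out = n)] <- field$dy
  inter[seq(3, by = 3, length.out = n)] <- field$dz
  write_meta_raw(path, inter, field$size, field$origin, field$spacing,
                 nchannels = 3L)
  invisible(path)
}

#' Read a displacement field from a 3-channel MetaImage
#'
#' @param path `.mha` or `.mhd` file with `ElementNumberOfChannels = 3`.
#' @param domain,codomain direction labels to stamp on the field.
#' @return A [vector_field()].
#' @export
read_field <- function(path, domain = "A", codomain = "B") {
  m <- read_meta_raw(path)
  if (m$nchannels != 3L) stop("expected 3-channel field, got ", m$nchannels)
  n <- prod(m$size)
  vector_field(array(m$values[seq(1, by = 3, length.out = n)], m$size),
               array(m$values[seq(2, by = 3, length.out = n)], m$size),
               array(m$values[seq(3, by = 3, length.out = n)], m$size),
               m$origin, m$spacing, domain, codomain)
}

#' Read paired landmark files
#'
#' Reads two whitespace-separated text files (one voxel-index triple per
#' line, one file per image) and converts indices to world millimetres via
#' the image geometry. Public lung-landmark sets conventionally use 1-based
#' voxel indices; set `index_base = 0` for 0-based files.
#'
#' @param path_fixed,path_moving landmark files for the fixed and moving image.
#' @param image_geometry geometry of the images the indices refer to
#'   (a [grid_geometry()] or grid; used for both files).
#' @param index_base 1 (default) or 0.
#' @return A [landmark_set()] with `source_convention = "voxel-index"`.
#' @export
read_landmarks <- function(path_fixed, path_moving, image_geometry,
                           index_base = 1) {
  g <- geometry_of(image_geometry)
  parse_one <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    pts <- matrix(NA_real_, length(lines), 3)
    for (i in seq_along(lines)) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(tok))
      if (length(v) != 3 || any(!is.finite(v)))
        stop("unparsable landmark line ", i, " in ", path, ": '", lines[i], "'")
      pts[i, ] <- v
    }
    pts
  }
  pf <- parse_one(path_fixed)
  pm <- parse_one(path_moving)
  if (nrow(pf) != nrow(pm))
    stop("landmark count mismatch: ", nrow(pf), " in ", path_fixed,
         " vs ", nrow(pm), " in ", path_moving)
  to_world <- function(p)
    sweep(sweep(p - index_base, 2L, g$spacing, `*`), 2L, g$origin, `+`)
  landmark_set(to_world(pf), to_world(pm), source_convention = "voxel-index")
}

#' Write landmark voxel indices to a text file
#'
#' Inverse of [read_landmarks()] for one point set: world points are converted
#' to (generally fractional) voxel indices, rounded to the nearest voxel, and
#' written one triple per line.
#'
#' @param points N x 3 world points, mm.
#' @param path output path.
#' @param image_geometry geometry defining the index frame.
#' @param index_base 1 (default) or 0.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(points, path, image_geometry, index_base = 1) {
  g <- geometry_of(image_geometry)
  idx <- round(sweep(sweep(matrix(points, ncol = 3), 2L, g$origin, `-`),
                     2L, g$spacing, `/`)) + index_base
  writeLines(apply(idx, 1, paste, collapse = " "), path)
  invisible(path)
}
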