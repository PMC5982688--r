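# PCD v0.7 reader/writer.
#
# No R package on this system reads PCL's PCD format, so the dialects the
# open body-weight dataset uses are implemented here: FIELDS subsets of
# {x, y, z, rgb, t} (rgb either as a single packed float in the PCL
# convention or as three uint8 fields), DATA ascii or binary, organized or
# unorganized layouts, NaN-encoded invalid points.

floatToBits <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4, endian = "little"),
          "integer", n = length(x), size = 4, endian = "little")
}

bitsToFloat <- function(i) {
  readBin(writeBin(as.integer(i), raw(), size = 4, endian = "little"),
          "double", n = length(i), size = 4, endian = "little")
}

unpackRGB <- function(packedFloat) {
  bits <- floatToBits(packedFloat)
  r <- bitwAnd(bitwShiftR(bits, 16L), 255L)
  g <- bitwAnd(bitwShiftR(bits, 8L), 255L)
  b <- bitwAnd(bits, 255L)
  cbind(r = r, g = g, b = b)
}

packRGB <- function(rgb) {
  bitsToFloat(bitwOr(bitwOr(bitwShiftL(as.integer(rgb[, 1]), 16L),
                            bitwShiftL(as.integer(rgb[, 2]), 8L)),
                     as.integer(rgb[, 3])))
}

pcdFormatError <- function(line, why) {
  stop("malformed PCD header: ", why, " [", line, "]", call. = FALSE)
}

#' Read a PCD point-cloud file
#'
#' Reads PCL's PCD v0.7 format, ascii or binary, with any subset of the
#' fields x, y, z, rgb (packed float or split r/g/b uint8) and t
#' (temperature, degrees Celsius). The organized grid layout is preserved
#' when the header declares HEIGHT > 1; NaN coordinates mark invalid points.
#'
#' @param path path to a .pcd file.
#' @return a [PointCloud-class].
#' @seealso [writePCD()], [parseDatasetFilename()]
#' @export
readPCD <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) pcdFormatError("<eof>", "truncated header")
    line <- sub("\r$", "", line)
    if (grepl("^#", line) || !nzchar(trimws(line))) next
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    key <- toupper(tok[1])
    hdr[[key]] <- tok[-1]
    if (key == "DATA") break
    if (!key %in% c("VERSION", "FIELDS", "SIZE", "TYPE", "COUNT",
                    "WIDTH", "HEIGHT", "VIEWPOINT", "POINTS"))
      pcdFormatError(line, "unknown header keyword")
  }
  for (req in c("FIELDS", "SIZE", "TYPE", "WIDTH", "HEIGHT", "POINTS",
                "DATA"))
    if (is.null(hdr[[req]]))
      pcdFormatError(req, "missing required header entry")
  fields <- tolower(hdr$FIELDS)
  sizes <- as.integer(hdr$SIZE)
  types <- toupper(hdr$TYPE)
  counts <- if (is.null(hdr$COUNT)) rep(1L, length(fields))
            else as.integer(hdr$COUNT)
  if (length(sizes) != length(fields) || length(types) != length(fields) ||
      length(counts) != length(fields))
    pcdFormatError(paste(hdr$FIELDS, collapse = " "),
                   "FIELDS/SIZE/TYPE/COUNT length mismatch")
  if (any(counts != 1L))
    pcdFormatError("COUNT", "only COUNT 1 fields are supported")
  if (!all(c("x", "y", "z") %in% fields))
    pcdFormatError(paste(fields, collapse = " "),
                   "FIELDS must include x, y and z")
  npts <- as.integer(hdr$POINTS[1])
  width <- as.integer(hdr$WIDTH[1])
  height <- as.integer(hdr$HEIGHT[1])
  if (width * height != npts)
    pcdFormatError(paste("POINTS", npts), "WIDTH * HEIGHT != POINTS")
  dialect <- tolower(hdr$DATA[1])

  nf <- length(fields)
  if (dialect == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) != npts && npts > 0)
      pcdFormatError(paste("DATA ascii,", length(txt), "rows"),
                     "data row count does not match POINTS")
    if (npts == 0) {
      vals <- matrix(numeric(0), 0, nf)
    } else {
      toks <- strsplit(trimws(txt), "[[:space:]]+")
      nt <- lengths(toks)
      if (any(nt != nf))
        stop("field-count mismatch in data row ",
             which(nt != nf)[1], call. = FALSE)
      vals <- matrix(suppressWarnings(as.numeric(unlist(toks))),
                     ncol = nf, byrow = TRUE)
    }
  } else if (dialect == "binary") {
    stride <- sum(sizes)
    raws <- readBin(con, "raw", n = stride * npts)
    if (length(raws) != stride * npts)
      pcdFormatError("DATA binary", "truncated binary payload")
    vals <- matrix(NA_real_, npts, nf)
    off <- 0L
    for (j in seq_len(nf)) {
      cols <- as.vector(outer(seq_len(sizes[j]) + off,
                              (seq_len(npts) - 1L) * stride, "+"))
      sub <- raws[cols]
      vals[, j] <- switch(types[j],
        F = readBin(sub, "double", n = npts, size = sizes[j],
                    endian = "little"),
        U = as.numeric(readBin(sub, "integer", n = npts, size = sizes[j],
                    signed = sizes[j] >= 4, endian = "little")),
        I = as.numeric(readBin(sub, "integer", n = npts, size = sizes[j],
                    endian = "little")),
        pcdFormatError(paste("TYPE", types[j]), "unsupported field type"))
      off <- off + sizes[j]
    }
  } else {
    pcdFormatError(paste("DATA", dialect), "unsupported DATA dialect")
  }

  colIx <- function(f) match(f, fields)
  co <- vals[, c(colIx("x"), colIx("y"), colIx("z")), drop = FALSE]
  color <- NULL
  if ("rgb" %in% fields) {
    color <- unpackRGB(vals[, colIx("rgb")])
  } else if (all(c("r", "g", "b") %in% fields)) {
    color <- cbind(vals[, colIx("r")], vals[, colIx("g")],
                   vals[, colIx("b")])
  }
  temp <- if ("t" %in% fields) vals[, colIx("t")] else NULL
  meta <- tryCatch(parseDatasetFilename(basename(path)),
                   error = function(e) list())
  pointCloud(co, color = color, temperature = temp,
             width = if (height > 1L) width else 0L,
             height = if (height > 1L) height else 0L,
             meta = meta)
}

#' Write a point cloud to a PCD file
#'
#' The ascii dialect stores coordinates with 6 decimal places (round-trip
#' within 1e-6 m) and color as split uint8 r/g/b fields; the binary dialect
#' stores coordinates and temperature as 8-byte floats (exact round-trip)
#' and color as a PCL packed-float rgb field.
#'
#' @param cloud a [PointCloud-class].
#' @param path output path.
#' @param dialect "ascii" or "binary".
#' @export
writePCD <- function(cloud, path, dialect = c("ascii", "binary")) {
  dialect <- match.arg(dialect)
  stopifnot(is(cloud, "PointCloud"))
  n <- nrow(cloud@coords)
  org <- isOrganized(cloud)
  width <- if (org) cloud@width else n
  height <- if (org) cloud@height else 1L
  withColor <- hasColor(cloud)
  withTemp <- hasTemperature(cloud)

  if (dialect == "ascii") {
    fields <- c("x", "y", "z",
                if (withColor) c("r", "g", "b"), if (withTemp) "t")
    sizes <- c(4, 4, 4, if (withColor) c(1, 1, 1), if (withTemp) 4)
    types <- c("F", "F", "F", if (withColor) c("U", "U", "U"),
               if (withTemp) "F")
  } else {
    fields <- c("x", "y", "z", if (withColor) "rgb", if (withTemp) "t")
    sizes <- c(8, 8, 8, if (withColor) 4, if (withTemp) 8)
    types <- c("F", "F", "F", if (withColor) "F", if (withTemp) "F")
  }
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", paste(fields, collapse = " ")),
           paste("SIZE", paste(sizes, collapse = " ")),
           paste("TYPE", paste(types, collapse = " ")),
           paste("COUNT", paste(rep(1L, length(fields)), collapse = " ")),
           paste("WIDTH", width),
           paste("HEIGHT", height),
           "VIEWPOINT 0 0 0 1 0 0 0",
           paste("POINTS", n),
           paste("DATA", dialect))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(hdr, con)
  if (n == 0) return(invisible(NULL))

  if (dialect == "ascii") {
    rows <- sprintf("%.6f %.6f %.6f", cloud@coords[, 1], cloud@coords[, 2],
                    cloud@coords[, 3])
    if (withColor)
      rows <- paste(rows, cloud@color[, 1], cloud@color[, 2],
                    cloud@color[, 3])
    if (withTemp) {
      tt <- cloud@temperature
      tt[is.na(tt)] <- NaN
      rows <- paste(rows, sprintf("%.4f", tt))
    }
    writeLines(rows, con)
  } else {
    stride <- sum(sizes)
    buf <- raw(stride * n)
    off <- 0L
    putF <- function(vals, size) {
      b <- writeBin(as.numeric(vals), raw(), size = size,
                    endian = "little")
      bm <- matrix(b, nrow = size)
      ix <- as.vector(outer(seq_len(size) + off,
                            (seq_len(n) - 1L) * stride, "+"))
      buf[ix] <<- as.vector(bm)
      off <<- off + size
    }
    putF(cloud@coords[, 1], 8L)
    putF(cloud@coords[, 2], 8L)
    putF(cloud@coords[, 3], 8L)
    if (withColor) putF(packRGB(cloud@color), 4L)
    if (withTemp) {
      tt <- cloud@temperature
      tt[is.na(tt)] <- NaN
      putF(tt, 8L)
    }
    writeBin(buf, con)
  }
  invisible(NULL)
}

#' Parse the dataset file-name convention into subject metadata
#'
#' The open dataset names each frame
#' \code{GENDER_GROUNDTRUTH_PERSONID_FRAME_ID.pcd}. The gender token may be
#' \code{f}/\code{m} or \code{female}/\code{male} (case-insensitive); the
#' ground-truth token is the weight in kilograms.
#'
#' @param name file name (directories are stripped).
#' @return list with \code{gender} ("female"/"male"), \code{ground_truth_kg},
#'   \code{person_id} and \code{frame_id}.
#' @examples
#' parseDatasetFilename("f_62_007_0012.pcd")
#' @export
parseDatasetFilename <- function(name) {
  base <- basename(name)
  if (!grepl("\\.pcd$", base, ignore.case = TRUE))
    stop("not a .pcd file name: ", name, call. = FALSE)
  stem <- sub("\\.pcd$", "", base, ignore.case = TRUE)
  tok <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(tok) != 4)
    stop("expected GENDER_GROUNDTRUTH_PERSONID_FRAMEID.pcd, got: ",
         base, call. = FALSE)
  g <- tolower(tok[1])
  gender <- if (g %in% c("f", "female")) "female"
            else if (g %in% c("m", "male")) "male"
            else stop("unrecognized gender token: ", tok[1], call. = FALSE)
  wt <- suppressWarnings(as.numeric(tok[2]))
  if (!is.finite(wt) || wt <= 0)
    stop("ground-truth weight token is not a positive number: ", tok[2],
         call. = FALSE)
  pid <- suppressWarnings(as.integer(tok[3]))
  fid <- suppressWarnings(as.integer(tok[4]))
  if (is.na(pid) || is.na(fid))
    stop("person/frame id tokens must be integers: ", base, call. = FALSE)
  list(gender = gender, ground_truth_kg = wt, person_id = pid,
       frame_id = fid)
}
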