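# Readers/writers for the three generic point-cloud formats. No installed
# R package parses PLY/PCD, so these follow the public format specs
# directly. Coordinates are always interpreted as millimetres.

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.feature_names <- c("curvature", "sigma", "quality", "scalar", "intensity")

#' Read a point cloud from PLY, PCD or XYZ
#'
#' PLY (ascii and binary little-endian), PCD (ascii) and plain XYZ are
#' supported. A per-vertex scalar property named `curvature`, `sigma`,
#' `quality`, `scalar` or `intensity` (PLY/PCD), or a 4th numeric column
#' (XYZ), is loaded into the cloud's feature channel. XYZ lines starting
#' with `#` are comments.
#'
#' @param path file path.
#' @param format `"auto"` (by extension) or one of `"ply"`, `"pcd"`,
#'   `"xyz"`.
#' @param source_tag label stored on the returned cloud.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "pcd", "xyz"),
                             source_tag = "synthetic") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", pcd = "pcd", xyz = "xyz", txt = "xyz",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  switch(format,
         ply = .read_ply(path, source_tag),
         pcd = .read_pcd(path, source_tag),
         xyz = .read_xyz(path, source_tag))
}

#' Write a point cloud to PLY, PCD or XYZ
#'
#' The feature channel, when present, is written as a `curvature` vertex
#' property (PLY/PCD) or 4th column (XYZ).
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param format `"auto"` (by extension) or one of `"ply"`, `"pcd"`,
#'   `"xyz"`.
#' @param binary write binary little-endian PLY instead of ascii.
#' @export
write_point_cloud <- function(cloud, path,
                              format = c("auto", "ply", "pcd", "xyz"),
                              binary = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", pcd = "pcd", xyz = "xyz", txt = "xyz",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  switch(format,
         ply = .write_ply(cloud, path, binary),
         pcd = .write_pcd(cloud, path),
         xyz = .write_xyz(cloud, path))
  invisible(path)
}

.read_xyz <- function(path, source_tag) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  rows <- which(keep)
  if (length(rows) == 0L) stop("empty XYZ file: ", path)
  vals <- lapply(rows, function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) < 3L || anyNA(v)) {
      stop("malformed XYZ record at line ", i, " of ", path)
    }
    v
  })
  ncols <- vapply(vals, length, 1L)
  pts <- do.call(rbind, lapply(vals, function(v) v[1:3]))
  feats <- if (all(ncols >= 4L)) vapply(vals, function(v) v[4L], 1.0) else NULL
  point_cloud(pts, feats, source_tag)
}

.write_xyz <- function(cloud, path) {
  m <- cloud$points
  if (!is.null(cloud$features)) m <- cbind(m, cloud$features)
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.9g", r), collapse = " ")),
             path)
}

.parse_ply_header <- function(con, path) {
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("PLY header not terminated in ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(), types = character(), lists = logical())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property before element in ", path)
      if (tok[2] == "list") {
        cur$props <- c(cur$props, tok[5])
        cur$types <- c(cur$types, paste(tok[3], tok[4], sep = ":"))
        cur$lists <- c(cur$lists, TRUE)
      } else {
        cur$props <- c(cur$props, tok[3])
        cur$types <- c(cur$types, tok[2])
        cur$lists <- c(cur$lists, FALSE)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      stop("unrecognized PLY header line in ", path, ": ", line)
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format '", fmt, "' in ", path)
  }
  list(format = fmt, elements = elements)
}

.read_ply <- function(path, source_tag) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .parse_ply_header(con, path)
  vert <- hdr$elements[["vertex"]]
  if (is.null(vert) || vert$count < 1L) stop("PLY has no vertices: ", path)
  if (any(vert$lists)) stop("list properties on vertex element unsupported: ", path)
  nprop <- length(vert$props)
  if (hdr$format == "ascii") {
    # elements appear in declaration order; vertex is read first if first
    elnames <- names(hdr$elements)
    vals <- NULL
    for (el in elnames) {
      e <- hdr$elements[[el]]
      if (el == "vertex") {
        vals <- matrix(NA_real_, e$count, nprop)
        for (i in seq_len(e$count)) {
          line <- readLines(con, n = 1L)
          v <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
          if (length(v) < nprop || anyNA(v[seq_len(nprop)])) {
            stop("malformed PLY vertex record ", i, " in ", path)
          }
          vals[i, ] <- v[seq_len(nprop)]
        }
        break  # later elements are irrelevant
      } else {
        readLines(con, n = e$count)  # skip
      }
    }
  } else {
    elnames <- names(hdr$elements)
    vals <- NULL
    for (el in elnames) {
      e <- hdr$elements[[el]]
      if (any(e$lists) && el != "vertex") {
        if (is.null(vals)) {
          stop("cannot skip list element '", el, "' preceding vertices in ", path)
        }
        break
      }
      sizes <- .ply_type_size[e$types]
      if (anyNA(sizes)) stop("unknown PLY property type in ", path)
      if (el == "vertex") {
        raw <- readBin(con, "raw", n = e$count * sum(sizes))
        if (length(raw) < e$count * sum(sizes)) {
          stop("truncated PLY payload in ", path)
        }
        vals <- matrix(NA_real_, e$count, nprop)
        offs <- cumsum(c(0L, sizes))
        stride <- sum(sizes)
        for (p in seq_len(nprop)) {
          ty <- e$types[p]
          sz <- sizes[p]
          # gather the p-th property bytes across records
          sel <- as.vector(outer(seq_len(sz), (seq_len(e$count) - 1L) * stride,
                                 "+") + offs[p])
          bytes <- raw[sel]
          vals[, p] <- switch(ty,
            float = , float32 = readBin(bytes, "double", e$count, size = 4L,
                                        endian = "little"),
            double = , float64 = readBin(bytes, "double", e$count, size = 8L,
                                         endian = "little"),
            char = , int8 = readBin(bytes, "integer", e$count, size = 1L,
                                    signed = TRUE, endian = "little"),
            uchar = , uint8 = readBin(bytes, "integer", e$count, size = 1L,
                                      signed = FALSE, endian = "little"),
            short = , int16 = readBin(bytes, "integer", e$count, size = 2L,
                                      signed = TRUE, endian = "little"),
            ushort = , uint16 = readBin(bytes, "integer", e$count, size = 2L,
                                        signed = FALSE, endian = "little"),
            int = , int32 = , uint = , uint32 =
              readBin(bytes, "integer", e$count, size = 4L, endian = "little"),
            stop("unsupported PLY type ", ty))
        }
        break
      } else {
        readBin(con, "raw", n = e$count * sum(sizes))
      }
    }
  }
  if (is.null(vals)) stop("PLY vertex element not found in ", path)
  ip <- match(c("x", "y", "z"), vert$props)
  if (anyNA(ip)) stop("PLY vertex element lacks x/y/z in ", path)
  feat_col <- match(.feature_names, vert$props)
  feat_col <- feat_col[!is.na(feat_col)][1]
  point_cloud(vals[, ip, drop = FALSE],
              if (!is.na(feat_col)) vals[, feat_col] else NULL,
              source_tag)
}

.write_ply <- function(cloud, path, binary) {
  n <- n_points(cloud)
  has_f <- !is.null(cloud$features)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           if (has_f) "property double curvature",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  m <- cloud$points
  if (has_f) m <- cbind(m, cloud$features)
  if (binary) {
    writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
  } else {
    body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
    writeChar(paste0(paste(body, collapse = "\n"), "\n"), con, eos = NULL)
  }
}

.read_pcd <- function(path, source_tag) {
  lines <- readLines(path, warn = FALSE)
  hdr_keys <- c("VERSION", "FIELDS", "SIZE", "TYPE", "COUNT", "WIDTH",
                "HEIGHT", "VIEWPOINT", "POINTS", "DATA")
  hdr <- list()
  data_start <- NA_integer_
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l) || startsWith(l, "#")) next
    tok <- strsplit(l, "\\s+")[[1]]
    if (toupper(tok[1]) %in% hdr_keys) {
      hdr[[toupper(tok[1])]] <- tok[-1]
      if (toupper(tok[1]) == "DATA") { data_start <- i + 1L; break }
    } else {
      stop("malformed PCD header at line ", i, " of ", path)
    }
  }
  if (is.na(data_start)) stop("PCD DATA line missing in ", path)
  if (tolower(hdr$DATA[1]) != "ascii") {
    stop("only ascii PCD is supported (got '", hdr$DATA[1], "') in ", path)
  }
  fields <- tolower(hdr$FIELDS)
  npts <- as.integer(hdr$POINTS[1])
  if (is.na(npts) || npts < 1L) stop("empty PCD cloud in ", path)
  rows <- lines[data_start:length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) < npts) stop("PCD declares ", npts, " points but has ",
                                length(rows), " data rows: ", path)
  vals <- matrix(NA_real_, npts, length(fields))
  for (i in seq_len(npts)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]), "\\s+")[[1]]))
    if (length(v) < length(fields) || anyNA(v[seq_along(fields)])) {
      stop("malformed PCD record ", i, " in ", path)
    }
    vals[i, ] <- v[seq_along(fields)]
  }
  ip <- match(c("x", "y", "z"), fields)
  if (anyNA(ip)) stop("PCD lacks x/y/z fields in ", path)
  feat_col <- match(.feature_names, fields)
  feat_col <- feat_col[!is.na(feat_col)][1]
  point_cloud(vals[, ip, drop = FALSE],
              if (!is.na(feat_col)) vals[, feat_col] else NULL,
              source_tag)
}

.write_pcd <- function(cloud, path) {
  n <- n_points(cloud)
  has_f <- !is.null(cloud$features)
  fields <- if (has_f) "x y z curvature" else "x y z"
  k <- if (has_f) 4L else 3L
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", fields),
           paste("SIZE", paste(rep(8L, k), collapse = " ")),
           paste("TYPE", paste(rep("F", k), collapse = " ")),
           paste("COUNT", paste(rep(1L, k), collapse = " ")),
           sprintf("WIDTH %d", n),
           "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0",
           sprintf("POINTS %d", n),
           "DATA ascii")
  m <- cloud$points
  if (has_f) m <- cbind(m, cloud$features)
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
}
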