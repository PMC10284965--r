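#' Read a triangle mesh from OBJ, PLY or STL
#'
#' Standard-format readers with no custom dialects. PLY is supported in
#' ascii and binary (little/big endian) form; STL in binary and ascii
#' form, with exact duplicate vertices merged at a tolerance of 1e-7 mm.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"obj"`, `"ply"`, `"stl"`; `"auto"`
#'   picks by file extension.
#' @return a [tri_mesh()] object.
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: file not found: ", path)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("obj", "ply", "stl"))
      stop("cannot infer mesh format from extension: ", path)
  }
  switch(format,
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl(path))
}

#' Write a triangle mesh to OBJ, PLY or STL
#'
#' Round trips preserve coordinates to better than 1e-5 mm in every
#' format. STL stores no shared topology; writing a non-watertight mesh
#' to STL succeeds with a warning.
#'
#' @param mesh a [tri_mesh()] object.
#' @param path output file path.
#' @param format one of `"auto"`, `"obj"`, `"ply"`, `"stl"`.
#' @param binary for PLY, write binary little-endian (default ascii);
#'   STL is always written binary.
#' @return `invisible(path)`.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply", "stl"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("obj", "ply", "stl"))
      stop("cannot infer mesh format from extension: ", path)
  }
  switch(format,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path, binary = binary),
         stl = write_stl(mesh, path))
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(fl) == 0L) stop("empty mesh: OBJ file has no faces")
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"),
                             function(x) as.numeric(x[2:4])))
  F <- do.call(rbind, lapply(strsplit(trimws(fl), "[[:space:]]+"), function(x) {
    idx <- as.integer(vapply(strsplit(x[-1], "/"), `[[`, "", 1L))
    if (length(idx) != 3L)
      stop("OBJ reader supports triangle faces only")
    idx
  }))
  tri_mesh(V, F)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.8g %.8g %.8g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type, endian) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", n = 1L, size = sz, endian = endian)
  } else {
    signed <- !startsWith(type, "u")
    readBin(con, "integer", n = 1L, size = sz, signed = signed || sz >= 4,
            endian = endian)
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- "ascii"
  endian <- "little"
  elements <- list()
  cur <- NULL
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unexpected end of PLY header")
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (fmt == "binary_big_endian") endian <- "big"
    } else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        elements[[cur]]$props[[tok[5]]] <-
          list(list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        elements[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") break
  }
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY file must contain vertex and face elements")
  nv <- elements$vertex$count
  nf <- elements$face$count
  if (nf == 0L) stop("empty mesh: PLY file has no faces")
  vp <- elements$vertex$props
  fp <- elements$face$props
  if (fmt == "ascii") {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    vlines <- rest[seq_len(nv)]
    flines <- rest[nv + seq_len(nf)]
    vdat <- do.call(rbind, lapply(strsplit(trimws(vlines), "[[:space:]]+"),
                                  as.numeric))
    colnames(vdat) <- names(vp)
    V <- vdat[, c("x", "y", "z"), drop = FALSE]
    F <- do.call(rbind, lapply(strsplit(trimws(flines), "[[:space:]]+"),
                               function(x) {
      n <- as.integer(x[1])
      if (n != 3L) stop("PLY reader supports triangle faces only")
      as.integer(x[2:4]) + 1L
    }))
  } else {
    V <- matrix(NA_real_, nv, length(vp))
    colnames(V) <- names(vp)
    for (i in seq_len(nv)) {
      for (j in seq_along(vp)) {
        V[i, j] <- ply_read_scalar(con, vp[[j]]$type, endian)
      }
    }
    V <- V[, c("x", "y", "z"), drop = FALSE]
    lp <- fp[[1]]
    if (!isTRUE(lp$list)) stop("PLY face element must be an index list")
    F <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      n <- ply_read_scalar(con, lp$count_type, endian)
      if (n != 3L) stop("PLY reader supports triangle faces only")
      for (k in 1:3) F[i, k] <- ply_read_scalar(con, lp$type, endian) + 1L
    }
  }
  tri_mesh(V, F)
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.10g %.10g %.10g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
}

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(512L, sz))
  close(con)
  txt <- rawToChar(head[head != as.raw(0)])
  is_ascii <- startsWith(txt, "solid") && grepl("facet", txt, fixed = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L) stop("empty mesh: STL file has no facets")
  stl_dedup(tri)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  # each 50-byte record: 12 float32 then a 2-byte attribute count
  raw <- readBin(con, "raw", n = nt * 50L)
  keep <- rep(c(rep(TRUE, 48L), FALSE, FALSE), nt)
  dat <- readBin(raw[keep], "double", n = nt * 12L, size = 4L,
                 endian = "little")
  rec <- matrix(dat, nrow = nt, ncol = 12L, byrow = TRUE)
  # columns 4..12 are the three vertices; 1..3 the facet normal
  rbind(rec[, 4:6, drop = FALSE], rec[, 7:9, drop = FALSE],
        rec[, 10:12, drop = FALSE])[order(rep(seq_len(nt), 3)), , drop = FALSE]
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^[[:space:]]*vertex", lines, value = TRUE)
  if (length(vl) %% 3L != 0L) stop("malformed ascii STL")
  do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"),
                        function(x) as.numeric(x[2:4])))
}

# merge duplicated corner vertices; tolerance in mm
stl_dedup <- function(tri, tol = 1e-7) {
  key <- paste(round(tri[, 1] / tol), round(tri[, 2] / tol),
               round(tri[, 3] / tol))
  idx <- match(key, unique(key))
  first <- !duplicated(key)
  V <- tri[first, , drop = FALSE]
  F <- matrix(idx, ncol = 3L, byrow = TRUE)
  tri_mesh(V, F)
}

write_stl <- function(mesh, path) {
  rep <- validate_mesh(mesh)
  if (!rep$is_watertight)
    warning("writing a non-watertight surface to STL")
  fn <- face_normals(mesh)$normals
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw(sprintf("%-10s", "palatoplate binary stl")),
             raw(80L))[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  V <- mesh$vertices
  F <- mesh$faces
  zero <- as.raw(c(0, 0))
  for (i in seq_len(nf)) {
    writeBin(c(fn[i, ], V[F[i, 1], ], V[F[i, 2], ], V[F[i, 3], ]), con,
             size = 4L, endian = "little")
    writeBin(zero, con)
  }
}
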