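# Triangle-mesh file IO: PLY (ASCII + binary little-endian), STL (ASCII +
# binary) and OBJ (triangles only). Counter-clockwise winding = outward.
#
# Precision notes: ASCII formats and binary PLY store full double precision
# (round trip well within 1e-6 mm); binary STL is defined as float32 by the
# format itself, so its round trip is only accurate to single precision.

mesh_format_of <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ply", "stl", "obj"))
    stopf("unknown mesh extension '.%s' (supported: ply, stl, obj)", ext)
  ext
}

#' Read a bone mesh from PLY/STL/OBJ
#'
#' @param path mesh file path; format inferred from the extension.
#' @param label bone name to attach; one of [bone_names()].
#' @param side `"left"` or `"right"`.
#' @return a [bone_mesh()].
#' @export
read_mesh <- function(path, label, side) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  fmt <- mesh_format_of(path)
  m <- switch(fmt,
              ply = read_ply(path),
              stl = read_stl(path),
              obj = read_obj(path))
  if (is.null(m$faces) || nrow(m$faces) == 0L)
    stopf("empty mesh (no faces): %s", path)
  bone_mesh(m$vertices, m$faces, label, side)
}

#' Write a bone mesh to PLY/STL/OBJ
#'
#' @param mesh a [bone_mesh()].
#' @param path output path; format inferred from the extension.
#' @param binary write the binary dialect where the format has one
#'   (PLY little-endian, STL). Ignored for OBJ.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "bone_mesh"))
  fmt <- mesh_format_of(path)
  switch(fmt,
         ply = write_ply(mesh, path, binary),
         stl = write_stl(mesh, path, binary),
         obj = write_obj(mesh, path))
  invisible(path)
}

## ---- PLY ----

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           "comment footmorph mesh",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(v)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ]), con, size = 4, endian = "little")
    }
  } else {
    vl <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    fl <- sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])
    writeLines(c(hdr, vl, fl), path)
  }
  invisible(path)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)
ply_type_int <- c("char", "uchar", "int8", "uint8", "short", "ushort",
                  "int16", "uint16", "int", "uint", "int32", "uint32")

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_hline <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L || b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    sub("\r$", "", rawToChar(chars))
  }
  if (read_hline() != "ply") stopf("corrupt PLY (missing magic): %s", path)
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    ln <- read_hline()
    if (ln == "end_header") break
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stopf("corrupt PLY header: %s", path)
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stopf("unsupported PLY format '%s': %s", fmt %||% "?", path)
  if (!all(c("vertex", "face") %in% names(elements)))
    stopf("corrupt PLY (missing vertex/face elements): %s", path)

  read_scalar <- function(type, n = 1L) {
    if (type %in% ply_type_int)
      readBin(con, "integer", n, size = ply_type_size[[type]],
              endian = "little", signed = !(ply_type_size[[type]] < 4 &&
                                              grepl("^u", type)) )
    else readBin(con, "double", n, size = ply_type_size[[type]],
                 endian = "little")
  }

  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    pos <- 0L
    take <- function(n) { r <- rest[pos + seq_len(n)]; pos <<- pos + n; r }
    out <- list()
    for (el in elements) {
      lines <- take(el$count)
      toks <- strsplit(trimws(lines), "\\s+")
      if (el$name == "vertex") {
        nm <- vapply(el$props, `[[`, "", "name")
        ix <- match(c("x", "y", "z"), nm)
        if (any(is.na(ix))) stopf("PLY vertex element lacks x/y/z: %s", path)
        vv <- t(vapply(toks, function(t) as.numeric(t[ix]), numeric(3)))
        out$vertices <- vv
      } else if (el$name == "face") {
        ff <- t(vapply(toks, function(t) {
          k <- as.integer(t[1])
          if (k != 3L) stopf("non-triangular PLY face (%d vertices): %s", k, path)
          as.integer(t[2:4])
        }, integer(3)))
        out$faces <- ff + 1L
      }
    }
    if (anyNA(out$vertices)) stopf("corrupt PLY vertex data: %s", path)
    out
  } else {
    out <- list()
    for (el in elements) {
      if (el$name == "vertex") {
        nm <- vapply(el$props, `[[`, "", "name")
        if (any(vapply(el$props, `[[`, TRUE, "list")))
          stopf("unsupported PLY: list property on vertices: %s", path)
        vals <- matrix(NA_real_, el$count, length(el$props))
        for (i in seq_len(el$count))
          for (j in seq_along(el$props))
            vals[i, j] <- read_scalar(el$props[[j]]$type)
        ix <- match(c("x", "y", "z"), nm)
        if (any(is.na(ix))) stopf("PLY vertex element lacks x/y/z: %s", path)
        out$vertices <- vals[, ix, drop = FALSE]
      } else if (el$name == "face") {
        p <- el$props[[1]]
        if (!p$list) stopf("unsupported PLY face encoding: %s", path)
        ff <- matrix(NA_integer_, el$count, 3)
        for (i in seq_len(el$count)) {
          k <- read_scalar(p$count_type)
          if (k != 3L) stopf("non-triangular PLY face (%d vertices): %s", k, path)
          ff[i, ] <- read_scalar(p$type, 3L)
        }
        out$faces <- ff + 1L
      } else {
        # skip unknown fixed-width element
        for (i in seq_len(el$count))
          for (p in el$props) {
            if (p$list) { k <- read_scalar(p$count_type); read_scalar(p$type, k) }
            else read_scalar(p$type)
          }
      }
    }
    out
  }
}

## ---- STL ----

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  v1 <- v[f[, 1], , drop = FALSE]
  v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw(sprintf("%-79s", "footmorph binary STL")), as.raw(0)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[i, ], v1[i, ], v2[i, ], v3[i, ])), con,
               size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    fmt3 <- function(x) sprintf("%.17g %.17g %.17g", x[, 1], x[, 2], x[, 3])
    lines <- c("solid footmorph",
               as.vector(rbind(paste0("  facet normal ", fmt3(n)),
                               "    outer loop",
                               paste0("      vertex ", fmt3(v1)),
                               paste0("      vertex ", fmt3(v2)),
                               paste0("      vertex ", fmt3(v3)),
                               "    endloop",
                               "  endfacet")),
               "endsolid footmorph")
    writeLines(lines, path)
  }
  invisible(path)
}

# Rebuild shared connectivity from an STL triangle soup by exact-coordinate
# vertex deduplication.
dedup_soup <- function(tri) {
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_stl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", min(512L, sz))
  close(con)
  printable <- head[head %in% as.raw(c(9L, 10L, 13L, 32:126))]
  txt <- rawToChar(printable)
  is_ascii <- length(printable) > 0.9 * length(head) &&
    grepl("^\\s*solid", txt) && grepl("facet", txt)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L) stopf("empty mesh (no facets in STL): %s", path)
    tri <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(t) as.numeric(t[2:4])))
    if (anyNA(tri) || nrow(tri) %% 3 != 0L)
      stopf("corrupt ASCII STL: %s", path)
    dedup_soup(tri)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    nf <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (is.na(nf) || nf < 0L || 84 + nf * 50 > sz)
      stopf("corrupt binary STL (bad facet count): %s", path)
    if (nf == 0L) stopf("empty mesh (no facets in STL): %s", path)
    tri <- matrix(NA_real_, nf * 3L, 3L)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "double", 12L, size = 4, endian = "little")
      readBin(con, "raw", 2L)
      tri[(i - 1L) * 3L + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
    dedup_soup(tri)
  }
}

## ---- OBJ ----

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c("# footmorph mesh",
               sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])),
             path)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(fl) == 0L) stopf("empty mesh (no faces in OBJ): %s", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(t) as.numeric(t[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(t) {
    t <- t[-1]
    if (length(t) != 3L)
      stopf("OBJ face with %d vertices; only triangles supported: %s",
            length(t), path)
    as.integer(vapply(strsplit(t, "/"), `[[`, "", 1L))
  }))
  if (anyNA(verts) || anyNA(faces)) stopf("corrupt OBJ: %s", path)
  list(vertices = verts, faces = faces)
}
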