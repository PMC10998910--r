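#' Read a triangle mesh from PLY, OBJ or STL
#'
#' Format is detected from the file extension. PLY files may be ascii or
#' binary little-endian; OBJ files are parsed from their `v`/`f` records
#' (texture/normal slots in `f` entries are ignored); STL files may be binary
#' or ascii, and since STL stores no connectivity, exactly coincident corner
#' vertices are welded on load.
#'
#' @param path path to a `.ply`, `.obj` or `.stl` file.
#' @return a [tri_mesh] preserving the file's vertex order (PLY/OBJ).
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path),
    stop("unsupported mesh format: .", ext, " (expected ply/obj/stl)")
  )
  validate_tri_mesh(m)
  m
}

#' Write a triangle mesh to PLY, OBJ or STL
#'
#' @param mesh a [tri_mesh].
#' @param path output path; format chosen by extension.
#' @param binary for PLY, write binary little-endian instead of ascii; STL is
#'   always binary, OBJ always text.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, binary = FALSE) {
  validate_tri_mesh(mesh)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path, binary = binary),
    obj = write_obj(mesh, path),
    stl = write_stl(mesh, path),
    stop("unsupported mesh format: .", ext, " (expected ply/obj/stl)")
  )
  invisible(path)
}

## ---- PLY ----

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type, n = 1L) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", n = n, size = sz, endian = "little")
  } else {
    signed <- !startsWith(type, "u")
    readBin(con, "integer", n = n, size = sz, signed = signed,
            endian = "little")
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = data.frame)
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3],
                                    item_type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY file lacks vertex or face element")
  if (identical(fmt, "ascii")) {
    read_ply_ascii_body(con, elements)
  } else if (identical(fmt, "binary_little_endian")) {
    read_ply_binary_body(con, elements)
  } else {
    stop("unsupported PLY format: ", fmt)
  }
}

read_ply_ascii_body <- function(con, elements) {
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  pos <- 1L
  out <- list()
  for (el in elements) {
    if (el$count == 0L) next
    chunk <- lines[pos:(pos + el$count - 1L)]
    pos <- pos + el$count
    if (el$name == "vertex") {
      vals <- matrix(as.numeric(unlist(strsplit(trimws(chunk), "\\s+"))),
                     nrow = el$count, byrow = TRUE)
      idx <- match(c("x", "y", "z"), names(el$props))
      out$vertices <- vals[, idx, drop = FALSE]
    } else if (el$name == "face") {
      faces <- lapply(strsplit(trimws(chunk), "\\s+"), function(tok) {
        k <- as.integer(tok[1])
        as.integer(tok[2:(1 + k)])
      })
      out$faces <- triangulate_polygons(faces)
    }
  }
  tri_mesh(out$vertices, out$faces, validate = FALSE)
}

read_ply_binary_body <- function(con, elements) {
  out <- list()
  for (el in elements) {
    if (el$name == "vertex") {
      types <- vapply(el$props, function(p) p$type, "")
      nm <- names(el$props)
      vals <- matrix(NA_real_, el$count, length(nm))
      # properties interleave per vertex; read record by record only if
      # mixed sizes, else read as one block
      if (length(unique(types)) == 1L) {
        block <- ply_read_scalar(con, types[1], n = el$count * length(nm))
        vals <- matrix(block, el$count, length(nm), byrow = TRUE)
      } else {
        for (i in seq_len(el$count))
          for (j in seq_along(nm))
            vals[i, j] <- ply_read_scalar(con, types[j])
      }
      out$vertices <- vals[, match(c("x", "y", "z"), nm), drop = FALSE]
    } else if (el$name == "face") {
      p <- el$props[[1]]
      faces <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        k <- ply_read_scalar(con, p$count_type)
        faces[[i]] <- ply_read_scalar(con, p$item_type, n = k)
      }
      out$faces <- triangulate_polygons(faces)
    }
  }
  tri_mesh(out$vertices, out$faces, validate = FALSE)
}

# 0-based polygon index lists -> 1-based triangle fan matrix
triangulate_polygons <- function(faces) {
  tris <- lapply(faces, function(ix) {
    ix <- as.integer(ix) + 1L
    if (length(ix) < 3L) return(NULL)
    cbind(ix[1], ix[2:(length(ix) - 1L)], ix[3:length(ix)])
  })
  do.call(rbind, tris)
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(v)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    body_v <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    body_f <- sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])
    writeLines(c(hdr, body_v, body_f), path)
  }
  invisible(path)
}

## ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L || length(flines) == 0L)
    stop("malformed mesh: OBJ without v/f records")
  v <- t(vapply(strsplit(vlines, "\\s+"),
                function(tok) as.numeric(tok[2:4]), numeric(3)))
  faces <- lapply(strsplit(flines, "\\s+"), function(tok) {
    as.integer(vapply(strsplit(tok[-1], "/", fixed = TRUE),
                      `[[`, "", 1L))
  })
  tris <- lapply(faces, function(ix) {
    if (length(ix) < 3L) return(NULL)
    cbind(ix[1], ix[2:(length(ix) - 1L)], ix[3:length(ix)])
  })
  tri_mesh(v, do.call(rbind, tris), validate = FALSE)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  invisible(path)
}

## ---- STL ----

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", n = 80L)
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(con, "integer", size = 4L, endian = "little")
    if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  if (is_binary) {
    tri <- matrix(NA_real_, ntri * 3L, 3L)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
      tri[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
      readBin(con, "raw", n = 2L)
    }
  } else {
    close(con)
    on.exit(NULL)
    lines <- trimws(readLines(path, warn = FALSE))
    vlines <- lines[startsWith(lines, "vertex")]
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
      stop("malformed mesh: ascii STL without vertex triples")
    tri <- t(vapply(strsplit(vlines, "\\s+"),
                    function(tok) as.numeric(tok[2:4]), numeric(3)))
  }
  weld_vertices(tri)
}

# Turn a soup of corner triples into an indexed mesh by exact-match welding.
weld_vertices <- function(tri) {
  key <- apply(tri, 1L, paste, collapse = " ")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  v <- tri[uniq, , drop = FALSE]
  f <- matrix(idx, ncol = 3L, byrow = TRUE)
  tri_mesh(v, f, validate = FALSE)
}

write_stl <- function(mesh, path) {
  co <- face_corners(mesh)
  nrm <- cross3(co$B - co$A, co$C - co$A)
  len <- row_norms(nrm)
  nrm <- nrm / ifelse(len > 0, len, 1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(n_faces(mesh)), con, size = 4L, endian = "little")
  for (i in seq_len(n_faces(mesh))) {
    writeBin(c(nrm[i, ], co$A[i, ], co$B[i, ], co$C[i, ]), con,
             size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
  invisible(path)
}
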