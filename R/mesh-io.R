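#' Read a triangle mesh from STL, PLY or OBJ
#'
#' The format is taken from the file extension (`.stl`, `.ply`, `.obj`,
#' case-insensitive). STL may be binary or ASCII (detected from content);
#' its per-facet repeated corners are merged with a 1e-6 mm tolerance. OBJ
#' 1-based indices are kept as the package's native 1-based indexing; PLY
#' 0-based indices are shifted up. Quads and larger polygons in OBJ/PLY are
#' fan-triangulated.
#'
#' @param path file path.
#' @param label component label for the resulting mesh.
#' @return a validated [trimesh()].
#' @export
read_mesh <- function(path, label = "mesh") {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = read_stl(path, label),
    obj = read_obj(path, label),
    ply = read_ply(path, label),
    stop("unsupported mesh format '", ext, "' (use STL, PLY or OBJ)")
  )
  validate_trimesh(mesh)
  mesh
}

# binary STL: 80-byte header, uint32 count, 50 bytes per facet
stl_is_binary <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 84)
  n <- readBin(head[81:84], "integer", 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(n)
  if (identical(expected, as.numeric(size))) return(TRUE)
  # fall back to sniffing for the ASCII keyword
  !grepl("^\\s*solid", rawToChar(head[1:min(40, length(head))]))
}

read_stl <- function(path, label) {
  if (stl_is_binary(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    tri <- matrix(NA_real_, nrow = 3L * n, ncol = 3L)
    for (i in seq_len(n)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)  # attribute byte count
      tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], ncol = 3L, byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop("malformed ASCII STL: ", path)
    tri <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
  }
  faces <- matrix(seq_len(nrow(tri)), ncol = 3L, byrow = TRUE)
  merged <- merge_vertices(tri, faces, tol = 1e-6)
  trimesh(merged$vertices, merged$faces, label)
}

read_obj <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L) stop("malformed OBJ: ", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(vapply(strsplit(x[-1], "/"), `[`, "", 1L))
    if (any(idx < 0)) idx[idx < 0] <- nrow(verts) + 1L + idx[idx < 0]
    fan_triangulate(idx)
  }))
  trimesh(verts, faces, label)
}

read_ply <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("malformed PLY: ", path)
  if (!any(grepl("format\\s+ascii", lines))) stop("only ASCII PLY is supported: ", path)
  end <- match("end_header", trimws(lines))
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", lines, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path)
  body <- lines[(end + 1L):length(lines)]
  verts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                                 function(x) {
    k <- as.integer(x[1])
    fan_triangulate(as.integer(x[2:(1 + k)]) + 1L)  # PLY is 0-based
  }))
  trimesh(verts, faces, label)
}

fan_triangulate <- function(idx) {
  if (length(idx) < 3L) stop("face with fewer than 3 vertices")
  if (length(idx) == 3L) return(matrix(idx, ncol = 3L))
  do.call(rbind, lapply(2:(length(idx) - 1L), function(k) idx[c(1L, k, k + 1L)]))
}

#' Write a triangle mesh to ASCII STL or OBJ
#'
#' @param mesh a [trimesh()].
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$label), con)
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- face_normal(tri)
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
        "    endloop",
        "  endfacet"
      ), con)
    }
    writeLines(sprintf("endsolid %s", mesh$label), con)
  } else if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    stop("unsupported output format '", ext, "' (use stl or obj)")
  }
  invisible(path)
}

face_normal <- function(tri) {
  e1 <- tri[2, ] - tri[1, ]
  e2 <- tri[3, ] - tri[1, ]
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-300) c(0, 0, 0) else n / nn
}

#' Read landmarks from CSV or JSON
#'
#' CSV files need columns `name,x,y,z`; JSON files map landmark names to
#' length-3 coordinate arrays. Coordinates are in mm.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("cannot read landmark file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "x", "y", "z") %in% names(df)))
    pts <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, c("x", "y", "z")]))
    names(pts) <- df$name
  } else if (ext == "json") {
    pts <- lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.numeric)
  } else {
    stop("unsupported landmark format '", ext, "'")
  }
  do.call(landmark_set, pts)
}

#' Read per-patient implant parameters
#'
#' CSV (or JSON array of records) with columns `patient_id`, `side`,
#' `inclination_deg`, `anteversion_deg`, `stem_anteversion_deg`,
#' `head_offset_mm`, `head_diameter_mm`.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return data frame with the validated columns.
#' @export
read_implant_params <- function(path) {
  if (!file.exists(path)) stop("cannot read implant parameter file: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
        else if (ext == "json") as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
        else stop("unsupported implant parameter format '", ext, "'")
  needed <- c("patient_id", "side", "inclination_deg", "anteversion_deg",
              "stem_anteversion_deg", "head_offset_mm", "head_diameter_mm")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L)
    stop("missing implant parameter columns: ", paste(missing, collapse = ", "))
  if (!all(df$side %in% c("L", "R"))) stop("side must be 'L' or 'R'")
  num <- setdiff(needed, c("patient_id", "side"))
  if (!all(vapply(df[num], function(x) all(is.finite(x)), TRUE)))
    stop("non-finite implant parameters")
  df
}

#' Write landmarks to CSV
#'
#' @param landmarks a [landmark_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(name = names(landmarks),
                   x = vapply(landmarks, `[`, 0, 1L),
                   y = vapply(landmarks, `[`, 0, 2L),
                   z = vapply(landmarks, `[`, 0, 3L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
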