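# Legacy-ASCII VTK unstructured-grid serialisation for hexahedral meshes
# with per-element scalar fields. Only VTK cell type 12 (hexahedron) is
# accepted; anything else is a contract violation for this package.

#' Write a hexahedral mesh as a legacy VTK unstructured grid
#'
#' Nodes, hexahedral cells and all per-element fields are written in ASCII
#' with full double precision, so a read/write round trip reproduces the mesh
#' to floating-point round-off.
#'
#' @param mesh a `hex_mesh`
#' @param path output file path (.vtk)
#' @param title dataset title line
#' @return `path`, invisibly
#' @export
write_mesh <- function(mesh, path, title = "tractmorph hexahedral mesh") {
  stopifnot(inherits(mesh, "hex_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 9L * m), con)
  el0 <- mesh$elements - 1L
  writeLines(paste(8L, el0[, 1], el0[, 2], el0[, 3], el0[, 4],
                   el0[, 5], el0[, 6], el0[, 7], el0[, 8]), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(12L, m)), con)
  if (length(mesh$fields)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    writeLines(sprintf("FIELD elem_fields %d", length(mesh$fields)), con)
    for (nm in names(mesh$fields)) {
      writeLines(sprintf("%s 1 %d double", nm, m), con)
      writeLines(sprintf("%.17g", as.numeric(mesh$fields[[nm]])), con)
    }
  }
  invisible(path)
}

# token stream with line numbers for parse errors
vtk_tokens <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(lines, "[ \t]+")
  lens <- vapply(toks, length, 1L)
  tok <- unlist(toks, use.names = FALSE)
  line <- rep(seq_along(lines), lens)
  keep <- nzchar(tok)
  list(tok = tok[keep], line = line[keep], path = path)
}

vtk_error <- function(ts, pos, msg) {
  ln <- if (pos <= length(ts$line)) ts$line[pos] else NA_integer_
  stop(sprintf("malformed VTK file '%s' (line %s): %s", ts$path,
               ifelse(is.na(ln), "EOF", ln), msg), call. = FALSE)
}

vtk_take <- function(ts, pos, k) {
  if (pos + k - 1 > length(ts$tok)) vtk_error(ts, length(ts$tok), "unexpected end of file")
  ts$tok[pos:(pos + k - 1)]
}

vtk_numeric <- function(ts, pos, k, what) {
  v <- suppressWarnings(as.numeric(vtk_take(ts, pos, k)))
  if (anyNA(v)) vtk_error(ts, pos + which(is.na(v))[1] - 1, paste("non-numeric", what))
  v
}

#' Read a hexahedral mesh from a legacy VTK unstructured grid
#'
#' @param path input .vtk file (legacy ASCII)
#' @return a `hex_mesh` with any per-element fields attached
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("mesh file '%s' does not exist", path))
  header <- readLines(path, n = 1, warn = FALSE)
  if (!grepl("^# vtk DataFile", header))
    stop(sprintf("malformed VTK file '%s' (line 1): missing '# vtk DataFile' header", path))
  ts <- vtk_tokens(path)
  # skip the header comment and title: find the ASCII token
  pos <- which(ts$tok == "ASCII")[1]
  if (is.na(pos)) vtk_error(ts, 1, "only ASCII legacy VTK is supported")
  pos <- pos + 1
  if (!identical(vtk_take(ts, pos, 2), c("DATASET", "UNSTRUCTURED_GRID")))
    vtk_error(ts, pos, "expected DATASET UNSTRUCTURED_GRID")
  pos <- pos + 2
  if (vtk_take(ts, pos, 1) != "POINTS") vtk_error(ts, pos, "expected POINTS")
  n <- as.integer(ts$tok[pos + 1]); pos <- pos + 3  # skip dtype token
  if (is.na(n) || n < 1) vtk_error(ts, pos - 2, "bad POINTS count")
  nodes <- matrix(vtk_numeric(ts, pos, 3 * n, "point coordinate"),
                  ncol = 3, byrow = TRUE)
  pos <- pos + 3 * n
  if (vtk_take(ts, pos, 1) != "CELLS") vtk_error(ts, pos, "expected CELLS")
  m <- as.integer(ts$tok[pos + 1]); sz <- as.integer(ts$tok[pos + 2]); pos <- pos + 3
  if (is.na(m) || is.na(sz)) vtk_error(ts, pos - 2, "bad CELLS counts")
  cells <- as.integer(vtk_numeric(ts, pos, sz, "cell connectivity"))
  pos <- pos + sz
  if (sz != 9L * m || any(cells[seq(1, sz, by = 9)] != 8L))
    vtk_error(ts, pos - sz, "only 8-node hexahedral cells are supported")
  el <- matrix(cells, ncol = 9, byrow = TRUE)[, -1, drop = FALSE] + 1L
  if (vtk_take(ts, pos, 1) != "CELL_TYPES") vtk_error(ts, pos, "expected CELL_TYPES")
  pos <- pos + 2
  types <- as.integer(vtk_numeric(ts, pos, m, "cell type"))
  if (any(types != 12L))
    vtk_error(ts, pos + which(types != 12L)[1] - 1,
              sprintf("non-hexahedral cell type %d", types[types != 12L][1]))
  pos <- pos + m
  fields <- list()
  if (pos <= length(ts$tok) && ts$tok[pos] == "CELL_DATA") {
    pos <- pos + 2
    if (vtk_take(ts, pos, 1) != "FIELD") vtk_error(ts, pos, "expected FIELD after CELL_DATA")
    k <- as.integer(ts$tok[pos + 2]); pos <- pos + 3
    for (f in seq_len(k)) {
      hdr <- vtk_take(ts, pos, 3)
      nm <- hdr[1]; ncomp <- as.integer(hdr[2]); ntup <- as.integer(hdr[3])
      pos <- pos + 4  # skip dtype token
      if (is.na(ncomp) || ncomp != 1L || is.na(ntup) || ntup != m)
        vtk_error(ts, pos - 4, sprintf("field '%s' must be 1-component per-cell", nm))
      fields[[nm]] <- vtk_numeric(ts, pos, m, sprintf("field '%s' value", nm))
      pos <- pos + m
    }
  }
  hex_mesh(nodes, el, fields = fields)
}

# ---- point cloud IO: XYZ and ASCII PLY ----

#' Read / write point clouds
#'
#' `read_point_cloud` dispatches on extension: `.xyz`/`.txt` whitespace
#' tables, `.ply` ASCII PLY (vertex x/y/z properties).
#'
#' @param path file path
#' @return numeric matrix n x 3
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stop(sprintf("point cloud file '%s' does not exist", path))
  if (grepl("\\.ply$", path, ignore.case = TRUE)) read_ply(path) else read_xyz(path)
}

#' @rdname read_point_cloud
#' @export
read_xyz <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) < 3) stop(sprintf("XYZ file '%s' has fewer than 3 columns", path))
  as_points(m[, 1:3, drop = FALSE], path)
}

#' @rdname read_point_cloud
#' @param points numeric matrix n x 3
#' @export
write_xyz <- function(points, path) {
  points <- as_points(points)
  writeLines(sprintf("%.17g %.17g %.17g", points[, 1], points[, 2], points[, 3]),
             path)
  invisible(path)
}

#' @rdname read_point_cloud
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || lines[1] != "ply" || !grepl("^format ascii", lines[2]))
    stop(sprintf("'%s' is not an ASCII PLY file", path))
  endh <- which(lines == "end_header")[1]
  if (is.na(endh)) stop(sprintf("PLY file '%s' has no end_header", path))
  vline <- grep("^element vertex ", lines[1:endh], value = TRUE)
  if (!length(vline)) stop(sprintf("PLY file '%s' declares no vertex element", path))
  nv <- as.integer(sub("^element vertex ", "", vline[1]))
  props <- grep("^property ", lines[1:endh], value = TRUE)
  pnames <- vapply(strsplit(props, " "), function(x) x[3], "")
  ixyz <- match(c("x", "y", "z"), pnames)
  if (anyNA(ixyz)) stop(sprintf("PLY file '%s' lacks x/y/z vertex properties", path))
  body <- lines[(endh + 1):(endh + nv)]
  vals <- matrix(as.numeric(unlist(strsplit(trimws(body), "[ \t]+"))),
                 nrow = nv, byrow = TRUE)
  as_points(vals[, ixyz, drop = FALSE], path)
}

#' @rdname read_point_cloud
#' @export
write_ply <- function(points, path) {
  points <- as_points(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(points)),
               "property double x", "property double y", "property double z",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", points[, 1], points[, 2], points[, 3]),
             con)
  invisible(path)
}
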