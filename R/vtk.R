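## Minimal VTK unstructured-grid I/O (legacy ASCII .vtk and XML-ASCII .vtu)
## for tetrahedral meshes with named point/cell data arrays.

.fmt_num <- function(x) formatC(x, format = "g", digits = 12)

#' Write a mesh (and optional fields) as a legacy ASCII VTK file
#'
#' @param mesh a `bv_mesh`.
#' @param path output file path (`.vtk`).
#' @param point_data named list of per-vertex numeric vectors.
#' @param cell_data named list of per-cell vectors; integer vectors (such as
#'   the `"region"` labels) are written as int arrays.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$tetrahedra)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "perfusim unstructured grid", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(apply(mesh$vertices, 1, function(r) paste(.fmt_num(r), collapse = " ")))
  wl(sprintf("CELLS %d %d", m, 5L * m))
  wl(apply(mesh$tetrahedra - 1L, 1, function(r)
    paste(c(4L, r), collapse = " ")))
  wl(sprintf("CELL_TYPES %d", m))
  wl(as.character(rep(10L, m)))
  if (length(point_data)) {
    wl(sprintf("POINT_DATA %d", n))
    for (nm in names(point_data)) {
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      wl(.fmt_num(point_data[[nm]]))
    }
  }
  if (length(cell_data)) {
    wl(sprintf("CELL_DATA %d", m))
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (is.integer(v)) {
        wl(sprintf("SCALARS %s int 1", nm), "LOOKUP_TABLE default")
        wl(as.character(v))
      } else {
        wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
        wl(.fmt_num(v))
      }
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid written by [write_vtk()]
#'
#' @param path file path.
#' @return list with `mesh` (a `bv_mesh`), `point_data` and `cell_data`
#'   (named lists).
#' @export
read_vtk <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cl <- matrix(scan(text = lines[(ic + 1):(ic + m)], quiet = TRUE),
               ncol = 5, byrow = TRUE)
  stopifnot(all(cl[, 1] == 4))
  tets <- matrix(as.integer(cl[, 2:5] + 1L), ncol = 4)
  mesh <- .finalize_mesh(pts, tets)
  read_scalars <- function(start, count) {
    out <- list()
    i <- start
    while (i <= length(lines)) {
      if (grepl("^(POINT_DATA|CELL_DATA)", lines[i])) break
      if (grepl("^SCALARS", lines[i])) {
        tok <- strsplit(lines[i], "\\s+")[[1]]
        vals <- scan(text = lines[(i + 2):(i + 1 + count)], quiet = TRUE)
        out[[tok[2]]] <- if (tok[3] == "int") as.integer(vals) else vals
        i <- i + 2 + count
      } else i <- i + 1
    }
    out
  }
  pd <- list(); cd <- list()
  ipd <- grep("^POINT_DATA", lines)
  if (length(ipd)) pd <- read_scalars(ipd[1] + 1, n)
  icd <- grep("^CELL_DATA", lines)
  if (length(icd)) cd <- read_scalars(icd[1] + 1, m)
  list(mesh = mesh, point_data = pd, cell_data = cd)
}

#' Write a mesh and fields as an XML-ASCII `.vtu` file
#'
#' @inheritParams write_vtk
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$tetrahedra)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  da <- function(type, name, ncomp, values) {
    nm <- if (nzchar(name)) sprintf(' Name="%s"', name) else ""
    wl(sprintf('<DataArray type="%s"%s NumberOfComponents="%d" format="ascii">',
               type, nm, ncomp))
    wl(paste(values, collapse = " "))
    wl("</DataArray>")
  }
  wl('<?xml version="1.0"?>',
     '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
     "<UnstructuredGrid>",
     sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  wl("<Points>")
  da("Float64", "", 3L, .fmt_num(as.numeric(t(mesh$vertices))))
  wl("</Points>", "<Cells>")
  da("Int32", "connectivity", 1L, as.integer(t(mesh$tetrahedra)) - 1L)
  da("Int32", "offsets", 1L, seq_len(m) * 4L)
  da("UInt8", "types", 1L, rep(10L, m))
  wl("</Cells>")
  if (length(point_data)) {
    wl("<PointData>")
    for (nm in names(point_data)) {
      da("Float64", nm, 1L, .fmt_num(point_data[[nm]]))
    }
    wl("</PointData>")
  }
  if (length(cell_data)) {
    wl("<CellData>")
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (is.integer(v)) da("Int32", nm, 1L, v)
      else da("Float64", nm, 1L, .fmt_num(v))
    }
    wl("</CellData>")
  }
  wl("</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  invisible(path)
}

# volume-weighted cell -> node averaging (for exporting cell fields as
# point data)
cell_to_node <- function(mesh, cell_values) {
  n <- nrow(mesh$vertices)
  num <- numeric(n); den <- numeric(n)
  w <- mesh$cell_volumes
  for (a in 1:4) {
    s <- rowsum(cbind(cell_values * w, w), mesh$tetrahedra[, a])
    idx <- as.integer(rownames(s))
    num[idx] <- num[idx] + s[, 1]
    den[idx] <- den[idx] + s[, 2]
  }
  num / pmax(den, .Machine$double.xmin)
}
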