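#' Read a tetrahedral mesh
#'
#' Supported dialects: Gmsh v2.2 ASCII (`.msh`), legacy ASCII VTK unstructured
#' grid (`.vtk`) and a minimal Abaqus input subset (`.inp`: `*NODE`,
#' `*ELEMENT, TYPE=C3D4`, `*NSET`). Fixed-boundary node sets travel as type-15
#' point elements with physical tag 1 (Gmsh), a `fixed` point scalar (VTK) or
#' `*NSET, NSET=FIXED` (Abaqus); the expander center is carried only by the
#' Abaqus dialect (`*NSET, NSET=CENTER`) and is otherwise supplied via
#' configuration. Abaqus node numbering is 1-based and VTK 0-based on file;
#' both are converted at the parser. Negative-volume tetrahedra are reoriented
#' with a warning; degenerate ones are an error naming the element.
#'
#' @param path File path.
#' @param format One of `"gmsh"`, `"vtk"`, `"abaqus_inp"`; default inferred
#'   from the extension (.msh/.vtk/.inp).
#' @return A [scalp_mesh()]. VTK point/cell data arrays, if present, are
#'   attached as attributes `point_data` / `cell_data`.
#' @export
read_mesh <- function(path, format = c("auto", "gmsh", "vtk", "abaqus_inp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     msh = "gmsh", vtk = "vtk", inp = "abaqus_inp",
                     stop("unknown mesh format for '", path,
                          "'; pass format= explicitly"))
  }
  switch(format,
         gmsh = read_gmsh(path),
         vtk = read_vtk(path),
         abaqus_inp = read_abaqus_inp(path))
}

#' Write a tetrahedral mesh
#'
#' Counterpart of [read_mesh()]; round trips are lossless for coordinates and
#' connectivity in all three dialects.
#'
#' @param mesh A [scalp_mesh()].
#' @param path Output file path.
#' @param format One of `"gmsh"`, `"vtk"`, `"abaqus_inp"` (default from
#'   extension).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "gmsh", "vtk", "abaqus_inp")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     msh = "gmsh", vtk = "vtk", inp = "abaqus_inp",
                     stop("unknown mesh format for '", path, "'"))
  }
  switch(format,
         gmsh = write_gmsh(mesh, path),
         vtk = write_vtk_mesh(mesh, path),
         abaqus_inp = write_abaqus_inp(mesh, path))
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

# ---- Gmsh v2.2 ASCII ----------------------------------------------------------

write_gmsh <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
                   fmt_num(mesh$nodes[, 3])), con)
  writeLines("$EndNodes", con)
  nf <- length(mesh$fixed_nodes)
  nt <- nrow(mesh$tets)
  writeLines(c("$Elements", as.character(nf + nt)), con)
  id <- 0L
  if (nf) {
    writeLines(paste(seq_len(nf), 15, 2, 1, 1, mesh$fixed_nodes), con)
    id <- nf
  }
  writeLines(paste(id + seq_len(nt), 4, 2, 2, 1,
                   mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                   mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
}

read_gmsh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- function(name) {
    a <- match(paste0("$", name), lines)
    b <- match(paste0("$End", name), lines)
    if (is.na(a) || is.na(b)) stop("malformed gmsh file: missing $", name)
    lines[(a + 1):(b - 1)]
  }
  fmt <- strsplit(trimws(sec("MeshFormat")[1]), "\\s+")[[1]]
  if (!startsWith(fmt[1], "2")) {
    stop("unsupported gmsh version ", fmt[1], " (need v2 ASCII)")
  }
  nl <- sec("Nodes")
  n <- as.integer(nl[1])
  ntab <- do.call(rbind, lapply(strsplit(trimws(nl[1 + seq_len(n)]), "\\s+"),
                                as.numeric))
  ids <- as.integer(ntab[, 1])
  nodes <- ntab[, 2:4, drop = FALSE]
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  el <- sec("Elements")
  m <- as.integer(el[1])
  fixed <- integer(0)
  tets <- list()
  for (r in seq_len(m)) {
    f <- as.integer(strsplit(trimws(el[1 + r]), "\\s+")[[1]])
    type <- f[2]; ntags <- f[3]
    conn <- f[(4 + ntags):length(f)]
    if (type == 15L) {
      if (ntags >= 1 && f[4] == 1L) fixed <- c(fixed, remap[conn[1]])
    } else if (type == 4L) {
      if (length(conn) != 4) {
        stop("malformed element ", f[1], ": tetrahedron needs 4 nodes, got ",
             length(conn))
      }
      tets[[length(tets) + 1]] <- remap[conn]
    } else {
      stop("unsupported gmsh element type ", type, " (element ", f[1], ")")
    }
  }
  if (!length(tets)) stop("gmsh file contains no tetrahedra")
  scalp_mesh(nodes, do.call(rbind, tets), fixed_nodes = fixed)
}

# ---- legacy VTK ASCII unstructured grid ---------------------------------------

write_vtk_mesh <- function(mesh, path, point_data = NULL, cell_data = NULL,
                           title = "scalpexp mesh") {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(paste(fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
                   fmt_num(mesh$nodes[, 3])), con)
  writeLines(paste("CELLS", m, 5 * m), con)
  writeLines(paste(4, mesh$tets[, 1] - 1, mesh$tets[, 2] - 1,
                   mesh$tets[, 3] - 1, mesh$tets[, 4] - 1), con)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(rep("10", m), con)

  writeLines(paste("POINT_DATA", n), con)
  fixed <- integer(n); fixed[mesh$fixed_nodes] <- 1L
  writeLines(c("SCALARS fixed int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(fixed), con)
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    if (is.matrix(v) && ncol(v) == 3) {
      writeLines(paste("VECTORS", nm, "double"), con)
      writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), con)
    } else {
      writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"), con)
      writeLines(fmt_num(v), con)
    }
  }
  if (length(cell_data)) {
    writeLines(paste("CELL_DATA", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"), con)
      writeLines(fmt_num(cell_data[[nm]]), con)
    }
  }
}

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  if (!grepl("ASCII", paste(lines[1:4], collapse = " "))) {
    stop("only ASCII legacy VTK is supported")
  }
  i <- grep("^POINTS", lines)[1]
  if (is.na(i)) stop("malformed VTK: no POINTS section")
  n <- as.integer(toks(lines[i])[2])
  vals <- numeric(0); r <- i + 1L
  while (length(vals) < 3 * n) {          # coordinates may wrap across lines
    vals <- c(vals, as.numeric(toks(lines[r]))); r <- r + 1L
  }
  pts <- matrix(vals[1:(3 * n)], ncol = 3, byrow = TRUE)

  j <- grep("^CELLS", lines)[1]
  if (is.na(j)) stop("malformed VTK: no CELLS section")
  m <- as.integer(toks(lines[j])[2])
  cl <- lapply(strsplit(trimws(lines[j + seq_len(m)]), "\\s+"), as.integer)
  sizes <- vapply(cl, function(x) x[1], 0L)
  if (any(sizes != 4L)) {
    bad <- which(sizes != 4L)[1]
    stop("malformed element ", bad, ": cell with ", sizes[bad],
         " nodes is not a tetrahedron")
  }
  tets <- do.call(rbind, lapply(cl, function(x) x[2:5] + 1L))
  k <- grep("^CELL_TYPES", lines)[1]
  ct <- as.integer(unlist(strsplit(trimws(
    lines[(k + 1):(k + m)]), "\\s+")))[1:m]
  if (any(ct != 10L)) stop("unsupported VTK cell type ", ct[ct != 10][1])

  fixed <- integer(0)
  point_data <- list()
  pd <- grep("^POINT_DATA", lines)[1]
  if (!is.na(pd)) {
    r <- pd + 1L
    while (r <= length(lines)) {
      t_ <- toks(lines[r])
      if (!length(t_) || t_[1] == "CELL_DATA") break
      if (t_[1] == "SCALARS") {
        nm <- t_[2]
        vals <- numeric(0); rr <- r + 2L
        while (length(vals) < n) {
          vals <- c(vals, as.numeric(toks(lines[rr]))); rr <- rr + 1L
        }
        if (nm == "fixed") fixed <- which(vals != 0)
        else point_data[[nm]] <- vals[1:n]
        r <- rr
      } else if (t_[1] == "VECTORS") {
        nm <- t_[2]
        vals <- numeric(0); rr <- r + 1L
        while (length(vals) < 3 * n) {
          vals <- c(vals, as.numeric(toks(lines[rr]))); rr <- rr + 1L
        }
        point_data[[nm]] <- matrix(vals[1:(3 * n)], ncol = 3, byrow = TRUE)
        r <- rr
      } else {
        r <- r + 1L
      }
    }
  }
  mesh <- scalp_mesh(pts, tets, fixed_nodes = fixed)
  if (length(point_data)) attr(mesh, "point_data") <- point_data
  mesh
}

# ---- minimal Abaqus .inp subset ----------------------------------------------

write_abaqus_inp <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines("scalpexp tetrahedral mesh", con)
  writeLines("*NODE", con)
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
                   fmt_num(mesh$nodes[, 3]), sep = ", "), con)
  writeLines("*ELEMENT, TYPE=C3D4", con)
  writeLines(paste(seq_len(nrow(mesh$tets)), mesh$tets[, 1], mesh$tets[, 2],
                   mesh$tets[, 3], mesh$tets[, 4], sep = ", "), con)
  if (length(mesh$fixed_nodes)) {
    writeLines("*NSET, NSET=FIXED", con)
    sets <- split(mesh$fixed_nodes,
                  ceiling(seq_along(mesh$fixed_nodes) / 16))
    writeLines(vapply(sets, paste, "", collapse = ", "), con)
  }
  if (!is.null(mesh$center_point)) {
    d2 <- rowSums(sweep(mesh$nodes, 2, mesh$center_point)^2)
    writeLines("*NSET, NSET=CENTER", con)
    writeLines(as.character(which.min(d2)), con)
  }
}

read_abaqus_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\*\\*", lines)]            # comments
  hdr <- grep("^\\*", lines)
  nodes <- NULL; tets <- NULL; fixed <- integer(0); center <- NULL
  for (h in seq_along(hdr)) {
    from <- hdr[h] + 1L
    to <- if (h < length(hdr)) hdr[h + 1L] - 1L else length(lines)
    if (to < from) next
    head_ <- toupper(gsub("\\s", "", lines[hdr[h]]))
    if (!startsWith(head_, "*NODE") && !startsWith(head_, "*ELEMENT") &&
        !startsWith(head_, "*NSET")) next
    body <- trimws(lines[from:to])
    body <- body[nzchar(body)]
    fields <- lapply(strsplit(body, ","), function(x) as.numeric(trimws(x)))
    if (startsWith(head_, "*NODE")) {
      tab <- do.call(rbind, fields)
      nodes <- tab[order(tab[, 1]), 2:4, drop = FALSE]
      if (!all(tab[order(tab[, 1]), 1] == seq_len(nrow(tab)))) {
        stop("abaqus reader requires contiguous 1-based node ids")
      }
    } else if (startsWith(head_, "*ELEMENT")) {
      if (!grepl("TYPE=C3D4", head_)) {
        stop("unsupported abaqus element type in: ", lines[hdr[h]])
      }
      tab <- do.call(rbind, fields)
      if (ncol(tab) != 5) {
        stop("malformed element ", tab[1, 1], ": C3D4 needs 4 nodes, got ",
             ncol(tab) - 1)
      }
      tets <- matrix(as.integer(tab[, 2:5]), ncol = 4)
    } else if (startsWith(head_, "*NSET")) {
      ids <- as.integer(unlist(fields))
      ids <- ids[!is.na(ids)]
      if (grepl("NSET=FIXED", head_)) fixed <- ids
      if (grepl("NSET=CENTER", head_)) center <- ids[1]
    }
  }
  if (is.null(nodes) || is.null(tets)) {
    stop("malformed abaqus file: need *NODE and *ELEMENT sections")
  }
  scalp_mesh(nodes, tets, fixed_nodes = fixed,
             center_point = if (!is.null(center)) nodes[center, ] else NULL)
}

#' Export a deformed state as a legacy VTK file
#'
#' Writes the reference mesh with the displacement field as a point-data
#' vector array plus optional per-node or per-element scalar fields (e.g.
#' element strain or stress measures), suitable for ParaView-style rendering
#' of the expansion steps.
#'
#' @param state A [deformed_state()].
#' @param mesh The corresponding [scalp_mesh()].
#' @param path Output `.vtk` path.
#' @param fields Named list of extra fields: length-n vectors or n x 3
#'   matrices become point data, length-m vectors cell data.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(state, mesh, path, fields = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  point_data <- list(displacement = disp_matrix(state$u, n))
  cell_data <- list()
  for (nm in names(fields)) {
    v <- fields[[nm]]
    len <- if (is.matrix(v)) nrow(v) else length(v)
    if (len == n) point_data[[nm]] <- v
    else if (len == m) cell_data[[nm]] <- v
    else stop("field '", nm, "' matches neither node nor element count")
  }
  write_vtk_mesh(mesh, path, point_data = point_data, cell_data = cell_data,
                 title = paste("scalpexp step", state$pseudo_time))
  invisible(path)
}
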