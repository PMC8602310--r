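# Mesh exchange. Two text formats are supported:
#   * VTK XML unstructured grid (.vtu), ASCII, with the tissue label stored
#     as an integer cell-data field "tissue" (artery=1, mixed=2, fibrous=3,
#     lipid=4, calcium=5);
#   * Gmsh MSH 4.1, with one discrete entity per run of equally-labeled
#     elements and the tissue code as the entity's physical tag (a subset of
#     the format sufficient for lossless round-trips of our meshes).
# Coordinates are written with 17 significant digits, so write -> read is the
# identity on IEEE doubles.

fmt_num <- function(x) sprintf("%.17g", x)

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("vtu", "msh")) return(ext)
  stop("unknown mesh format for '", path, "' (supported: .vtu, .msh)")
}

#' Read and write labeled vessel meshes
#'
#' @param mesh a `labeled_mesh`.
#' @param path file path; the format is deduced from the extension unless
#'   given explicitly.
#' @param format `"vtu"` (VTK XML unstructured grid) or `"msh"`
#'   (Gmsh MSH 4.1).
#' @return `read_mesh()` returns a `labeled_mesh`; `write_mesh()` returns
#'   `path` invisibly.
#' @export
write_mesh <- function(mesh, path, format = guess_format(path)) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  format <- match.arg(format, c("vtu", "msh"))
  if (format == "vtu") write_vtu(mesh, path) else write_msh(mesh, path)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = guess_format(path)) {
  format <- match.arg(format, c("vtu", "msh"))
  if (format == "vtu") read_vtu(path) else read_msh(path)
}

# ---- VTU -------------------------------------------------------------------

vtk_cell_type <- function(mesh) if (mesh$dim == 2L) 22L else 24L

write_vtu <- function(mesh, path) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  nen <- ncol(mesh$elements)
  pts <- mesh$nodes
  if (mesh$dim == 2L) pts <- cbind(pts, 0)
  con <- t(mesh$elements) - 1L
  codes <- tissue_classes()[as.character(mesh$labels)]
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="1.0" byte_order="LittleEndian">',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m),
    '      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste(fmt_num(t(pts)), collapse = " "),
    '        </DataArray>',
    '      </Points>',
    '      <Cells>',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    paste(as.integer(con), collapse = " "),
    '        </DataArray>',
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    paste(seq_len(m) * nen, collapse = " "),
    '        </DataArray>',
    '        <DataArray type="UInt8" Name="types" format="ascii">',
    paste(rep(vtk_cell_type(mesh), m), collapse = " "),
    '        </DataArray>',
    '      </Cells>',
    '      <CellData Scalars="tissue">',
    '        <DataArray type="Int32" Name="tissue" format="ascii">',
    paste(codes, collapse = " "),
    '        </DataArray>',
    '      </CellData>',
    '    </Piece>',
    '  </UnstructuredGrid>',
    '</VTKFile>'
  )
  writeLines(lines, path)
}

read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (is.na(xml2::xml_attr(piece, "NumberOfPoints"))) stop("malformed VTU: no Piece")
  get_arr <- function(xpath) {
    nd <- xml2::xml_find_first(doc, xpath)
    if (inherits(nd, "xml_missing")) return(NULL)
    scan(text = xml2::xml_text(nd), quiet = TRUE)
  }
  pts <- get_arr(".//Points/DataArray")
  con <- get_arr(".//Cells/DataArray[@Name='connectivity']")
  off <- get_arr(".//Cells/DataArray[@Name='offsets']")
  typ <- get_arr(".//Cells/DataArray[@Name='types']")
  lab <- get_arr(".//CellData/DataArray[@Name='tissue']")
  if (is.null(lab)) stop("VTU file has no 'tissue' cell-data field")
  pts <- matrix(pts, ncol = 3L, byrow = TRUE)
  utyp <- unique(typ)
  if (length(utyp) != 1L || !utyp %in% c(22, 24)) {
    stop("unsupported VTK cell type(s): ", paste(utyp, collapse = ", "),
         " (need 22 or 24)")
  }
  nen <- if (utyp == 22) 6L else 10L
  if (any(diff(c(0, off)) != nen)) stop("mixed element sizes in VTU file")
  elems <- matrix(as.integer(con) + 1L, ncol = nen, byrow = TRUE)
  dim <- if (utyp == 22) 2L else 3L
  nodes <- pts[, seq_len(dim), drop = FALSE]
  labeled_mesh(nodes, elems, as_tissue(as.integer(lab)))
}

# ---- Gmsh MSH 4.1 ----------------------------------------------------------

gmsh_elem_type <- function(mesh) if (mesh$dim == 2L) 9L else 11L
# VTK and Gmsh quadratic-tet mid-side orders differ in the last two nodes
gmsh_perm <- function(nen) if (nen == 10L) c(1:8, 10L, 9L) else seq_len(nen)

write_msh <- function(mesh, path) {
  n <- nrow(mesh$nodes)
  nen <- ncol(mesh$elements)
  pts <- mesh$nodes
  if (mesh$dim == 2L) pts <- cbind(pts, 0)
  codes <- as.integer(tissue_classes()[as.character(mesh$labels)])
  runs <- rle(codes)
  nblk <- length(runs$lengths)
  bb <- apply(pts, 2, range)
  ent_dim <- if (mesh$dim == 2L) 2L else 3L
  con <- c("$MeshFormat", "4.1 0 8", "$EndMeshFormat", "$Entities")
  counts <- c(0L, 0L, 0L, 0L)
  counts[ent_dim + 1L] <- nblk
  con <- c(con, paste(counts, collapse = " "))
  for (b in seq_len(nblk)) {
    con <- c(con, paste(c(b, fmt_num(bb[1, ]), fmt_num(bb[2, ]), 1L,
                          runs$values[b]), collapse = " "))
  }
  con <- c(con, "$EndEntities", "$Nodes",
           paste(1L, n, 1L, n), paste(ent_dim, 1L, 0L, n),
           as.character(seq_len(n)),
           apply(pts, 1, function(r) paste(fmt_num(r), collapse = " ")),
           "$EndNodes", "$Elements",
           paste(nblk, nrow(mesh$elements), 1L, nrow(mesh$elements)))
  perm <- gmsh_perm(nen)
  etype <- gmsh_elem_type(mesh)
  e0 <- 0L
  for (b in seq_len(nblk)) {
    len <- runs$lengths[b]
    con <- c(con, paste(ent_dim, b, etype, len))
    idx <- e0 + seq_len(len)
    rows <- cbind(idx, mesh$elements[idx, perm, drop = FALSE])
    con <- c(con, apply(rows, 1, paste, collapse = " "))
    e0 <- e0 + len
  }
  con <- c(con, "$EndElements")
  writeLines(con, path)
}

read_msh <- function(path) {
  ln <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), ln)
    i1 <- match(paste0("$End", name), ln)
    if (is.na(i0) || is.na(i1)) stop("MSH file missing $", name, " section")
    ln[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(sec("MeshFormat")[1], " ")[[1]]
  if (fmt[1] != "4.1") stop("unsupported MSH version ", fmt[1], " (need 4.1)")

  ent <- sec("Entities")
  counts <- as.integer(strsplit(ent[1], "\\s+")[[1]])
  phys <- list()  # entity tag -> physical (tissue) tag, per dimension
  row <- 2L
  for (d in 0:3) {
    for (k in seq_len(counts[d + 1L])) {
      v <- as.numeric(strsplit(ent[row], "\\s+")[[1]])
      # point entities: tag x y z numPhys ...; higher-dim: tag bbox(6) numPhys ...
      np_at <- if (d == 0L) 5L else 8L
      npt <- v[np_at]
      key <- paste(d, as.integer(v[1]), sep = ":")
      phys[[key]] <- if (npt >= 1) as.integer(v[np_at + 1L]) else NA_integer_
      row <- row + 1L
    }
  }

  nod <- sec("Nodes")
  hdr <- as.integer(strsplit(nod[1], "\\s+")[[1]])
  nnode <- hdr[2]
  pts <- matrix(NA_real_, nnode, 3L)
  row <- 2L
  for (b in seq_len(hdr[1])) {
    bh <- as.integer(strsplit(nod[row], "\\s+")[[1]])
    nb <- bh[4]
    tags <- as.integer(nod[row + seq_len(nb)])
    coords <- t(vapply(nod[row + nb + seq_len(nb)],
                       function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]]),
                       numeric(3), USE.NAMES = FALSE))
    pts[tags, ] <- coords
    row <- row + 1L + 2L * nb
  }

  elt <- sec("Elements")
  hdr <- as.integer(strsplit(elt[1], "\\s+")[[1]])
  nel <- hdr[2]
  elems <- NULL
  labs <- integer(nel)
  etypes <- integer(0)
  row <- 2L
  for (b in seq_len(hdr[1])) {
    bh <- as.integer(strsplit(elt[row], "\\s+")[[1]])
    d <- bh[1]; tag <- bh[2]; etype <- bh[3]; nb <- bh[4]
    etypes <- union(etypes, etype)
    dat <- t(vapply(elt[row + seq_len(nb)],
                    function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]]),
                    numeric(1L + if (etype == 9L) 6L else 10L),
                    USE.NAMES = FALSE))
    ids <- as.integer(dat[, 1])
    lab <- phys[[paste(d, tag, sep = ":")]]
    if (is.null(lab) || is.na(lab)) {
      stop("MSH element block on entity ", tag,
           " has no physical (tissue) tag")
    }
    labs[ids] <- lab
    conn <- matrix(as.integer(dat[, -1, drop = FALSE]), nrow = nb)
    if (is.null(elems)) elems <- matrix(NA_integer_, nel, ncol(conn))
    elems[ids, ] <- conn
    row <- row + 1L + nb
  }
  if (length(etypes) != 1L || !etypes %in% c(9L, 11L)) {
    stop("unsupported Gmsh element type(s): ", paste(etypes, collapse = ", "))
  }
  nen <- ncol(elems)
  elems <- elems[, order(gmsh_perm(nen)), drop = FALSE]  # back to VTK order
  dim <- if (etypes == 9L) 2L else 3L
  labeled_mesh(pts[, seq_len(dim), drop = FALSE], elems, as_tissue(labs))
}
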