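# Mesh file I/O: Gmsh MSH v4.1 (ASCII) and legacy VTK (ASCII), with region
# labels and fiber directions carried as element data so that a written mesh
# round-trips losslessly. Node/element tags are 1-based on disk in both
# formats' conventions (legacy VTK connectivity is 0-based).

.region_tag <- c(AF = 1L, NP = 2L)

#' Write a tetrahedral mesh to disk
#'
#' Supports Gmsh MSH v4.1 ASCII (`.msh`) and legacy VTK ASCII (`.vtk`).
#' Region labels are stored as volume-entity tags (MSH) or an integer cell
#' field `region` (VTK); fiber directions travel as 3-component element/cell
#' data `M1`, `M2` (zero vectors for NP elements).
#'
#' @param mesh An `ivd_mesh`.
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         msh = .write_msh(mesh, path),
         vtk = .write_vtk(mesh, path),
         stop("unsupported mesh format: .", ext, " (use .msh or .vtk)"))
  invisible(path)
}

#' Read a tetrahedral mesh
#'
#' Reads meshes written by [write_mesh()] (and plain tetrahedral meshes from
#' other tools in the same formats). Files containing non-tetrahedral volume
#' elements are rejected.
#'
#' @param path Mesh file (`.msh` or `.vtk`).
#' @return An `ivd_mesh` (without a generating `spec`; `l_c` and volumes are
#'   recomputed, fiber vectors and regions restored if present).
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         msh = .read_msh(path),
         vtk = .read_vtk(path),
         stop("unsupported mesh format: .", ext))
}

.finish_mesh <- function(nodes, tets, region, M1, M2, interface = NULL) {
  storage.mode(tets) <- "integer"
  vol <- .tet_volumes(nodes, tets)
  if (any(vol <= 0)) stop("mesh contains non-positively-oriented tetrahedra")
  if (is.null(interface)) {
    # fall back to the extreme-z planes (exact only for unwedged discs)
    zr <- range(nodes[, 3])
    interface <- integer(nrow(nodes))
    interface[abs(nodes[, 3] - zr[2]) < 1e-9] <- 1L
    interface[abs(nodes[, 3] - zr[1]) < 1e-9] <- 2L
  }
  mesh <- structure(
    list(nodes = nodes, tets = tets, region = region, M1 = M1, M2 = M2,
         l_c = rep(NA_real_, nrow(tets)), volume = vol,
         cranial_nodes = which(interface == 1L),
         caudal_nodes = which(interface == 2L),
         basis = diag(3), spec = NULL, seed = NA_integer_),
    class = "ivd_mesh")
  mesh$l_c <- characteristic_length(mesh)
  mesh
}

.interface_code <- function(mesh) {
  code <- integer(nrow(mesh$nodes))
  code[mesh$cranial_nodes] <- 1L
  code[mesh$caudal_nodes] <- 2L
  code
}

.fiber_or_zero <- function(M) {
  out <- M
  out[is.na(out)] <- 0
  out
}

.write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  regions <- c("AF", "NP")
  wl <- function(...) writeLines(paste0(...), con)
  wl("$MeshFormat")
  wl("4.1 0 8")
  wl("$EndMeshFormat")
  bb <- apply(mesh$nodes, 2, range)
  wl("$Entities")
  wl("0 0 0 2")
  for (rt in .region_tag[regions])
    wl(paste(rt, paste(sprintf("%.16g", c(bb[1, ], bb[2, ])), collapse = " "),
             "0", "0"))
  wl("$EndEntities")
  wl("$Nodes")
  wl(paste("1", n, "1", n))
  wl(paste("3 1 0", n))
  writeLines(as.character(seq_len(n)), con)
  writeLines(sprintf("%.16g %.16g %.16g",
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  wl("$EndNodes")
  wl("$Elements")
  ne <- nrow(mesh$tets)
  wl(paste("2", ne, "1", ne))
  eid <- seq_len(ne)
  for (rg in regions) {
    sel <- which(mesh$region == rg)
    wl(paste("3", .region_tag[[rg]], "4", length(sel)))
    writeLines(sprintf("%d %d %d %d %d", eid[sel],
                       mesh$tets[sel, 1], mesh$tets[sel, 2],
                       mesh$tets[sel, 3], mesh$tets[sel, 4]), con)
  }
  wl("$EndElements")
  for (nm in c("M1", "M2")) {
    M <- .fiber_or_zero(mesh[[nm]])
    wl("$ElementData")
    wl("1"); wl(paste0("\"", nm, "\""))
    wl("1"); wl("0")
    wl("3"); wl("0"); wl("3"); wl(as.character(ne))
    writeLines(sprintf("%d %.16g %.16g %.16g", eid, M[, 1], M[, 2], M[, 3]), con)
    wl("$EndElementData")
  }
  # interface node sets (1 = cranial, 2 = caudal) as nodal data
  code <- .interface_code(mesh)
  wl("$NodeData")
  wl("1"); wl("\"interface\"")
  wl("1"); wl("0")
  wl("3"); wl("0"); wl("1"); wl(as.character(n))
  writeLines(sprintf("%d %d", seq_len(n), code), con)
  wl("$EndNodeData")
  invisible(path)
}

.read_msh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- function(name) {
    a <- which(lines == paste0("$", name))
    b <- which(lines == paste0("$End", name))
    if (length(a) != 1 || length(b) != 1) stop("malformed MSH: missing $", name)
    lines[(a + 1):(b - 1)]
  }
  fmt <- strsplit(sec("MeshFormat")[1], "\\s+")[[1]]
  if (!startsWith(fmt[1], "4")) stop("unsupported MSH version: ", fmt[1])
  if (fmt[2] != "0") stop("binary MSH not supported")

  nl <- sec("Nodes")
  hdr <- as.numeric(strsplit(nl[1], "\\s+")[[1]])
  nblocks <- hdr[1]; nnode <- hdr[2]
  nodes <- matrix(NA_real_, nnode, 3)
  i <- 2
  for (b in seq_len(nblocks)) {
    bh <- as.numeric(strsplit(nl[i], "\\s+")[[1]])
    nb <- bh[4]
    tags <- as.integer(nl[i + seq_len(nb)])
    xyz <- do.call(rbind, strsplit(nl[i + nb + seq_len(nb)], "\\s+"))
    nodes[tags, ] <- matrix(as.numeric(xyz[, 1:3]), ncol = 3)
    i <- i + 1 + 2 * nb
  }

  el <- sec("Elements")
  hdr <- as.numeric(strsplit(el[1], "\\s+")[[1]])
  nblocks <- hdr[1]; nel <- hdr[2]
  tets <- matrix(NA_integer_, nel, 4)
  region <- character(nel)
  elem_tag <- integer(nel)
  i <- 2; pos <- 0L
  for (b in seq_len(nblocks)) {
    bh <- as.numeric(strsplit(el[i], "\\s+")[[1]])
    dim_ <- bh[1]; etag <- bh[2]; etype <- bh[3]; nb <- bh[4]
    if (dim_ == 3 && etype != 4)
      stop("unsupported element type ", etype, " (only 4-node tetrahedra)")
    rows <- do.call(rbind, strsplit(el[i + seq_len(nb)], "\\s+"))
    if (dim_ == 3) {
      sel <- pos + seq_len(nb)
      elem_tag[sel] <- as.integer(rows[, 1])
      tets[sel, ] <- matrix(as.integer(rows[, 2:5]), ncol = 4)
      region[sel] <- names(.region_tag)[match(etag, .region_tag)]
      pos <- pos + nb
    }
    i <- i + 1 + nb
  }
  tets <- tets[seq_len(pos), , drop = FALSE]
  region <- region[seq_len(pos)]
  elem_tag <- elem_tag[seq_len(pos)]
  region[is.na(region)] <- "AF"
  # restore on-disk element tags as element order (blocks are per region)
  ord <- order(elem_tag)
  tets <- tets[ord, , drop = FALSE]
  region <- region[ord]
  elem_tag <- elem_tag[ord]

  E <- nrow(tets)
  M1 <- matrix(NA_real_, E, 3); M2 <- matrix(NA_real_, E, 3)
  starts <- which(lines == "$ElementData")
  for (a in starts) {
    b <- which(lines == "$EndElementData"); b <- min(b[b > a])
    blk <- lines[(a + 1):(b - 1)]
    nstr <- as.integer(blk[1])
    name <- gsub('"', "", blk[2])
    nreal <- as.integer(blk[2 + nstr])
    nint <- as.integer(blk[3 + nstr + nreal])
    ints <- as.integer(blk[3 + nstr + nreal + seq_len(nint)])
    nrec <- ints[3]
    rows <- do.call(rbind, strsplit(blk[3 + nstr + nreal + nint + seq_len(nrec)], "\\s+"))
    if (name %in% c("M1", "M2")) {
      tgt <- match(as.integer(rows[, 1]), elem_tag)
      vals <- matrix(as.numeric(rows[, 2:4]), ncol = 3)
      if (name == "M1") M1[tgt, ] <- vals else M2[tgt, ] <- vals
    }
  }
  zero1 <- rowSums(abs(M1)) < 1e-14 | is.na(rowSums(M1))
  zero2 <- rowSums(abs(M2)) < 1e-14 | is.na(rowSums(M2))
  M1[zero1, ] <- NA_real_; M2[zero2, ] <- NA_real_

  interface <- NULL
  nstarts <- which(lines == "$NodeData")
  for (a in nstarts) {
    b <- which(lines == "$EndNodeData"); b <- min(b[b > a])
    blk <- lines[(a + 1):(b - 1)]
    nstr <- as.integer(blk[1])
    name <- gsub('"', "", blk[2])
    if (name != "interface") next
    nreal <- as.integer(blk[2 + nstr])
    nint <- as.integer(blk[3 + nstr + nreal])
    ints <- as.integer(blk[3 + nstr + nreal + seq_len(nint)])
    rows <- do.call(rbind, strsplit(blk[3 + nstr + nreal + nint + seq_len(ints[3])], "\\s+"))
    interface <- integer(nrow(nodes))
    interface[as.integer(rows[, 1])] <- as.integer(rows[, 2])
  }
  .finish_mesh(nodes, tets, region, M1, M2, interface)
}

.write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  n <- nrow(mesh$nodes); ne <- nrow(mesh$tets)
  wl("# vtk DataFile Version 3.0")
  wl("ivdfem tetrahedral mesh (mm)")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(paste("POINTS", n, "double"))
  writeLines(sprintf("%.16g %.16g %.16g",
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  wl(paste("CELLS", ne, 5 * ne))
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  wl(paste("CELL_TYPES", ne))
  writeLines(rep("10", ne), con)
  wl(paste("CELL_DATA", ne))
  wl("SCALARS region int 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(.region_tag[mesh$region]), con)
  for (nm in c("M1", "M2")) {
    M <- .fiber_or_zero(mesh[[nm]])
    wl(paste("VECTORS", nm, "double"))
    writeLines(sprintf("%.16g %.16g %.16g", M[, 1], M[, 2], M[, 3]), con)
  }
  wl(paste("POINT_DATA", n))
  wl("SCALARS interface int 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(.interface_code(mesh)), con)
  invisible(path)
}

.read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^ASCII", lines))) stop("only ASCII legacy VTK is supported")
  tok <- function(pat) grep(pat, lines)[1]
  ip <- tok("^POINTS")
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- do.call(rbind, strsplit(trimws(lines[ip + seq_len(n)]), "\\s+"))
  nodes <- matrix(as.numeric(pts[, 1:3]), ncol = 3)
  ic <- tok("^CELLS")
  ne <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cl <- do.call(rbind, strsplit(trimws(lines[ic + seq_len(ne)]), "\\s+"))
  if (any(cl[, 1] != "4")) stop("unsupported element with != 4 nodes in VTK file")
  tets <- matrix(as.integer(cl[, 2:5]), ncol = 4) + 1L
  it <- tok("^CELL_TYPES")
  ct <- as.integer(lines[it + seq_len(ne)])
  if (any(ct != 10L)) stop("unsupported VTK cell type(s): ", paste(unique(ct[ct != 10L]), collapse = ", "))
  region <- rep("AF", ne)
  ir <- grep("^SCALARS region", lines)
  if (length(ir) == 1) {
    vals <- as.integer(lines[ir + 1L + seq_len(ne)])
    region <- names(.region_tag)[match(vals, .region_tag)]
  }
  M1 <- matrix(NA_real_, ne, 3); M2 <- matrix(NA_real_, ne, 3)
  for (nm in c("M1", "M2")) {
    iv <- grep(paste0("^VECTORS ", nm, " "), lines)
    if (length(iv) == 1) {
      rows <- do.call(rbind, strsplit(trimws(lines[iv + seq_len(ne)]), "\\s+"))
      M <- matrix(as.numeric(rows[, 1:3]), ncol = 3)
      M[rowSums(abs(M)) < 1e-14, ] <- NA_real_
      if (nm == "M1") M1 <- M else M2 <- M
    }
  }
  interface <- NULL
  ii <- grep("^SCALARS interface", lines)
  if (length(ii) == 1)
    interface <- as.integer(lines[ii + 1L + seq_len(n)])
  .finish_mesh(nodes, tets, region, M1, M2, interface)
}
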