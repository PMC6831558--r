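#' @importFrom stats median quantile runif sd setNames
NULL

REGION_LABELS <- c("cortical", "trabecular", "tooth", "pdl", "screw")

#' Construct a tetrahedral mesh
#'
#' A `tet_mesh` is the container every other stage of the pipeline operates
#' on: node coordinates in millimetres, 4-node tetrahedra, a tissue-region
#' label per element (`cortical`, `trabecular`, `tooth`, `pdl`, `screw`),
#' and named node/element sets used for constraints, muscle insertions and
#' region summaries.
#'
#' Elements are required to have strictly positive signed volume under the
#' stored node ordering. If `fix_orientation = TRUE` (the default), inverted
#' tetrahedra are repaired by swapping their last two nodes and the number of
#' repairs is reported via a message; zero-volume (degenerate) elements are
#' always an error.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in mm.
#' @param elems integer matrix, one row per tetrahedron, four 1-based node
#'   indices per row.
#' @param region character vector, one region label per element.
#' @param node_sets named list of integer vectors (1-based node ids).
#' @param elem_sets named list of integer vectors (1-based element ids).
#' @param fix_orientation repair negative-volume tets by a node swap.
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elems, region,
                     node_sets = list(), elem_sets = list(),
                     fix_orientation = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns (x, y, z)")
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  dimnames(elems) <- NULL
  if (ncol(elems) != 4L) stop("elems must have 4 columns (4-node tets)")
  n <- nrow(nodes); ne <- nrow(elems)
  if (length(region) != ne) stop("region must have one label per element")
  region <- as.character(region)
  bad_reg <- setdiff(unique(region), REGION_LABELS)
  if (length(bad_reg) > 0)
    stop("unknown region label(s): ", paste(bad_reg, collapse = ", "))
  if (anyNA(elems) || any(elems < 1L) || any(elems > n)) {
    bad <- which(apply(elems, 1L, function(r) anyNA(r) || any(r < 1L | r > n)))
    stop("element(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         " reference nonexistent node ids")
  }
  dup <- elems[, 1L] == elems[, 2L] | elems[, 1L] == elems[, 3L] |
    elems[, 1L] == elems[, 4L] | elems[, 2L] == elems[, 3L] |
    elems[, 2L] == elems[, 4L] | elems[, 3L] == elems[, 4L]
  if (any(dup))
    stop("element(s) ", paste(utils::head(which(dup), 5L), collapse = ", "),
         " repeat a node id")
  vol <- .tet_signed_volumes(nodes, elems)
  if (any(vol == 0))
    stop("degenerate (zero-volume) element(s): ",
         paste(utils::head(which(vol == 0), 5L), collapse = ", "))
  neg <- vol < 0
  if (any(neg)) {
    if (!fix_orientation)
      stop("negative-volume element(s): ",
           paste(utils::head(which(neg), 5L), collapse = ", "))
    tmp <- elems[neg, 3L]
    elems[neg, 3L] <- elems[neg, 4L]
    elems[neg, 4L] <- tmp
    message("repaired node ordering of ", sum(neg), " inverted element(s)")
  }
  chk_sets <- function(sets, upper, what) {
    if (length(sets) == 0) return(lapply(sets, as.integer))
    if (is.null(names(sets)) || any(names(sets) == ""))
      stop(what, " must be a named list")
    lapply(sets, function(s) {
      s <- as.integer(s)
      if (length(s) && (anyNA(s) || any(s < 1L | s > upper)))
        stop(what, " references nonexistent ids")
      s
    })
  }
  structure(list(
    nodes = nodes, elems = elems, region = region,
    node_sets = chk_sets(node_sets, n, "node_sets"),
    elem_sets = chk_sets(elem_sets, ne, "elem_sets")
  ), class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$elems), "tets\n")
  cat("  regions:", paste(sprintf("%s=%d", names(table(x$region)),
                                  table(x$region)), collapse = " "), "\n")
  if (length(x$node_sets))
    cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  if (length(x$elem_sets))
    cat("  elem sets:", paste(names(x$elem_sets), collapse = ", "), "\n")
  invisible(x)
}

.tet_signed_volumes <- function(nodes, elems) {
  p1 <- nodes[elems[, 1L], , drop = FALSE]
  a <- nodes[elems[, 2L], , drop = FALSE] - p1
  b <- nodes[elems[, 3L], , drop = FALSE] - p1
  c_ <- nodes[elems[, 4L], , drop = FALSE] - p1
  (a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) +
   a[, 2L] * (b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]) +
   a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

#' Signed tetrahedron volumes
#'
#' @param mesh a `tet_mesh`.
#' @return numeric vector of element volumes in mm^3 (all positive for a
#'   valid mesh).
#' @export
tet_volumes <- function(mesh) .tet_signed_volumes(mesh$nodes, mesh$elems)

#' Element centroids
#' @param mesh a `tet_mesh`.
#' @return ne x 3 matrix of element centroids (mm).
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elems[, 1L], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 2L], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 3L], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 4L], , drop = FALSE]) / 4
}

# ---------------------------------------------------------------------------
# Abaqus-INP subset + native JSON I/O
# ---------------------------------------------------------------------------

#' Read a tetrahedral mesh
#'
#' Reads either a subset of the Abaqus INP dialect (`*NODE`,
#' `*ELEMENT, TYPE=C3D4`, `*NSET`, `*ELSET`) or the package's native JSON
#' format. INP element blocks whose `ELSET=` name is one of the five region
#' labels assign that region directly; otherwise regions may be supplied by
#' later `*ELSET` blocks named after a region. Unknown INP keywords are
#' skipped with a warning. Arbitrary (non-contiguous) INP ids are remapped
#' to contiguous 1-based indices in increasing id order.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"inp"` or `"json"`.
#' @return a `tet_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "inp", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "inp"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") .read_mesh_json(path) else .read_mesh_inp(path)
}

.read_mesh_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*\\*\\*", lines)]        # comments
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  is_kw <- startsWith(lines, "*")
  blocks <- cumsum(is_kw)
  node_id <- numeric(0); node_xyz <- NULL
  el_id <- integer(0); el_conn <- NULL; el_region <- character(0)
  nsets <- list(); elsets <- list()
  kw_of <- function(h) toupper(sub("^\\*([A-Za-z ]+).*$", "\\1", h))
  opt_of <- function(h, key) {
    m <- regmatches(h, regexpr(paste0("(?i)", key, "\\s*=\\s*[^,]+"), h, perl = TRUE))
    if (length(m) == 0) return(NA_character_)
    trimws(sub("^[^=]*=", "", m))
  }
  for (b in unique(blocks[is_kw])) {
    blk <- lines[blocks == b]
    header <- blk[1L]
    body <- blk[-1L]
    kw <- trimws(kw_of(header))
    parse_nums <- function(x) {
      v <- unlist(strsplit(paste(x, collapse = ","), ","))
      v <- trimws(v); v <- v[nzchar(v)]
      out <- suppressWarnings(as.numeric(v))
      if (anyNA(out)) stop("malformed numeric record in *", kw, " block: '",
                           v[which(is.na(out))[1L]], "'")
      out
    }
    if (kw == "NODE") {
      vals <- matrix(parse_nums(body), ncol = 4L, byrow = TRUE)
      node_id <- c(node_id, vals[, 1L])
      node_xyz <- rbind(node_xyz, vals[, 2:4, drop = FALSE])
    } else if (kw == "ELEMENT") {
      type <- toupper(opt_of(header, "TYPE"))
      if (is.na(type) || type != "C3D4")
        stop("only *ELEMENT TYPE=C3D4 is supported (got ",
             ifelse(is.na(type), "no TYPE", type), ")")
      elset <- opt_of(header, "ELSET")
      vals <- matrix(parse_nums(body), ncol = 5L, byrow = TRUE)
      el_id <- c(el_id, as.integer(vals[, 1L]))
      el_conn <- rbind(el_conn, vals[, 2:5, drop = FALSE])
      reg <- if (!is.na(elset) && tolower(elset) %in% REGION_LABELS)
        tolower(elset) else NA_character_
      el_region <- c(el_region, rep(reg, nrow(vals)))
      if (!is.na(elset) && !(tolower(elset) %in% REGION_LABELS))
        elsets[[elset]] <- c(elsets[[elset]], as.integer(vals[, 1L]))
    } else if (kw == "NSET") {
      nm <- opt_of(header, "NSET")
      if (is.na(nm)) stop("*NSET block without NSET= name")
      nsets[[nm]] <- c(nsets[[nm]], as.integer(parse_nums(body)))
    } else if (kw == "ELSET") {
      nm <- opt_of(header, "ELSET")
      if (is.na(nm)) stop("*ELSET block without ELSET= name")
      ids <- as.integer(parse_nums(body))
      if (tolower(nm) %in% REGION_LABELS) {
        elsets[[paste0(".region.", tolower(nm))]] <-
          c(elsets[[paste0(".region.", tolower(nm))]], ids)
      } else elsets[[nm]] <- c(elsets[[nm]], ids)
    } else {
      warning("skipping unsupported INP keyword *", kw)
    }
  }
  if (length(node_id) == 0) stop("no *NODE records found")
  if (length(el_id) == 0) stop("no *ELEMENT records found")
  if (anyDuplicated(node_id))
    stop("duplicate node id: ", node_id[anyDuplicated(node_id)])
  if (anyDuplicated(el_id))
    stop("duplicate element id: ", el_id[anyDuplicated(el_id)])
  # remap to contiguous 1-based in increasing-id order
  nord <- order(node_id)
  node_id <- node_id[nord]; node_xyz <- node_xyz[nord, , drop = FALSE]
  nmap <- setNames(seq_along(node_id), as.character(node_id))
  eord <- order(el_id)
  el_id <- el_id[eord]
  el_conn <- el_conn[eord, , drop = FALSE]
  el_region <- el_region[eord]
  conn_key <- as.character(as.vector(el_conn))
  miss <- which(!(conn_key %in% names(nmap)))
  if (length(miss)) {
    bad_e <- el_id[((miss[1L] - 1L) %% nrow(el_conn)) + 1L]
    stop("element ", bad_e, " references nonexistent node id ",
         conn_key[miss[1L]])
  }
  conn <- matrix(nmap[conn_key], ncol = 4L)
  emap <- setNames(seq_along(el_id), as.character(el_id))
  # region elsets collected under .region.<label>
  for (lbl in REGION_LABELS) {
    key <- paste0(".region.", lbl)
    if (!is.null(elsets[[key]])) {
      ids <- as.character(elsets[[key]])
      if (any(!(ids %in% names(emap))))
        stop("region elset '", lbl, "' references nonexistent element ids")
      el_region[emap[ids]] <- lbl
      elsets[[key]] <- NULL
    }
  }
  if (anyNA(el_region))
    stop("element(s) without a region label, e.g. id ",
         el_id[which(is.na(el_region))[1L]],
         "; supply ELSET=<region> on *ELEMENT or a region-named *ELSET")
  remap_set <- function(ids, map, what) {
    k <- as.character(ids)
    if (any(!(k %in% names(map)))) stop(what, " set references unknown ids")
    unname(map[k])
  }
  nsets <- lapply(nsets, remap_set, map = nmap, what = "node")
  elsets <- lapply(elsets, remap_set, map = emap, what = "element")
  tet_mesh(node_xyz, conn, el_region, nsets, elsets)
}

.read_mesh_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tet_mesh(matrix(as.numeric(obj$nodes), ncol = 3L, byrow = FALSE),
           matrix(as.integer(obj$elems), ncol = 4L, byrow = FALSE),
           obj$region,
           lapply(obj$node_sets, as.integer),
           lapply(obj$elem_sets, as.integer))
}

#' Write a tetrahedral mesh
#'
#' Writes the INP subset (one `*ELEMENT, TYPE=C3D4, ELSET=<region>` block
#' per region, then `*NSET`/`*ELSET` blocks) or the native JSON format.
#' Coordinates are written with 17 significant digits so a read/write/read
#' round trip is the identity.
#'
#' @param mesh a `tet_mesh`.
#' @param path output file.
#' @param format `"auto"`, `"inp"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "inp", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "inp"
  if (format == "json") {
    obj <- list(nodes = mesh$nodes, elems = mesh$elems, region = mesh$region,
                node_sets = mesh$node_sets, elem_sets = mesh$elem_sets)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  out <- character(0)
  out <- c(out, "*NODE")
  out <- c(out, sprintf("%d, %.17g, %.17g, %.17g",
                        seq_len(nrow(mesh$nodes)),
                        mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]))
  for (lbl in unique(mesh$region)) {
    ids <- which(mesh$region == lbl)
    out <- c(out, sprintf("*ELEMENT, TYPE=C3D4, ELSET=%s", lbl))
    out <- c(out, sprintf("%d, %d, %d, %d, %d", ids,
                          mesh$elems[ids, 1L], mesh$elems[ids, 2L],
                          mesh$elems[ids, 3L], mesh$elems[ids, 4L]))
  }
  fmt_set <- function(ids) {
    chunks <- split(ids, ceiling(seq_along(ids) / 12))
    vapply(chunks, function(ch) paste(ch, collapse = ", "), character(1))
  }
  for (nm in names(mesh$node_sets)) {
    out <- c(out, sprintf("*NSET, NSET=%s", nm), fmt_set(mesh$node_sets[[nm]]))
  }
  for (nm in names(mesh$elem_sets)) {
    out <- c(out, sprintf("*ELSET, ELSET=%s", nm), fmt_set(mesh$elem_sets[[nm]]))
  }
  writeLines(out, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Surface extraction
# ---------------------------------------------------------------------------

#' Extract the boundary surface of a tet mesh
#'
#' Returns the triangular faces that belong to exactly one tetrahedron,
#' with outward unit normals (oriented away from the owning element's
#' centroid) and face centroids. Used for gauge-patch selection, muscle
#' insertion areas and surface strain maps.
#'
#' @param mesh a `tet_mesh`.
#' @return an object of class `surface_patch`: list with `faces` (nf x 3
#'   node ids), `owner` (owning element id per face), `normals` (nf x 3,
#'   unit), `centroids` (nf x 3, mm), `areas` (nf, mm^2).
#' @export
extract_surface <- function(mesh) {
  ne <- nrow(mesh$elems)
  # local faces of tet (1,2,3,4)
  fidx <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  faces <- rbind(mesh$elems[, fidx[1L, ]], mesh$elems[, fidx[2L, ]],
                 mesh$elems[, fidx[3L, ]], mesh$elems[, fidx[4L, ]])
  owner <- rep(seq_len(ne), times = 4L)
  srt <- t(apply(faces, 1L, sort))
  n <- as.double(nrow(mesh$nodes)) + 1
  key <- (srt[, 1L] * n + srt[, 2L]) * n + srt[, 3L]   # exact below 2^53
  uk <- match(key, key)             # first-occurrence index per face key
  cnt <- tabulate(uk, nbins = length(key))
  bnd <- cnt[uk] == 1L
  faces <- faces[bnd, , drop = FALSE]
  owner <- owner[bnd]
  a <- mesh$nodes[faces[, 1L], , drop = FALSE]
  b <- mesh$nodes[faces[, 2L], , drop = FALSE]
  c_ <- mesh$nodes[faces[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2))
  areas <- len / 2
  nrm <- nrm / len
  fc <- (a + b + c_) / 3
  ec <- element_centroids(mesh)[owner, , drop = FALSE]
  flip <- rowSums(nrm * (fc - ec)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  structure(list(faces = faces, owner = owner, normals = nrm,
                 centroids = fc, areas = areas),
            class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  cat("surface_patch:", nrow(x$faces), "boundary faces, total area",
      format(sum(x$areas), digits = 6), "mm^2\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Legacy VTK export (and a minimal reader used for round-trip checks)
# ---------------------------------------------------------------------------

#' Write a mesh (plus per-element scalar fields) as legacy ASCII VTK
#'
#' Produces a `DATASET UNSTRUCTURED_GRID` file readable by standard viewers
#' (ParaView etc.); each entry of `cell_data` becomes a `SCALARS` array in
#' the order given. This is how differential strain maps are projected onto
#' the model surface for inspection.
#'
#' @param mesh a `tet_mesh`.
#' @param path output file.
#' @param cell_data named list of numeric vectors, one value per element.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list()) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  for (nm in names(cell_data))
    if (length(cell_data[[nm]]) != ne)
      stop("cell_data field '", nm, "' has length ", length(cell_data[[nm]]),
           ", expected ", ne)
  out <- c("# vtk DataFile Version 3.0", "jawstrain mesh", "ASCII",
           "DATASET UNSTRUCTURED_GRID",
           sprintf("POINTS %d double", n),
           sprintf("%.17g %.17g %.17g",
                   mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
           sprintf("CELLS %d %d", ne, 5L * ne),
           sprintf("4 %d %d %d %d", mesh$elems[, 1L] - 1L,
                   mesh$elems[, 2L] - 1L, mesh$elems[, 3L] - 1L,
                   mesh$elems[, 4L] - 1L),
           sprintf("CELL_TYPES %d", ne),
           rep("10", ne))
  if (length(cell_data)) {
    out <- c(out, sprintf("CELL_DATA %d", ne))
    for (nm in names(cell_data)) {
      out <- c(out, sprintf("SCALARS %s double 1", nm),
               "LOOKUP_TABLE default",
               sprintf("%.17g", as.numeric(cell_data[[nm]])))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# minimal reader for files written by write_vtk (round-trip checks)
.read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", lines)[1L]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1L]][2L])
  pts <- matrix(as.numeric(unlist(strsplit(lines[(ip + 1L):(ip + n)], "\\s+"))),
                ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1L]
  ne <- as.integer(strsplit(lines[ic], "\\s+")[[1L]][2L])
  cl <- matrix(as.integer(unlist(strsplit(lines[(ic + 1L):(ic + ne)], "\\s+"))),
               ncol = 5L, byrow = TRUE)
  elems <- cl[, 2:5, drop = FALSE] + 1L
  cd <- list()
  icd <- grep("^CELL_DATA", lines)
  if (length(icd)) {
    i <- icd[1L] + 1L
    while (i <= length(lines)) {
      if (grepl("^SCALARS", lines[i])) {
        nm <- strsplit(lines[i], "\\s+")[[1L]][2L]
        vals <- as.numeric(lines[(i + 2L):(i + 1L + ne)])
        cd[[nm]] <- vals
        i <- i + 2L + ne
      } else i <- i + 1L
    }
  }
  list(nodes = pts, elems = elems, cell_data = cd)
}

# ---------------------------------------------------------------------------
# Structured box mesh (verification problems: patch test, cantilever)
# ---------------------------------------------------------------------------

#' Structured tetrahedral box mesh
#'
#' Meshes the box `[0,lx] x [0,ly] x [0,lz]` with a regular grid of
#' `nx x ny x nz` cells, each split into six tetrahedra along a consistent
#' diagonal so neighbouring cells conform. Generates the face node sets
#' (`face_x0`, `face_x1`, ..., `face_z1`) used by the solver verification
#' problems (uniform-strain patch test, cantilever bending).
#'
#' @param lx,ly,lz box dimensions, mm.
#' @param nx,ny,nz cells per direction.
#' @param region region label applied to all elements.
#' @return a `tet_mesh`.
#' @export
box_mesh <- function(lx, ly, lz, nx, ny, nz, region = "cortical") {
  xs <- seq(0, lx, length.out = nx + 1L)
  ys <- seq(0, ly, length.out = ny + 1L)
  zs <- seq(0, lz, length.out = nz + 1L)
  nid <- function(i, j, k) ((k) * (ny + 1L) + j) * (nx + 1L) + i + 1L
  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  nodes <- cbind(xs[g$i + 1L], ys[g$j + 1L], zs[g$k + 1L])
  cells <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  elems <- .kuhn_tets(cells$i, cells$j, cells$k, nid)
  nsets <- list(
    face_x0 = which(abs(nodes[, 1L]) < 1e-12),
    face_x1 = which(abs(nodes[, 1L] - lx) < 1e-12),
    face_y0 = which(abs(nodes[, 2L]) < 1e-12),
    face_y1 = which(abs(nodes[, 2L] - ly) < 1e-12),
    face_z0 = which(abs(nodes[, 3L]) < 1e-12),
    face_z1 = which(abs(nodes[, 3L] - lz) < 1e-12))
  tet_mesh(nodes, elems, rep(region, nrow(elems)), node_sets = nsets,
           fix_orientation = TRUE)
}

# Kuhn (Freudenthal) subdivision of unit cells into 6 conforming tets.
# i,j,k: vectors of cell lower-corner indices; nid(i,j,k) -> node id.
.kuhn_tets <- function(i, j, k, nid) {
  v000 <- nid(i, j, k);         v100 <- nid(i + 1L, j, k)
  v010 <- nid(i, j + 1L, k);    v110 <- nid(i + 1L, j + 1L, k)
  v001 <- nid(i, j, k + 1L);    v101 <- nid(i + 1L, j, k + 1L)
  v011 <- nid(i, j + 1L, k + 1L); v111 <- nid(i + 1L, j + 1L, k + 1L)
  rbind(cbind(v000, v100, v110, v111),
        cbind(v000, v110, v010, v111),
        cbind(v000, v010, v011, v111),
        cbind(v000, v011, v001, v111),
        cbind(v000, v001, v101, v111),
        cbind(v000, v101, v100, v111))
}
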