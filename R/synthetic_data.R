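# Synthetic inputs: a parametric curved-corpus mandible phantom with tooth
# sockets and a conforming PDL shell, smooth grayscale fields over cortical
# bone, default muscle tables, gauge definitions, and synthetic in-vivo
# strain samples. Everything is deterministic given the seed, so the whole
# pipeline is testable without any downloads.
#
# Phantom geometry: a U-shaped curved corpus (structured grid in
# arch-length s, width w, height x coordinates, each cell split into six
# conforming tetrahedra) with a condylar post rising at each posterior end.
# The anatomical frame is X superoinferior, Y anteroposterior, Z
# mediolateral; the working (chewing) side is Z > 0.

#' Specify a mandible phantom
#'
#' Parameters of the parametric phantom. The PDL shell is
#' `pdl_thickness` element layers of `pdl_layer_mm` each, wrapped around
#' every tooth block on its mesial/distal/lingual/buccal sides and root
#' apex (the occlusal surface stays exposed). `pdl_thickness = 0` builds
#' the identical grid but labels the whole socket interior as tooth, so the
#' zero-PDL twin is geometry-matched to its PDL sibling. Non-zero
#' thicknesses below 3 layers are rejected: robust non-manifold shell
#' meshing needs at least 3 layers across the ligament space.
#'
#' @param corpus_length arc length of the corpus centerline, mm.
#' @param corpus_height,corpus_width cross-section size, mm.
#' @param arch_radius centerline radius of arch curvature, mm.
#' @param n_sockets tooth sockets per side.
#' @param socket_depth,socket_width,socket_length socket size, mm.
#' @param socket_gap gap between neighbouring sockets, mm.
#' @param socket_offset arc distance from the symphysis to the first socket
#'   edge, mm.
#' @param pdl_thickness PDL shell thickness in element layers (0 or >= 3).
#' @param pdl_layer_mm thickness of one PDL element layer, mm.
#' @param edge_length target element edge length outside the PDL, mm.
#' @param post_height,post_length condylar post height and arch-wise
#'   footprint, mm.
#' @param seed integer seed stamped on the phantom (the structured mesh is
#'   fully deterministic; the seed feeds derived random fields).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(corpus_length = 100,
                         corpus_height = 13,
                         corpus_width = 9,
                         arch_radius = 32,
                         n_sockets = 3,
                         socket_depth = 6.5,
                         socket_width = 4.5,
                         socket_length = 4.5,
                         socket_gap = 3.5,
                         socket_offset = 6,
                         pdl_thickness = 3,
                         pdl_layer_mm = 0.3,
                         edge_length = 2.2,
                         post_height = 11,
                         post_length = 6,
                         seed = 1L) {
  spec <- list(corpus_length = corpus_length, corpus_height = corpus_height,
               corpus_width = corpus_width, arch_radius = arch_radius,
               n_sockets = as.integer(n_sockets),
               socket_depth = socket_depth, socket_width = socket_width,
               socket_length = socket_length, socket_gap = socket_gap,
               socket_offset = socket_offset,
               pdl_thickness = as.integer(pdl_thickness),
               pdl_layer_mm = pdl_layer_mm,
               edge_length = edge_length, post_height = post_height,
               post_length = post_length, seed = as.integer(seed))
  for (f in c("corpus_length", "corpus_height", "corpus_width",
              "arch_radius", "socket_depth", "socket_width", "socket_length",
              "socket_gap", "socket_offset", "pdl_layer_mm", "edge_length",
              "post_height", "post_length"))
    if (!is.finite(spec[[f]]) || spec[[f]] <= 0)
      stop(f, " must be positive")
  if (spec$n_sockets < 1L) stop("n_sockets must be >= 1")
  if (spec$pdl_thickness != 0L && spec$pdl_thickness < 3L)
    stop("pdl_thickness must be 0 or >= 3 element layers")
  t_mm <- spec$pdl_thickness * spec$pdl_layer_mm
  t_mm3 <- max(spec$pdl_thickness, 3L) * spec$pdl_layer_mm  # grid always carved
  core <- c(width = spec$socket_width - 2 * t_mm3,
            length = spec$socket_length - 2 * t_mm3,
            depth = spec$socket_depth - t_mm3)
  if (any(core <= 0))
    stop("socket too small for the PDL shell: increase socket size or ",
         "decrease pdl_layer_mm")
  if (spec$edge_length > min(core)) {
    stop("edge length too coarse to honor pdl_thickness inside the sockets; ",
         "use edge_length <= ", format(min(core), digits = 4), " mm")
  }
  if (spec$socket_width >= spec$corpus_width)
    stop("socket_width leaves no cortical wall; widen the corpus")
  if (spec$socket_depth >= spec$corpus_height)
    stop("socket_depth leaves no bone below the roots; deepen the corpus")
  half <- spec$corpus_length / 2
  last_edge <- spec$socket_offset +
    spec$n_sockets * spec$socket_length +
    (spec$n_sockets - 1L) * spec$socket_gap
  if (last_edge + spec$post_length + 2 * spec$edge_length > half)
    stop("sockets + condylar posts do not fit on the arch; lengthen the ",
         "corpus or reduce n_sockets")
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec: corpus", x$corpus_length, "x", x$corpus_width, "x",
      x$corpus_height, "mm, arch radius", x$arch_radius, "mm,",
      x$n_sockets, "sockets/side, PDL", x$pdl_thickness, "layers of",
      x$pdl_layer_mm, "mm, edge", x$edge_length, "mm, seed", x$seed, "\n")
  invisible(x)
}

# append a filled segment of grid lines: from the current last line to `to`
# with target spacing h (at least one cell)
.seg <- function(lines, to, h) {
  a <- lines[length(lines)]
  n <- max(1L, as.integer(ceiling((to - a) / h - 1e-9)))
  c(lines, seq(a, to, length.out = n + 1L)[-1L])
}

#' Generate the mandible phantom mesh
#'
#' Builds the structured curved-corpus phantom described by a
#' [phantom_spec()]: tissue regions (`cortical` shell, `trabecular` core,
#' `tooth` blocks, `pdl` shells, two `screw` markers), the node sets needed
#' by [build_chewing_case()] (`bite_occlusal`, `condyle_working`,
#' `condyle_balancing`, ten muscle insertion sets) and the element sets
#' used by the region analyses (`alveolar`: cortical elements lining the
#' sockets; `tooth_root`: the apical part of the tooth blocks that are not
#' bite-constrained, where the ligament's stress shielding is observable
#' without the occlusal-constraint artifact; `tooth_root_all`: every
#' root). Gauge
#' definitions for three corpus sites (ULAT, LLAT buccal; MED lingual) are
#' attached as attribute `"gauges"`, and the analytic solid volume plus the
#' chord-approximation tolerance as attributes `"analytic_volume"` /
#' `"volume_tol"`.
#'
#' @param spec a `phantom_spec`.
#' @return a `tet_mesh` (attributes: `"spec"`, `"gauges"`,
#'   `"analytic_volume"`, `"volume_tol"`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  L <- spec$corpus_length; W <- spec$corpus_width; H <- spec$corpus_height
  R <- spec$arch_radius
  t_lay <- max(spec$pdl_thickness, 3L)      # grid always carves the shell
  pdl <- spec$pdl_layer_mm
  t_mm <- t_lay * pdl
  edge <- spec$edge_length
  sw <- spec$socket_width; sl <- spec$socket_length; sd <- spec$socket_depth
  half <- L / 2

  # ---- grid lines -------------------------------------------------------
  wl <- W / 2 - sw / 2; wr <- W / 2 + sw / 2
  lines_w <- 0
  lines_w <- .seg(lines_w, wl, edge)
  lines_w <- .seg(lines_w, wl + t_mm, pdl)
  lines_w <- .seg(lines_w, wr - t_mm, edge)
  lines_w <- .seg(lines_w, wr, pdl)
  lines_w <- .seg(lines_w, W, edge)

  sb <- H - sd
  lines_x <- 0
  lines_x <- .seg(lines_x, sb, edge)
  lines_x <- .seg(lines_x, sb + t_mm, pdl)
  lines_x <- .seg(lines_x, H, edge)
  nzc <- length(lines_x) - 1L              # corpus cell layers
  lines_x <- .seg(lines_x, H + spec$post_height, edge)

  # socket centres as arc distance from the symphysis (s = half)
  d_centres <- spec$socket_offset + spec$socket_length / 2 +
    (seq_len(spec$n_sockets) - 1L) * (sl + spec$socket_gap)
  centres_working <- half - d_centres      # working side: s < half (Z > 0)
  centres_balancing <- half + d_centres
  centres <- sort(c(centres_working, centres_balancing))
  lines_s <- 0
  lines_s <- .seg(lines_s, spec$post_length, edge)
  for (cc in centres) {
    lines_s <- .seg(lines_s, cc - sl / 2, edge)
    lines_s <- .seg(lines_s, cc - sl / 2 + t_mm, pdl)
    lines_s <- .seg(lines_s, cc + sl / 2 - t_mm, edge)
    lines_s <- .seg(lines_s, cc + sl / 2, pdl)
  }
  lines_s <- .seg(lines_s, L - spec$post_length, edge)
  lines_s <- .seg(lines_s, L, edge)

  ni <- length(lines_s); nj <- length(lines_w); nk <- length(lines_x)
  nci <- ni - 1L; ncj <- nj - 1L; nck <- nk - 1L

  # ---- active cells -----------------------------------------------------
  sc <- (lines_s[-1L] + lines_s[-ni]) / 2
  wc <- (lines_w[-1L] + lines_w[-nj]) / 2
  xc <- (lines_x[-1L] + lines_x[-nk]) / 2
  cells <- expand.grid(i = seq_len(nci), j = seq_len(ncj), k = seq_len(nck))
  csc <- sc[cells$i]; cwc <- wc[cells$j]; cxc <- xc[cells$k]
  in_post_band <- csc < spec$post_length | csc > L - spec$post_length
  active <- cells$k <= nzc | in_post_band
  cells <- cells[active, , drop = FALSE]
  csc <- csc[active]; cwc <- cwc[active]; cxc <- cxc[active]
  ncell <- nrow(cells)

  # ---- region classification -------------------------------------------
  region_cell <- rep("trabecular", ncell)
  # cortical shell of the corpus and the whole posts
  shell <- cells$j == 1L | cells$j == ncj | cells$k == 1L |
    cells$k == nzc | cells$i == 1L | cells$i == nci | cells$k > nzc
  region_cell[shell] <- "cortical"
  # sockets
  t_use <- spec$pdl_thickness          # 0 -> socket entirely tooth
  tm <- t_use * pdl
  in_core <- rep(FALSE, ncell); in_sock <- rep(FALSE, ncell)
  near_sock <- rep(FALSE, ncell)
  socket_of <- rep(NA_integer_, ncell)   # which socket a core cell belongs to
  for (ix in seq_along(centres)) {
    cc <- centres[ix]
    ds <- abs(csc - cc)
    sock <- ds < sl / 2 & cwc > wl & cwc < wr & cxc > sb & cells$k <= nzc
    core <- ds < sl / 2 - tm & cwc > wl + tm & cwc < wr - tm & cxc > sb + tm &
      cells$k <= nzc
    near <- ds < sl / 2 + 1.05 * edge & cwc > wl - 1.05 * edge &
      cwc < wr + 1.05 * edge & cxc > sb - 1.05 * edge & cells$k <= nzc
    in_sock <- in_sock | sock
    in_core <- in_core | core
    socket_of[core] <- ix
    near_sock <- near_sock | (near & !sock)
  }
  region_cell[in_sock] <- "pdl"
  region_cell[in_core] <- "tooth"
  if (t_use == 0L) region_cell[in_sock] <- "tooth"
  region_cell[near_sock & region_cell %in% c("cortical", "trabecular")] <-
    "cortical"
  alveolar_cell <- near_sock & region_cell == "cortical"
  # screw markers: one per side on the buccal surface behind the last socket
  for (s_scr in c(half - (d_centres[spec$n_sockets] + sl / 2 + 1.5 * edge),
                  half + (d_centres[spec$n_sockets] + sl / 2 + 1.5 * edge))) {
    cand <- which(cells$j == ncj & cells$k <= nzc & region_cell == "cortical" &
                    !alveolar_cell)
    pick <- cand[which.min((csc[cand] - s_scr)^2 +
                             (cxc[cand] - 0.45 * H)^2)]
    region_cell[pick] <- "screw"
  }
  # tooth roots: apical part of each tooth block. The primary `tooth_root`
  # comparison set excludes the bite-constrained teeth, whose strain state
  # is dominated by the occlusal displacement constraint (a boundary-
  # condition artifact, like the condylar constraint points);
  # `tooth_root_all` keeps every root.
  root_cell <- region_cell == "tooth" & cxc < H - 0.35 * sd
  n_bite <- max(1L, spec$n_sockets - 1L)
  bite_idx <- match(half - d_centres[seq_len(n_bite)], centres)
  root_free_cell <- root_cell & !(socket_of %in% bite_idx)

  # ---- nodes and tets ---------------------------------------------------
  lin <- function(i, j, k) i + 1L + j * ni + k * (ni * nj)   # 0-based i,j,k
  used <- logical(ni * nj * nk)
  ci0 <- cells$i - 1L; cj0 <- cells$j - 1L; ck0 <- cells$k - 1L
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1)
    used[lin(ci0 + di, cj0 + dj, ck0 + dk)] <- TRUE
  idmap <- integer(ni * nj * nk)
  idmap[used] <- seq_len(sum(used))
  nid <- function(i, j, k) idmap[lin(i, j, k)]
  # node parametric coordinates (only used nodes)
  gidx <- which(used) - 1L
  gi <- gidx %% ni
  gj <- (gidx %/% ni) %% nj
  gk <- gidx %/% (ni * nj)
  s_n <- lines_s[gi + 1L]; w_n <- lines_w[gj + 1L]; x_n <- lines_x[gk + 1L]
  phi <- (half - s_n) / R
  r <- R + (w_n - W / 2)
  nodes <- cbind(x_n, r * cos(phi), r * sin(phi))
  elems <- .kuhn_tets(ci0, cj0, ck0, nid)
  region <- rep(region_cell, times = 6L)

  # ---- node sets --------------------------------------------------------
  # bite teeth: the anterior working-side sockets (premolar/first-molar
  # analogues), all but the most posterior
  bite_centres <- half - d_centres[seq_len(n_bite)]
  tol <- 1e-9
  in_bite_s <- Reduce(`|`, lapply(bite_centres, function(bc)
    abs(s_n - bc) < sl / 2 - tm + tol))
  bite_nodes <- which(abs(x_n - H) < tol & in_bite_s &
    w_n > wl + tm - tol & w_n < wr - tm + tol)
  top <- H + spec$post_height
  cond_pick <- function(s_target) {
    cand <- which(abs(x_n - top) < tol)
    cand[which.min((s_n[cand] - s_target)^2 + (w_n[cand] - W / 2)^2)]
  }
  condyle_working <- cond_pick(spec$post_length / 2)
  condyle_balancing <- cond_pick(L - spec$post_length / 2)

  d_end <- pmin(s_n, L - s_n)          # arc distance to nearest posterior end
  sidesel <- function(working) if (working) s_n < half else s_n > half
  ins <- list()
  for (side in c("working", "balancing")) {
    wk <- side == "working"
    outer_surf <- abs(w_n - W) < tol & x_n <= H + tol
    inner_surf <- abs(w_n) < tol & x_n <= H + tol
    ins[[paste0("ins_superficial_masseter_", side)]] <-
      which(outer_surf & sidesel(wk) & d_end > spec$post_length &
              d_end < spec$post_length + 10 & x_n > 0.1 * H & x_n < 0.55 * H)
    ins[[paste0("ins_deep_masseter_", side)]] <-
      which(outer_surf & sidesel(wk) & d_end > spec$post_length &
              d_end < spec$post_length + 7 & x_n >= 0.55 * H & x_n < 0.98 * H)
    ins[[paste0("ins_medial_pterygoid_", side)]] <-
      which(inner_surf & sidesel(wk) & d_end > spec$post_length &
              d_end < spec$post_length + 9 & x_n > 0.05 * H & x_n < 0.5 * H)
    # temporalis on the condylar post (coronoid analogue): anterior face
    post_face_anterior <- abs(d_end - spec$post_length) < tol & x_n > H + tol
    post_face_posterior <- d_end < tol & x_n > H + tol
    ins[[paste0("ins_anterior_temporalis_", side)]] <-
      which(post_face_anterior & sidesel(wk) &
              x_n > H + 0.3 * spec$post_height &
              x_n < H + 0.95 * spec$post_height)
    ins[[paste0("ins_posterior_temporalis_", side)]] <-
      which(post_face_posterior & sidesel(wk) &
              x_n > H + 0.2 * spec$post_height &
              x_n < H + 0.9 * spec$post_height)
  }
  for (nm in names(ins))
    if (length(ins[[nm]]) == 0) stop("internal: empty insertion set ", nm)
  node_sets <- c(list(bite_occlusal = bite_nodes,
                      condyle_working = condyle_working,
                      condyle_balancing = condyle_balancing), ins)

  # ---- element sets -----------------------------------------------------
  cell_elems <- function(mask) as.vector(outer(which(mask),
                                               (0:5) * ncell, "+"))
  elem_sets <- list(alveolar = cell_elems(alveolar_cell),
                    tooth_root = cell_elems(root_free_cell),
                    tooth_root_all = cell_elems(root_cell),
                    screws = cell_elems(region_cell == "screw"))

  mesh <- tet_mesh(nodes, elems, region, node_sets, elem_sets,
                   fix_orientation = TRUE)

  # ---- gauges -----------------------------------------------------------
  gsock <- half - d_centres[spec$n_sockets]    # most posterior working socket
  mkg <- function(name, w_side, xfrac) {
    phi_g <- (half - gsock) / R
    outward <- c(0, cos(phi_g), sin(phi_g)) * (if (w_side == "outer") 1 else -1)
    r_g <- R + (if (w_side == "outer") W / 2 else -W / 2)
    ctr <- c(xfrac * H, r_g * cos(phi_g), r_g * sin(phi_g))
    xg <- c(1, 0, 0)
    yg <- c(outward[2] * 0 - outward[3] * 0,
            outward[3] * 1 - outward[1] * 0,
            outward[1] * 0 - outward[2] * 1)
    yg <- yg / sqrt(sum(yg^2))
    gauge_site(name, ctr, radius = 2.2 * edge,
               rotation = rbind(xg, yg, outward))
  }
  gauges <- list(ULAT = mkg("ULAT", "outer", 0.45),
                 LLAT = mkg("LLAT", "outer", 0.15),
                 MED = mkg("MED", "inner", 0.35))

  attr(mesh, "spec") <- spec
  attr(mesh, "gauges") <- gauges
  vol <- L * W * H + 2 * spec$post_length * W * spec$post_height
  dphi_max <- max(diff(lines_s)) / R
  attr(mesh, "analytic_volume") <- vol
  attr(mesh, "volume_tol") <- vol * dphi_max^2    # chord-vs-arc deficit bound
  mesh
}

#' Default synthetic muscle table for the phantom
#'
#' Ten jaw-elevator muscles (working/balancing superficial and deep
#' masseter, anterior and posterior temporalis, medial pterygoid) with
#' synthetic PCSA and normalised-EMG values plausible for a macaque-sized
#' jaw during unilateral chewing (working side more active). These are
#' generator defaults, not measured values. Cranial origin points are
#' placed relative to each insertion centroid so the pull is mostly
#' superior with anatomically signed anteroposterior/mediolateral
#' components (masseter slightly lateral-anterior, temporalis
#' posterior-superior, medial pterygoid medial-anterior).
#'
#' @param mesh a phantom `tet_mesh` (for insertion centroids).
#' @return muscle definition data.frame (see [read_muscles()]).
#' @export
default_muscles <- function(mesh) {
  base <- data.frame(
    name = rep(c("superficial_masseter", "deep_masseter",
                 "anterior_temporalis", "posterior_temporalis",
                 "medial_pterygoid"), 2L),
    side = rep(c("working", "balancing"), each = 5L),
    pcsa_cm2 = rep(c(2.5, 1.3, 2.0, 1.0, 1.9), 2L),
    emg_scale = c(0.90, 0.80, 0.85, 0.60, 0.90,
                  0.55, 0.45, 0.50, 0.35, 0.60),
    stringsAsFactors = FALSE)
  # offsets (up, anterior, lateral): lateral sign follows the side (+Z
  # working); medial pterygoid pulls medially (negative lateral offset)
  off <- list(superficial_masseter = c(20, 8, 6),
              deep_masseter = c(18, 2, 4),
              anterior_temporalis = c(28, 4, 1),
              posterior_temporalis = c(24, -8, 1),
              medial_pterygoid = c(18, 6, -8))
  base$insertion_set <- paste0("ins_", base$name, "_", base$side)
  org <- t(vapply(seq_len(nrow(base)), function(i) {
    nodes <- mesh$node_sets[[base$insertion_set[i]]]
    ctr <- colMeans(mesh$nodes[nodes, , drop = FALSE])
    o <- off[[base$name[i]]]
    lat_sign <- if (sign(ctr[3L]) != 0) sign(ctr[3L]) else 1
    # anterior = +Y at the posterior corpus on both sides
    ctr + c(o[1L], o[2L], lat_sign * o[3L])
  }, numeric(3L)))
  base$origin_x <- org[, 1L]; base$origin_y <- org[, 2L]
  base$origin_z <- org[, 3L]
  base
}

#' Synthetic grayscale field over cortical bone
#'
#' A smooth low-order spatial ramp plus bounded uniform noise, scaled into
#' `gv_range`. The default range maps (through the default calibration) to
#' apparent densities giving cortical Young's moduli of roughly 13-20 GPa,
#' so calibrated E stays far above the calibration floor for all elements.
#'
#' @param mesh a `tet_mesh` with cortical elements.
#' @param seed integer seed.
#' @param gv_range numeric length-2 grayscale range.
#' @param noise bounded noise amplitude as a fraction of the range.
#' @param constant if non-NULL, every cortical element gets this grayscale
#'   value (constant-mode flag).
#' @return named numeric vector: grayscale per cortical element id.
#' @export
make_grayscale <- function(mesh, seed = 1L, gv_range = NULL, noise = 0.04,
                           constant = NULL) {
  cort <- which(mesh$region == "cortical")
  if (length(cort) == 0) stop("mesh has no cortical elements")
  if (!is.null(constant))
    return(setNames(rep(as.numeric(constant), length(cort)),
                    as.character(cort)))
  if (is.null(gv_range)) {
    cal <- calibration_model()
    gv_range <- (c(1.6e6, 2.4e6) - cal$density_intercept) / cal$density_slope
  }
  ctr <- element_centroids(mesh)[cort, , drop = FALSE]
  rng <- apply(ctr, 2L, range)
  span <- pmax(rng[2L, ] - rng[1L, ], 1e-12)
  u <- sweep(sweep(ctr, 2L, rng[1L, ]), 2L, span, "/")
  f <- 0.2 + 0.6 * (0.5 * u[, 1L] + 0.3 * u[, 2L] + 0.2 * u[, 3L])
  set.seed(as.integer(seed))
  f <- f + stats::runif(length(f), -noise, noise)
  f <- pmin(1, pmax(0, f))
  setNames(gv_range[1L] + f * (gv_range[2L] - gv_range[1L]),
           as.character(cort))
}

#' Synthetic in-vivo strain sample with planted summary statistics
#'
#' Draws per-cycle maximum/minimum principal strains from a
#' piecewise-linear quantile function anchored at the planted minimum,
#' quartiles (median +/- IQR/2), and maximum, so the empirical median and
#' IQR converge to the planted values as `n` grows. Principal strain
#' orientations are drawn uniformly inside the planted circular arc.
#'
#' @param gauge gauge name.
#' @param n number of chew cycles (>= 4).
#' @param e1 list `(median, iqr, range = c(min, max))` for the maximum
#'   principal strain, microstrain.
#' @param emin same for the minimum principal strain (negative values).
#' @param orientation_arc `c(start_deg, width_deg)` of the planted
#'   orientation arc.
#' @param seed integer seed.
#' @return data.frame (`gauge`, `cycle`, `e1`, `emin`, `theta`), class
#'   `invivo_sample`.
#' @export
make_invivo <- function(gauge, n,
                        e1 = list(median = 150, iqr = 80, range = c(15, 270)),
                        emin = list(median = -140, iqr = 75,
                                    range = c(-250, -12)),
                        orientation_arc = c(50, 45), seed = 1L) {
  n <- as.integer(n)
  if (n < 4L) stop("need n >= 4 cycles (quartiles undefined below 4)")
  qfun <- function(p, plant) {
    v <- c(plant$range[1L], plant$median - plant$iqr / 2, plant$median,
           plant$median + plant$iqr / 2, plant$range[2L])
    if (any(diff(v) < 0))
      stop("infeasible plant: need min <= median - IQR/2 and ",
           "median + IQR/2 <= max (range must be at least as wide as IQR)")
    stats::approx(c(0, 0.25, 0.5, 0.75, 1), v, xout = p)$y
  }
  set.seed(as.integer(seed))
  p1 <- stats::runif(n); p2 <- stats::runif(n); pt <- stats::runif(n)
  out <- data.frame(gauge = gauge, cycle = seq_len(n),
                    e1 = qfun(p1, e1), emin = qfun(p2, emin),
                    theta = (orientation_arc[1L] +
                               pt * orientation_arc[2L]) %% 360)
  class(out) <- c("invivo_sample", "data.frame")
  out
}
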