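# Principal strains, gauge-frame rotation, gauge-site readouts,
# element-level differential maps and region summaries.
#
# Reporting convention: "e1" is the maximum principal strain and "e2" the
# minimum principal strain (the field's gauge convention). For the full 3D
# tensor the minimum is the smallest of the three eigenvalues; at a gauge
# it is the smaller of the two in-plane principal values.

.as_tensor_mat <- function(t) {
  if (is.matrix(t) && all(dim(t) == c(3L, 3L))) {
    if (max(abs(t - base::t(t))) > 1e-8 * max(1, max(abs(t))))
      stop("strain tensor must be symmetric")
    return(t)
  }
  t <- as.numeric(t)
  if (length(t) != 6L)
    stop("tensor must be 3x3 matrix or 6-vector (exx,eyy,ezz,exy,exz,eyz)")
  matrix(c(t[1L], t[4L], t[5L],
           t[4L], t[2L], t[6L],
           t[5L], t[6L], t[3L]), 3L, 3L)
}

.tensor_to_voigt <- function(m)
  c(exx = m[1L, 1L], eyy = m[2L, 2L], ezz = m[3L, 3L],
    exy = m[1L, 2L], exz = m[1L, 3L], eyz = m[2L, 3L])

#' Principal strains of a single tensor
#'
#' Eigen-decomposition of a symmetric small-strain tensor. Values are
#' sorted in decreasing order; `e1` (maximum principal strain) is the
#' first, and the reported minimum principal strain is the last.
#'
#' @param t 3x3 symmetric matrix or 6-vector `(exx,eyy,ezz,exy,exz,eyz)`
#'   with tensor shear components.
#' @return list with `values` (length 3, decreasing) and `axes` (3x3,
#'   columns = unit principal directions, right-handed).
#' @export
principal <- function(t) {
  m <- .as_tensor_mat(t)
  eg <- eigen(m, symmetric = TRUE)
  ax <- eg$vectors
  if (det(ax) < 0) ax[, 3L] <- -ax[, 3L]
  list(values = eg$values, axes = ax)
}

#' Principal strain values for every element of a strain field
#'
#' Vectorised closed-form eigenvalues of the symmetric 3x3 tensors
#' (trigonometric solution of the characteristic cubic).
#'
#' @param strains a `strain_field` (ne x 6) or any matrix with columns
#'   `exx, eyy, ezz, exy, exz, eyz`.
#' @return data.frame with `e1 >= mid >= e_min` per element (`e1` maximum,
#'   `e_min` minimum principal strain, same units as input).
#' @export
principal_values <- function(strains) {
  s <- unclass(strains)
  xx <- s[, 1L]; yy <- s[, 2L]; zz <- s[, 3L]
  xy <- s[, 4L]; xz <- s[, 5L]; yz <- s[, 6L]
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * (xy^2 + xz^2 + yz^2)
  p <- sqrt(p2 / 6)
  e1 <- emid <- emin <- q
  nz <- p > 0
  if (any(nz)) {
    bxx <- (xx - q) / p; byy <- (yy - q) / p; bzz <- (zz - q) / p
    bxy <- xy / p; bxz <- xz / p; byz <- yz / p
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(1, pmax(-1, detB / 2))
    phi <- acos(r) / 3
    l1 <- q + 2 * p * cos(phi)
    l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    l2 <- 3 * q - l1 - l3
    e1[nz] <- l1[nz]; emid[nz] <- l2[nz]; emin[nz] <- l3[nz]
  }
  data.frame(e1 = e1, mid = emid, e_min = emin)
}

#' Rotate a strain tensor into another frame
#'
#' `t' = R t R'` for an orthonormal rotation `R` whose rows are the target
#' frame's axes expressed in the source frame. Trace and principal values
#' are invariant.
#'
#' @param t 3x3 symmetric matrix or 6-vector.
#' @param R orthonormal 3x3 rotation.
#' @return same representation as the input (6-vector in, 6-vector out).
#' @export
rotate_tensor <- function(t, R) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L)) || max(abs(R %*% base::t(R) - diag(3))) > 1e-9)
    stop("R must be an orthonormal 3x3 rotation")
  m <- .as_tensor_mat(t)
  out <- R %*% m %*% base::t(R)
  if (is.matrix(t) && all(dim(t) == c(3L, 3L))) out else .tensor_to_voigt(out)
}

# vectorised R t R' over all rows of a strain field
.rotate_field <- function(strains, R) {
  s <- unclass(strains)
  comp <- function(i, j) {
    # E'_ij = sum_kl R[i,k] R[j,l] E_kl
    E <- list(list(s[, 1L], s[, 4L], s[, 5L]),
              list(s[, 4L], s[, 2L], s[, 6L]),
              list(s[, 5L], s[, 6L], s[, 3L]))
    acc <- 0
    for (k in 1:3) for (l in 1:3)
      acc <- acc + R[i, k] * R[j, l] * E[[k]][[l]]
    acc
  }
  out <- cbind(exx = comp(1, 1), eyy = comp(2, 2), ezz = comp(3, 3),
               exy = comp(1, 2), exz = comp(1, 3), eyz = comp(2, 3))
  attributes(out) <- c(attributes(out)[c("dim", "dimnames")],
                       attributes(strains)[c("n_elem", "mesh_sig")])
  class(out) <- class(strains)
  out
}

#' Anatomical-plane shear strain components
#'
#' Rotates strain tensors into the anatomical frame and returns the three
#' off-diagonal (tensor-shear) components: sagittal (XY), frontal (XZ) and
#' transverse (YZ), where X is superoinferior, Y anteroposterior and Z
#' mediolateral. The phantom generator builds meshes directly in this
#' frame, so the default is the identity rotation.
#'
#' @param strains a `strain_field` (or one 6-vector/3x3 tensor).
#' @param frame orthonormal 3x3 rotation, rows = anatomical axes in global
#'   coordinates.
#' @return data.frame with columns `sagittal`, `frontal`, `transverse`
#'   (same units as input; tensor shear convention).
#' @export
shear_components <- function(strains, frame = diag(3)) {
  frame <- as.matrix(frame)
  if (max(abs(frame %*% base::t(frame) - diag(3))) > 1e-9)
    stop("frame must be an orthonormal 3x3 rotation")
  if (!is.matrix(strains) || (is.matrix(strains) && all(dim(strains) == c(3L, 3L)))) {
    v <- rotate_tensor(strains, frame)
    v <- if (is.matrix(v)) .tensor_to_voigt(v) else v
    return(data.frame(sagittal = v[["exy"]], frontal = v[["exz"]],
                      transverse = v[["eyz"]]))
  }
  r <- .rotate_field(strains, frame)
  s <- unclass(r)
  data.frame(sagittal = s[, "exy"], frontal = s[, "exz"],
             transverse = s[, "eyz"])
}

# ---------------------------------------------------------------------------
# Gauge sites
# ---------------------------------------------------------------------------

#' Define a strain-gauge site
#'
#' A gauge site is a named circular patch on the model surface plus the
#' rotation from the global frame into the gauge frame (rows of `rotation`
#' are the gauge axes in global coordinates; the gauge plane is local xy,
#' local z is the surface normal).
#'
#' @param name gauge name (e.g. `"ULAT"`, `"LLAT"`, `"MED"`).
#' @param center patch centre, mm triple.
#' @param radius patch radius, mm (> 0).
#' @param rotation orthonormal 3x3 matrix.
#' @return object of class `gauge_site`.
#' @export
gauge_site <- function(name, center, radius, rotation) {
  rotation <- as.matrix(rotation)
  if (radius <= 0) stop("gauge radius must be > 0")
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-9)
    stop("gauge rotation must be orthonormal")
  structure(list(name = name, center = as.numeric(center),
                 radius = radius, rotation = rotation),
            class = "gauge_site")
}

#' Read / write gauge definitions (JSON)
#'
#' JSON schema: an array of objects with fields `name`, `center` (3),
#' `radius`, `rotation` (3x3, row-major rows).
#'
#' @param path JSON file.
#' @return list of `gauge_site` objects (named by gauge name).
#' @export
read_gauges <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(obj, function(g)
    gauge_site(g$name, unlist(g$center), g$radius,
               matrix(unlist(g$rotation), 3L, 3L, byrow = TRUE)))
  setNames(out, vapply(out, `[[`, "", "name"))
}

#' @rdname read_gauges
#' @param gauges list of `gauge_site` objects.
#' @export
write_gauges <- function(gauges, path) {
  obj <- lapply(gauges, function(g)
    list(name = g$name, center = g$center, radius = g$radius,
         rotation = lapply(seq_len(3L), function(i) g$rotation[i, ])))
  jsonlite::write_json(unname(obj), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read out FEM strains at a gauge site
#'
#' Selects the surface elements whose boundary-face centroid lies within
#' the patch radius of the gauge centre, rotates each element's strain
#' tensor into the gauge frame, and returns the in-plane principal strains
#' and the orientation of the maximum principal axis.
#'
#' Orientation convention: angle of the `e1` axis measured
#' counterclockwise from the gauge local +x axis, reported in degrees in
#' `[0, 360)`. A strain axis is 180-degree ambiguous; the representative
#' returned is `(0.5 * atan2(2 exy, exx - eyy)) mod 360`, which is fixed
#' and deterministic.
#'
#' @param mesh a `tet_mesh`.
#' @param strains a `strain_field` for that mesh.
#' @param site a `gauge_site`.
#' @param surface optional pre-computed [extract_surface()] result.
#' @return data.frame with one row per patch element: `element`, `e1`,
#'   `e2` (in-plane maximum/minimum principal strain, units of the input
#'   field), `theta_deg`. Attribute `"gauge"` carries the gauge name.
#' @export
gauge_readout <- function(mesh, strains, site, surface = NULL) {
  if (is.null(surface)) surface <- extract_surface(mesh)
  d2 <- rowSums((surface$centroids -
                   matrix(site$center, nrow(surface$centroids), 3L,
                          byrow = TRUE))^2)
  sel <- which(d2 <= site$radius^2)
  if (length(sel) == 0)
    stop("gauge '", site$name,
         "' patch selects no surface elements; increase the radius")
  owners <- unique(surface$owner[sel])
  sub <- unclass(strains)[owners, , drop = FALSE]
  cls <- class(strains)
  attr(sub, "n_elem") <- length(owners)
  class(sub) <- cls
  rot <- .rotate_field(sub, site$rotation)
  s <- unclass(rot)
  exx <- s[, "exx"]; eyy <- s[, "eyy"]; exy <- s[, "exy"]
  mean_ <- (exx + eyy) / 2
  rad <- sqrt(((exx - eyy) / 2)^2 + exy^2)
  theta <- (0.5 * atan2(2 * exy, exx - eyy) * 180 / pi) %% 360
  out <- data.frame(element = owners, e1 = mean_ + rad, e2 = mean_ - rad,
                    theta_deg = theta)
  attr(out, "gauge") <- site$name
  out
}

# ---------------------------------------------------------------------------
# Differential maps and region summaries
# ---------------------------------------------------------------------------

#' Element-level differential map between two model variants
#'
#' Computes the per-element difference `a - b` of a derived strain quantity
#' (e.g. maximum principal strain, or a shear component) obtained from two
#' solves on the identical mesh. For principal quantities the difference is
#' taken after computing the quantity per model, never as a tensor
#' difference. Swapping the arguments negates the map.
#'
#' @param a,b numeric per-element vectors of the same quantity from two
#'   variants (same mesh, same length).
#' @param quantity label, e.g. `"e1"`, `"e_min"`, `"e12"`, `"e13"`, `"e23"`.
#' @param pair optional character pair `c(name_a, name_b)`.
#' @return numeric vector of class `differential_map` with attributes
#'   `quantity` and `pair`.
#' @export
differential_map <- function(a, b, quantity = "e1", pair = c("A", "B")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("differential map requires identical meshes (lengths ",
         length(a), " vs ", length(b), ")")
  structure(a - b, class = "differential_map",
            quantity = quantity, pair = pair)
}

#' @export
print.differential_map <- function(x, ...) {
  p <- attr(x, "pair")
  cat(sprintf("differential_map %s (%s - %s): n=%d, range [%.4g, %.4g]\n",
              attr(x, "quantity"), p[1L], p[2L], length(x),
              min(x), max(x)))
  invisible(x)
}

#' Descriptive statistics of a strain quantity over an element region
#'
#' Mean, SD (sample SD, divisor n-1), minimum and maximum of a per-element
#' quantity over the given element ids — the summary-table format used to
#' report gauge-site and region strains.
#'
#' @param values per-element numeric vector (typically microstrain).
#' @param ids element ids of the region (non-empty). Default: all.
#' @param region region name for the output row.
#' @return one-row data.frame: `region`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
region_summary <- function(values, ids = seq_along(values),
                           region = "all") {
  if (length(ids) == 0) stop("empty region '", region, "'")
  v <- as.numeric(values[ids])
  data.frame(region = region, n = length(v), mean = mean(v),
             sd = if (length(v) > 1L) stats::sd(v) else 0,
             min = min(v), max = max(v))
}

#' Region summaries for all tissue regions of a mesh
#' @param values per-element numeric vector.
#' @param mesh a `tet_mesh`.
#' @return data.frame, one row per region present in the mesh.
#' @export
region_summaries <- function(values, mesh) {
  do.call(rbind, lapply(unique(mesh$region), function(r)
    region_summary(values, which(mesh$region == r), region = r)))
}
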