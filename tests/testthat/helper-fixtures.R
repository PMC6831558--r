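# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written with different algorithms from the implementation
# they check (brute force, finite differences, polynomial roots).

# small phantom for fast structural tests
quick_spec <- function(seed = 1L) {
  phantom_spec(corpus_length = 70, corpus_height = 12, corpus_width = 9,
               arch_radius = 24, n_sockets = 2, socket_depth = 6,
               socket_offset = 5, edge_length = 2.6, post_height = 8,
               post_length = 5.2, seed = seed)
}

quick_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom(quick_spec())
    cache
  }
})

# uniform material field for verification meshes
uniform_material <- function(mesh, E, v) {
  ne <- nrow(mesh$elems)
  structure(list(E = rep(E, ne), v = rep(v, ne), variant = "uniform",
                 n_elem = ne), class = "material_field")
}

# hand-built load case (bypasses the muscle machinery) for verification
raw_load_case <- function(mesh, forces, constraints) {
  structure(list(forces = forces, constraints = constraints,
                 scenario = "verification"), class = "load_case")
}

# nodal loads equivalent to a uniform traction sigma (3-vector, N/mm^2)
# on the boundary faces selected by `face_sel` (indices into the surface)
traction_loads <- function(mesh, surface, face_sel, sigma) {
  forces <- matrix(0, nrow(mesh$nodes), 3L)
  for (f in face_sel) {
    ids <- surface$faces[f, ]
    add <- surface$areas[f] / 3
    forces[ids, ] <- forces[ids, , drop = FALSE] +
      matrix(sigma * add, nrow = 3L, ncol = 3L, byrow = TRUE)
  }
  forces
}

# --- oracles ---------------------------------------------------------------

# brute-force boundary-face count: hash every face as a string
oracle_boundary_face_count <- function(mesh) {
  keys <- apply(mesh$elems, 1L, function(e) {
    combn(sort(e), 3L, paste, collapse = "-")
  })
  keys <- as.vector(keys)
  sum(table(keys) == 1L)
}

# elastic energy of one tet under nodal displacements (independent path:
# fit the affine displacement field, differentiate analytically, integrate
# the quadratic energy density over the volume)
oracle_tet_energy <- function(coords, u12, E, v) {
  U <- matrix(u12, ncol = 3L, byrow = TRUE)   # 4 x 3 nodal displacements
  X <- cbind(1, coords)                        # affine fit u(x) = A + G x
  coef <- solve(X, U)                          # 4x3; rows 2:4 = t(grad u)
  G <- t(coef[2:4, , drop = FALSE])            # G[i,j] = du_i/dx_j
  eps <- (G + t(G)) / 2
  lam <- E * v / ((1 + v) * (1 - 2 * v))
  mu <- E / (2 * (1 + v))
  vol <- abs(det(cbind(coords[2, ] - coords[1, ], coords[3, ] - coords[1, ],
                       coords[4, ] - coords[1, ]))) / 6
  vol * (0.5 * lam * sum(diag(eps))^2 + mu * sum(eps^2))
}

# stiffness as the finite-difference Hessian of the energy
oracle_energy_hessian <- function(coords, E, v, h = 1e-4) {
  K <- matrix(0, 12L, 12L)
  for (i in 1:12) for (j in i:12) {
    pp <- pm <- mp <- mm <- numeric(12L)
    pp[i] <- pp[i] + h; pp[j] <- pp[j] + h
    pm[i] <- pm[i] + h; pm[j] <- pm[j] - h
    mp[i] <- mp[i] - h; mp[j] <- mp[j] + h
    mm[i] <- mm[i] - h; mm[j] <- mm[j] - h
    K[i, j] <- K[j, i] <-
      (oracle_tet_energy(coords, pp, E, v) -
         oracle_tet_energy(coords, pm, E, v) -
         oracle_tet_energy(coords, mp, E, v) +
         oracle_tet_energy(coords, mm, E, v)) / (4 * h^2)
  }
  K
}

# eigenvalues as roots of the characteristic polynomial, via invariants
# computed with base det() and explicit principal minors
oracle_principal_values <- function(voigt) {
  A <- matrix(c(voigt[1], voigt[4], voigt[5],
                voigt[4], voigt[2], voigt[6],
                voigt[5], voigt[6], voigt[3]), 3L, 3L)
  I1 <- sum(diag(A))
  I2 <- det(A[-1, -1]) + det(A[-2, -2]) + det(A[-3, -3])
  I3 <- det(A)
  r <- polyroot(c(I3, -I2, I1, -1))
  sort(Re(r), decreasing = TRUE)
}

# evaluate the FE displacement field (linear interpolation) at a point
# inside element `el`, independently of the gradient formulas
fe_field_at <- function(mesh, u, el, p) {
  ids <- mesh$elems[el, ]
  X <- cbind(1, mesh$nodes[ids, , drop = FALSE])
  lam <- solve(t(X), c(1, p))          # barycentric-like weights
  as.numeric(t(u[ids, , drop = FALSE]) %*% lam)
}

# central-difference strain tensor of the FE field at a point
oracle_strain_at <- function(mesh, u, el, p, h = 1e-6) {
  G <- matrix(0, 3L, 3L)
  for (j in 1:3) {
    dp <- numeric(3L); dp[j] <- h
    G[, j] <- (fe_field_at(mesh, u, el, p + dp) -
                 fe_field_at(mesh, u, el, p - dp)) / (2 * h)
  }
  E <- (G + t(G)) / 2
  c(E[1, 1], E[2, 2], E[3, 3], E[1, 2], E[1, 3], E[2, 3])
}

# brute-force point location: barycentric test against every tet
locate_point <- function(mesh, p, tol = 1e-9) {
  gr <- jawstrain:::.tet_gradients(mesh$nodes, mesh$elems)
  p1 <- mesh$nodes[mesh$elems[, 1L], , drop = FALSE]
  d <- sweep(-p1, 2L, p, "+")
  l2 <- rowSums(gr$g[[2]] * d)
  l3 <- rowSums(gr$g[[3]] * d)
  l4 <- rowSums(gr$g[[4]] * d)
  l1 <- 1 - l2 - l3 - l4
  which(l1 >= -tol & l2 >= -tol & l3 >= -tol & l4 >= -tol)
}

# random small tet mesh: a perturbed box
random_box_mesh <- function(seed, nx = 2, ny = 2, nz = 2, jitter = 0.15) {
  set.seed(seed)
  m <- box_mesh(nx, ny, nz, nx, ny, nz)
  inner <- rowSums(m$nodes == 0 | sweep(m$nodes, 2, c(nx, ny, nz), "==")) == 0
  m$nodes[inner, ] <- m$nodes[inner, ] +
    matrix(runif(sum(inner) * 3, -jitter, jitter), ncol = 3L)
  tet_mesh(m$nodes, m$elems, m$region, m$node_sets, m$elem_sets)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_res <- qr(matrix(rnorm(9), 3L))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

inp_single_tet <- function(path) {
  writeLines(c(
    "*NODE",
    "1, 0., 0., 0.",
    "2, 1., 0., 0.",
    "3, 0., 1., 0.",
    "4, 0., 0., 1.",
    "*ELEMENT, TYPE=C3D4, ELSET=cortical",
    "10, 1, 2, 3, 4"), path)
  path
}
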