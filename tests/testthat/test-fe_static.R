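test_that("element stiffness is symmetric with a rigid-body nullspace", {
  set.seed(7)
  for (k in 1:5) {
    coords <- matrix(rnorm(12), 4L, 3L)
    if (det(cbind(coords[2, ] - coords[1, ], coords[3, ] - coords[1, ],
                  coords[4, ] - coords[1, ])) < 0)
      coords <- coords[c(1, 3, 2, 4), ]
    K <- element_stiffness(coords, E = 500, v = 0.3)
    expect_equal(K, t(K), tolerance = 1e-14)
    # rigid translations and a linearised rigid rotation are in the nullspace
    scale <- max(abs(K))
    for (tr in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      u <- rep(tr, 4L)
      expect_lt(max(abs(K %*% u)), 1e-9 * scale)
    }
    W <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3L)   # skew: rotation about z
    u_rot <- as.numeric(W %*% t(coords))   # (node1 xyz, node2 xyz, ...)
    expect_lt(max(abs(K %*% u_rot)), 1e-9 * scale)
    # exactly 6 near-zero eigenvalues
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-9 * scale), 6L)
  }
  expect_error(element_stiffness(matrix(0, 4, 3), 500, 0.3), "degenerate|invalid")
})

test_that("element stiffness matches the energy-Hessian oracle", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  K <- element_stiffness(coords, E = 1, v = 0.3)
  K_oracle <- oracle_energy_hessian(coords, E = 1, v = 0.3)
  expect_equal(K, K_oracle, tolerance = 1e-8)

  set.seed(11)
  coords2 <- coords + matrix(runif(12, -0.2, 0.2), 4L)
  K2 <- element_stiffness(coords2, E = 3, v = 0.42)
  expect_equal(K2, oracle_energy_hessian(coords2, E = 3, v = 0.42),
               tolerance = 1e-7 * max(abs(K2)), ignore_attr = TRUE)
})

test_that("assembled stiffness agrees with per-element stiffness", {
  m <- random_box_mesh(3)
  ne <- nrow(m$elems)
  mat <- uniform_material(m, 800, 0.25)
  K <- as.matrix(assemble_stiffness(m, mat))
  K_ref <- matrix(0, 3 * nrow(m$nodes), 3 * nrow(m$nodes))
  for (e in seq_len(ne)) {
    Ke <- element_stiffness(m$nodes[m$elems[e, ], ], 800, 0.25)
    dofs <- as.vector(t(outer(m$elems[e, ] - 1L, 1:3,
                              function(a, b) 3 * a + b)))
    K_ref[dofs, dofs] <- K_ref[dofs, dofs] + Ke
  }
  expect_equal(K, K_ref, tolerance = 1e-12, ignore_attr = TRUE)
  # global symmetry and non-negative strain energy
  expect_equal(K, t(K), tolerance = 1e-12)
  set.seed(4)
  for (k in 1:5) {
    u <- rnorm(ncol(K))
    expect_gte(sum(u * (K %*% u)), -1e-9 * max(abs(K)))
  }
})

test_that("free-free stiffness has exactly six near-zero eigenvalues", {
  m <- random_box_mesh(5, nx = 2, ny = 2, nz = 1)    # 81 DOF
  K <- as.matrix(assemble_stiffness(m, uniform_material(m, 100, 0.3)))
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6L)
})

test_that("zero load gives zero displacement; missing constraints error", {
  m <- box_mesh(2, 1, 1, 2, 1, 1)
  mat <- uniform_material(m, 1000, 0.3)
  lc <- raw_load_case(m, matrix(0, nrow(m$nodes), 3),
                      list(list(set = "clamp", nodes = m$node_sets$face_x0,
                                axes = 1:3)))
  sol <- solve_static(m, mat, lc)
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(sol$residual, 0)

  lc_bad <- raw_load_case(m, matrix(0, nrow(m$nodes), 3), list())
  expect_error(solve_static(m, mat, lc_bad), "constraints")
  # constraining a single node in one axis leaves rigid modes -> not PD
  lc_bad2 <- raw_load_case(m, matrix(0, nrow(m$nodes), 3),
                           list(list(set = "pt", nodes = 1L, axes = 1L)))
  suppressWarnings(   # CHOLMOD also warns before the factorisation fails
    expect_error(solve_static(m, mat, lc_bad2), "positive definite"))
})

test_that("uniaxial patch test reproduces the uniform strain state exactly", {
  E <- 1000; v <- 0.3; sigma <- 10
  m <- box_mesh(10, 4, 4, 5, 2, 2)
  surf <- extract_surface(m)
  sel <- which(abs(surf$centroids[, 1] - 10) < 1e-9)
  forces <- traction_loads(m, surf, sel, c(sigma, 0, 0))
  lc <- raw_load_case(m, forces, list(
    list(set = "x0", nodes = m$node_sets$face_x0, axes = 1L),
    list(set = "y0", nodes = m$node_sets$face_y0, axes = 2L),
    list(set = "z0", nodes = m$node_sets$face_z0, axes = 3L)))
  sol <- solve_static(m, uniform_material(m, E, v), lc)
  st <- recover_strains(m, sol)
  expect_lt(sol$residual, 1e-10)
  expect_lt(sol$equilibrium_error, 1e-10)
  expect_equal(unname(range(st[, "exx"])), rep(sigma / E, 2),
               tolerance = 1e-10)
  expect_equal(unname(range(st[, "eyy"])), rep(-v * sigma / E, 2),
               tolerance = 1e-10)
  expect_lt(max(abs(st[, c("exy", "exz", "eyz")])), 1e-10 * sigma / E)
})

test_that("iterative solver agrees with the direct factorisation", {
  m <- box_mesh(6, 2, 2, 6, 2, 2)
  surf <- extract_surface(m)
  sel <- which(abs(surf$centroids[, 1] - 6) < 1e-9)
  forces <- traction_loads(m, surf, sel, c(0, 0, -2))
  lc <- raw_load_case(m, forces, list(
    list(set = "clamp", nodes = m$node_sets$face_x0, axes = 1:3)))
  mat <- uniform_material(m, 500, 0.3)
  sol_d <- solve_static(m, mat, lc, solver = "direct")
  sol_i <- solve_static(m, mat, lc, solver = "cg", cg_tol = 1e-12)
  expect_equal(sol_i$u, sol_d$u, tolerance = 1e-8)
})

test_that("cantilever deflection converges monotonically toward beam theory", {
  E <- 2000; v <- 0.3; P <- 1; L <- 50; h <- 5
  I <- h^4 / 12
  exact <- P * L^3 / (3 * E * I)
  errs <- vapply(list(c(20, 2, 2), c(40, 4, 4), c(60, 6, 6)), function(nn) {
    m <- box_mesh(L, h, h, nn[1], nn[2], nn[3])
    tip <- which(abs(m$nodes[, 1] - L) < 1e-9)
    forces <- matrix(0, nrow(m$nodes), 3)
    forces[tip, 3] <- -P / length(tip)
    lc <- raw_load_case(m, forces, list(
      list(set = "clamp", nodes = m$node_sets$face_x0, axes = 1:3)))
    sol <- solve_static(m, uniform_material(m, E, v), lc)
    abs(abs(mean(sol$u[tip, 3])) - exact) / exact
  }, numeric(1))
  expect_true(all(diff(errs) < 0))          # monotone refinement convergence
})

test_that("solution is invariant under node-order permutation", {
  m <- box_mesh(4, 2, 2, 4, 2, 2)
  surf <- extract_surface(m)
  sel <- which(abs(surf$centroids[, 1] - 4) < 1e-9)
  forces <- traction_loads(m, surf, sel, c(1, 0.5, -2))
  lc <- raw_load_case(m, forces, list(
    list(set = "clamp", nodes = m$node_sets$face_x0, axes = 1:3)))
  mat <- uniform_material(m, 300, 0.28)
  sol <- solve_static(m, mat, lc)

  set.seed(9)
  perm <- sample(nrow(m$nodes))              # new id of old node i
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- tet_mesh(m$nodes[inv, ], matrix(perm[m$elems], ncol = 4),
                 m$region, lapply(m$node_sets, function(s) perm[s]),
                 m$elem_sets)
  lc2 <- raw_load_case(m2, forces[inv, ], list(
    list(set = "clamp", nodes = perm[m$node_sets$face_x0], axes = 1:3)))
  sol2 <- solve_static(m2, mat, lc2)
  expect_equal(sol2$u[perm, ], sol$u,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("strain recovery is exact for affine fields and matches finite differences", {
  m <- random_box_mesh(13)
  # symmetric affine field u = A x: every element strain equals A
  A <- matrix(c(3, 1, -2, 1, 5, 0.5, -2, 0.5, -1), 3L) * 1e-3
  u <- m$nodes %*% t(A)
  st <- recover_strains(m, u)
  for (e in sample(nrow(m$elems), 10)) {
    expect_equal(unname(unclass(st)[e, ]),
                 c(A[1, 1], A[2, 2], A[3, 3], A[1, 2], A[1, 3], A[2, 3]),
                 tolerance = 1e-12)
  }
  # rigid translation and linearised rotation give ~zero strain
  u_tr <- matrix(rep(c(4, -2, 9), each = nrow(m$nodes)), ncol = 3)
  expect_lt(max(abs(recover_strains(m, u_tr))), 1e-12)
  W <- matrix(c(0, 2, -1, -2, 0, 3, 1, -3, 0), 3L) * 1e-4
  expect_lt(max(abs(recover_strains(m, m$nodes %*% t(W)))), 1e-15)

  # random displacements: central-difference oracle at element centroids
  set.seed(21)
  u_rand <- matrix(rnorm(3 * nrow(m$nodes), sd = 1e-2), ncol = 3)
  st_r <- recover_strains(m, u_rand)
  ctr <- element_centroids(m)
  for (e in sample(nrow(m$elems), 8)) {
    expect_equal(unname(unclass(st_r)[e, ]),
                 oracle_strain_at(m, u_rand, e, ctr[e, ]),
                 tolerance = 1e-6)
  }
})

test_that("microstrain scaling and engineering shear accessor", {
  m <- random_box_mesh(2)
  u <- m$nodes %*% t(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3L)) * 1e-3
  st <- recover_strains(m, u)
  expect_equal(unname(microstrain(st)[1, "exy"]), 1e3, tolerance = 1e-9)
  g <- engineering_shear(st)
  expect_equal(unname(g[, "gxy"]), unname(2 * unclass(st)[, "exy"]))
})
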