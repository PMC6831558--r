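# Small-strain static linear elasticity on 4-node (constant-strain)
# tetrahedra: element stiffness, vectorised sparse assembly, constraint
# elimination, direct sparse solve, and strain recovery.
#
# Displacements are in mm, forces in N, moduli in MPa (N/mm^2), so units
# are consistent without conversion factors. Strains are stored with the
# tensor shear convention e_ij = (du_i/dx_j + du_j/dx_i)/2; engineering
# shear (gamma = 2 e_ij) is available via engineering_shear().

# shape-function gradients of the 4 barycentric functions; returns list
# with per-element gradient components g[[a]] = ne x 3 matrix, and volumes
.tet_gradients <- function(nodes, elems) {
  p1 <- nodes[elems[, 1L], , drop = FALSE]
  a <- nodes[elems[, 2L], , drop = FALSE] - p1
  b <- nodes[elems[, 3L], , drop = FALSE] - p1
  c_ <- nodes[elems[, 4L], , drop = FALSE] - p1
  cross3 <- function(u, v)
    cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
          u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
          u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  bc <- cross3(b, c_); ca <- cross3(c_, a); ab <- cross3(a, b)
  det <- rowSums(a * bc)
  if (any(det <= 0)) stop("degenerate or inverted element in gradient computation")
  g2 <- bc / det; g3 <- ca / det; g4 <- ab / det
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = det / 6)
}

#' Stiffness matrix of a single 4-node tetrahedron
#'
#' Closed-form constant-strain-tet stiffness `K = V B' D B` for an
#' isotropic material, in N/mm. Symmetric, positive semi-definite with the
#' six rigid-body modes as nullspace. DOF ordering: (node1 x,y,z, node2
#' x,y,z, ...).
#'
#' @param coords 4 x 3 matrix of node coordinates, mm.
#' @param E Young's modulus, MPa.
#' @param v Poisson's ratio, in (0, 0.5).
#' @return 12 x 12 numeric matrix.
#' @export
element_stiffness <- function(coords, E, v) {
  coords <- as.matrix(coords)
  if (!all(dim(coords) == c(4L, 3L))) stop("coords must be 4 x 3")
  if (E <= 0 || v <= 0 || v >= 0.5) stop("invalid elastic properties")
  gr <- .tet_gradients(coords, matrix(1:4, nrow = 1L))
  g <- rbind(gr$g[[1L]], gr$g[[2L]], gr$g[[3L]], gr$g[[4L]])  # 4 x 3
  V <- gr$vol
  # B matrix (6 x 12), engineering-shear rows
  B <- matrix(0, 6L, 12L)
  for (a in 1:4) {
    cx <- 3L * (a - 1L)
    B[1L, cx + 1L] <- g[a, 1L]
    B[2L, cx + 2L] <- g[a, 2L]
    B[3L, cx + 3L] <- g[a, 3L]
    B[4L, cx + 1L] <- g[a, 2L]; B[4L, cx + 2L] <- g[a, 1L]  # gamma_xy
    B[5L, cx + 1L] <- g[a, 3L]; B[5L, cx + 3L] <- g[a, 1L]  # gamma_xz
    B[6L, cx + 2L] <- g[a, 3L]; B[6L, cx + 3L] <- g[a, 2L]  # gamma_yz
  }
  lam <- E * v / ((1 + v) * (1 - 2 * v))
  mu <- E / (2 * (1 + v))
  D <- diag(c(rep(0, 3L), rep(mu, 3L)))
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  V * (t(B) %*% D %*% B)
}

#' Assemble the global sparse stiffness matrix
#'
#' Vectorised assembly over all elements: for shape-function gradients
#' `g_a` the (a,b) node block of the element stiffness is
#' `V * (lambda g_a g_b' + mu g_b g_a' + mu (g_a . g_b) I)`. This is an
#' independent formulation from [element_stiffness()] (which builds
#' `B' D B` explicitly); the two are cross-checked in the test suite.
#'
#' @param mesh a `tet_mesh`.
#' @param materials a complete `material_field`.
#' @return sparse symmetric `dgCMatrix` of size `3n x 3n`, N/mm.
#' @export
assemble_stiffness <- function(mesh, materials) {
  if (anyNA(materials$E)) stop("material field incomplete")
  gr <- .tet_gradients(mesh$nodes, mesh$elems)
  ne <- nrow(mesh$elems)
  V <- gr$vol
  lam <- materials$E * materials$v /
    ((1 + materials$v) * (1 - 2 * materials$v))
  mu <- materials$E / (2 * (1 + materials$v))
  nblk <- 144L
  ii <- integer(nblk * ne); jj <- integer(nblk * ne); xx <- numeric(nblk * ne)
  pos <- 0L
  for (a in 1:4) {
    ga <- gr$g[[a]]
    na <- mesh$elems[, a]
    for (b in 1:4) {
      gb <- gr$g[[b]]
      nb <- mesh$elems[, b]
      dot_ab <- rowSums(ga * gb)
      for (i in 1:3) {
        for (j in 1:3) {
          val <- lam * ga[, i] * gb[, j] + mu * gb[, i] * ga[, j]
          if (i == j) val <- val + mu * dot_ab
          rng <- pos + seq_len(ne)
          ii[rng] <- 3L * (na - 1L) + i
          jj[rng] <- 3L * (nb - 1L) + j
          xx[rng] <- V * val
          pos <- pos + ne
        }
      }
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(3L * nrow(mesh$nodes), 3L * nrow(mesh$nodes)))
}

.fixed_dofs <- function(constraints, n_nodes) {
  idx <- integer(0)
  for (cs in constraints)
    for (ax in cs$axes)
      idx <- c(idx, 3L * (cs$nodes - 1L) + ax)
  sort(unique(idx))
}

#' Solve the static linear elastic problem
#'
#' Assembles `K`, eliminates the constrained degrees of freedom (rows and
#' columns removed, so constraints are satisfied exactly and reactions are
#' recovered cleanly), and solves `K_ff u_f = f_f` with a sparse Cholesky
#' factorisation (the default, mirroring an implicit direct static solve).
#' An optional Jacobi-preconditioned conjugate-gradient solver is available
#' behind `solver = "cg"`.
#'
#' @param mesh a `tet_mesh`.
#' @param materials complete `material_field`.
#' @param load a `load_case`.
#' @param solver `"direct"` or `"cg"`.
#' @param cg_tol relative tolerance for the iterative solver.
#' @return object of class `fe_solution`: `u` (n x 3 mm), `residual`
#'   (relative residual on free DOFs), `reactions` (data.frame of reaction
#'   forces at constrained DOFs, N), `equilibrium_error` (relative net
#'   force imbalance), `fixed_dofs`, `log` (character lines).
#' @export
solve_static <- function(mesh, materials, load,
                         solver = c("direct", "cg"), cg_tol = 1e-10) {
  solver <- match.arg(solver)
  n <- nrow(mesh$nodes)
  K <- assemble_stiffness(mesh, materials)
  f <- as.numeric(t(load$forces))
  fixed <- .fixed_dofs(load$constraints, n)
  if (length(fixed) == 0)
    stop("no constraints: rigid-body modes present; add constraints")
  free <- setdiff(seq_len(3L * n), fixed)
  Kff <- K[free, free, drop = FALSE]
  ff <- f[free]
  uf <- if (solver == "direct") {
    Ks <- Matrix::forceSymmetric(Kff)
    ch <- tryCatch(Matrix::Cholesky(Ks, LDL = FALSE),
                   error = function(e)
                     stop("stiffness not positive definite after constraint ",
                          "elimination; check that constraints remove all ",
                          "rigid-body modes (", conditionMessage(e), ")"))
    as.numeric(Matrix::solve(ch, ff, system = "A"))
  } else {
    .cg_solve(Kff, ff, tol = cg_tol)
  }
  u <- numeric(3L * n)
  u[free] <- uf
  Ku <- as.numeric(K %*% u)
  fn <- sqrt(sum(ff^2))
  residual <- if (fn > 0) sqrt(sum((Ku[free] - ff)^2)) / fn else
    sqrt(sum(Ku[free]^2))
  # reactions at constrained DOFs
  react <- Ku[fixed] - f[fixed]
  applied_net <- colSums(load$forces)
  react_net <- c(sum(react[(fixed - 1L) %% 3L == 0L]),
                 sum(react[(fixed - 1L) %% 3L == 1L]),
                 sum(react[(fixed - 1L) %% 3L == 2L]))
  denom <- max(sqrt(sum(applied_net^2)), max(abs(f)), 1e-300)
  eq_err <- sqrt(sum((applied_net + react_net)^2)) / denom
  umat <- matrix(u, ncol = 3L, byrow = TRUE)
  logl <- c(sprintf("solver=%s ndof=%d nfixed=%d", solver, 3L * n,
                    length(fixed)),
            sprintf("relative residual = %.3e", residual),
            sprintf("net applied force  = [%s] N",
                    paste(sprintf("%.6g", applied_net), collapse = ", ")),
            sprintf("net reaction force = [%s] N",
                    paste(sprintf("%.6g", react_net), collapse = ", ")),
            sprintf("equilibrium error  = %.3e", eq_err))
  structure(list(u = umat, residual = residual,
                 reactions = data.frame(dof = fixed, force = react),
                 reaction_net = react_net, applied_net = applied_net,
                 equilibrium_error = eq_err, fixed_dofs = fixed, log = logl),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(x$log, sep = "\n")
  invisible(x)
}

# Jacobi-preconditioned conjugate gradients on the reduced system
.cg_solve <- function(A, b, tol = 1e-10, maxit = 20000L) {
  d <- Matrix::diag(A)
  if (any(d <= 0)) stop("non-positive diagonal; system not positive definite")
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) / bn < tol) return(x)
    z <- r / d
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  warning("CG did not reach tolerance ", tol, " in ", maxit, " iterations")
  x
}

#' Recover per-element strain tensors from nodal displacements
#'
#' Linear tets carry constant strain: `e = sym(grad u)` from the
#' shape-function gradients. Components are stored with the tensor shear
#' convention (`exy = (du_x/dy + du_y/dx)/2`).
#'
#' @param mesh a `tet_mesh`.
#' @param u n x 3 displacement matrix (mm), or an `fe_solution`.
#' @return a `strain_field`: ne x 6 matrix with columns
#'   `exx, eyy, ezz, exy, exz, eyz` (dimensionless).
#' @export
recover_strains <- function(mesh, u) {
  if (inherits(u, "fe_solution")) u <- u$u
  u <- as.matrix(u)
  if (nrow(u) != nrow(mesh$nodes) || ncol(u) != 3L)
    stop("u must be a ", nrow(mesh$nodes), " x 3 displacement matrix")
  gr <- .tet_gradients(mesh$nodes, mesh$elems)
  ne <- nrow(mesh$elems)
  H <- array(0, dim = c(ne, 3L, 3L))   # displacement gradient du_i/dx_j
  for (a in 1:4) {
    ua <- u[mesh$elems[, a], , drop = FALSE]
    ga <- gr$g[[a]]
    for (i in 1:3) for (j in 1:3)
      H[, i, j] <- H[, i, j] + ua[, i] * ga[, j]
  }
  strains <- cbind(exx = H[, 1L, 1L], eyy = H[, 2L, 2L], ezz = H[, 3L, 3L],
                   exy = (H[, 1L, 2L] + H[, 2L, 1L]) / 2,
                   exz = (H[, 1L, 3L] + H[, 3L, 1L]) / 2,
                   eyz = (H[, 2L, 3L] + H[, 3L, 2L]) / 2)
  structure(strains, class = c("strain_field", "matrix"),
            n_elem = ne, mesh_sig = .mesh_signature(mesh))
}

.mesh_signature <- function(mesh) {
  c(nrow(mesh$nodes), nrow(mesh$elems),
    sum(mesh$elems), round(sum(mesh$nodes) * 1e6))
}

#' Convert a strain field (or any strain quantity) to microstrain
#' @param x numeric strains (dimensionless).
#' @return `x * 1e6` (microstrain).
#' @export
microstrain <- function(x) {
  y <- unclass(x) * 1e6
  attributes(y) <- attributes(x)
  if (inherits(x, "strain_field")) class(y) <- class(x)
  y
}

#' Engineering shear components of a strain field
#'
#' Returns `gamma = 2 e_ij` for the three shear components (the package
#' stores tensor shear; some gauge conventions use engineering shear).
#'
#' @param strains a `strain_field`.
#' @return ne x 3 matrix with columns `gxy, gxz, gyz`.
#' @export
engineering_shear <- function(strains) {
  s <- unclass(strains)
  cbind(gxy = 2 * s[, "exy"], gxz = 2 * s[, "exz"], gyz = 2 * s[, "eyz"])
}
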