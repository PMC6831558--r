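test_that("principal strains: closed-form cases and the cubic-root oracle", {
  p <- principal(c(100, -50, 0, 0, 0, 0))
  expect_equal(p$values, c(100, 0, -50))

  # pure in-plane shear: e1 = +g, min = -g, orientation 45 degrees
  pv <- principal_values(matrix(c(0, 0, 0, 100, 0, 0), 1))
  expect_equal(pv$e1, 100)
  expect_equal(pv$e_min, -100)

  set.seed(31)
  for (k in 1:20) {
    v6 <- rnorm(6, sd = 200)
    pv <- principal_values(matrix(v6, 1))
    expect_equal(unlist(pv, use.names = FALSE),
                 oracle_principal_values(v6), tolerance = 1e-9)
    # trace invariant and ordering
    expect_equal(pv$e1 + pv$mid + pv$e_min, sum(v6[1:3]), tolerance = 1e-9)
    expect_gte(pv$e1, pv$mid); expect_gte(pv$mid, pv$e_min)
    # single-tensor path agrees, axes orthonormal
    pr <- principal(v6)
    expect_equal(pr$values, unlist(pv, use.names = FALSE), tolerance = 1e-9)
    expect_equal(crossprod(pr$axes), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # isotropic tensor (p = 0 branch)
  expect_equal(unlist(principal_values(matrix(c(5, 5, 5, 0, 0, 0), 1)),
                      use.names = FALSE), c(5, 5, 5))
})

test_that("tensor rotation preserves invariants and closed forms", {
  t0 <- c(10, 20, 30, 4, 5, 6)
  expect_equal(rotate_tensor(t0, diag(3)), t0, ignore_attr = TRUE)

  # 90-degree rotation about z swaps xx and yy and negates xy
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3L)
  tr <- rotate_tensor(t0, Rz)
  expect_equal(unname(tr[1:3]), c(20, 10, 30))
  expect_equal(unname(tr[4]), -4)

  for (k in 1:10) {
    R <- random_rotation(100 + k)
    set.seed(200 + k)
    t6 <- rnorm(6, sd = 100)
    tr <- rotate_tensor(t6, R)
    expect_equal(sum(tr[1:3]), sum(t6[1:3]), tolerance = 1e-9)
    expect_equal(oracle_principal_values(tr), oracle_principal_values(t6),
                 tolerance = 1e-9)
  }
  expect_error(rotate_tensor(t0, matrix(1, 3, 3)), "orthonormal")
})

test_that("anatomical shear components match direct R t R' indexing", {
  # already in the anatomical frame
  sh <- shear_components(c(0, 0, 0, 50, 0, 0))
  expect_equal(unlist(sh), c(sagittal = 50, frontal = 0, transverse = 0))
  # pure dilation has no shear in any frame
  R <- random_rotation(77)
  expect_equal(unlist(shear_components(c(7, 7, 7, 0, 0, 0), R)),
               c(sagittal = 0, frontal = 0, transverse = 0),
               tolerance = 1e-12)
  # field path equals per-element matrix algebra
  set.seed(55)
  S <- matrix(rnorm(6 * 12, sd = 100), ncol = 6,
              dimnames = list(NULL, c("exx", "eyy", "ezz", "exy", "exz", "eyz")))
  sf <- structure(S, class = c("strain_field", "matrix"))
  sh2 <- shear_components(sf, R)
  for (e in 1:12) {
    m <- R %*% jawstrain:::.as_tensor_mat(S[e, ]) %*% t(R)
    expect_equal(c(sh2$sagittal[e], sh2$frontal[e], sh2$transverse[e]),
                 c(m[1, 2], m[1, 3], m[2, 3]), tolerance = 1e-12)
  }
})

test_that("gauge readout selects the patch and reports in-plane strains", {
  m <- box_mesh(10, 6, 4, 5, 3, 2)
  # uniform uniaxial strain along x, gauge on the z = 4 face (plane xy)
  exx <- 2e-3
  u <- cbind(m$nodes[, 1] * exx, 0, 0)
  st <- recover_strains(m, u)
  site <- gauge_site("TOP", center = c(5, 3, 4), radius = 2.5, diag(3))
  ro <- gauge_readout(m, st, site)
  expect_gt(nrow(ro), 0)
  expect_equal(ro$e1, rep(exx, nrow(ro)), tolerance = 1e-12)
  expect_equal(ro$theta_deg, rep(0, nrow(ro)), tolerance = 1e-9)
  expect_identical(attr(ro, "gauge"), "TOP")

  # infinite radius covers every surface element
  surf <- extract_surface(m)
  ro_all <- gauge_readout(m, st, gauge_site("ALL", c(5, 3, 4), 1e9, diag(3)),
                          surface = surf)
  expect_setequal(ro_all$element, unique(surf$owner))

  # patch membership equals a brute-force distance filter
  ph <- quick_phantom()
  g <- attr(ph, "gauges")$ULAT
  sph <- extract_surface(ph)
  u2 <- cbind(ph$nodes[, 1] * 1e-3, 0, 0)
  ro2 <- gauge_readout(ph, recover_strains(ph, u2), g, surface = sph)
  d <- sqrt(colSums((t(sph$centroids) - g$center)^2))
  expect_setequal(ro2$element, unique(sph$owner[d <= g$radius]))

  expect_error(gauge_readout(m, st, gauge_site("FAR", c(999, 999, 999),
                                               0.5, diag(3))),
               "radius")
})

test_that("differential maps are antisymmetric and match the loop oracle", {
  set.seed(60)
  a <- rnorm(500); b <- rnorm(500)
  d <- differential_map(a, b, "e1", c("NO_PDL", "PDL"))
  expect_equal(as.numeric(d), vapply(seq_along(a),
                                     function(i) a[i] - b[i], numeric(1)))
  d2 <- differential_map(b, a, "e1", c("PDL", "NO_PDL"))
  expect_equal(as.numeric(d2), -as.numeric(d))
  expect_equal(as.numeric(differential_map(a, a)), rep(0, 500))
  expect_error(differential_map(a, b[-1]), "identical meshes")
})

test_that("region summaries reproduce two-pass statistics", {
  s <- region_summary(rep(100, 7), region = "const")
  expect_equal(s$mean, 100); expect_equal(s$sd, 0)
  expect_equal(s$min, 100); expect_equal(s$max, 100)

  s2 <- region_summary(c(1, 2, 3))
  expect_equal(s2$mean, 2); expect_equal(s2$min, 1); expect_equal(s2$max, 3)

  set.seed(71)
  v <- rnorm(1000, 50, 12)
  ids <- sample(1000, 400)
  s3 <- region_summary(v, ids, "rand")
  m <- sum(v[ids]) / length(ids)
  expect_equal(s3$mean, m, tolerance = 1e-12)
  expect_equal(s3$sd, sqrt(sum((v[ids] - m)^2) / (length(ids) - 1)),
               tolerance = 1e-12)
  expect_true(s3$min <= s3$mean && s3$mean <= s3$max)
  expect_error(region_summary(v, integer(0)), "empty region")
})

test_that("gauge definitions survive a JSON round trip", {
  ph <- quick_phantom()
  gauges <- attr(ph, "gauges")
  path <- withr::local_tempfile(fileext = ".json")
  write_gauges(gauges, path)
  back <- read_gauges(path)
  expect_identical(names(back), names(gauges))
  for (nm in names(gauges)) {
    expect_equal(back[[nm]]$center, gauges[[nm]]$center, tolerance = 1e-12)
    expect_equal(back[[nm]]$rotation, gauges[[nm]]$rotation,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(back[[nm]]$radius, gauges[[nm]]$radius)
  }
})
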