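test_that("phantom spec validation catches impossible geometry", {
  expect_error(phantom_spec(pdl_thickness = 2), "0 or >= 3")
  expect_error(phantom_spec(edge_length = 5), "too coarse")
  expect_error(phantom_spec(socket_width = 1.5), "too small")
  expect_error(phantom_spec(corpus_length = 40), "do not fit")
  expect_error(phantom_spec(corpus_width = -1), "positive")
})

test_that("phantom has the advertised structure", {
  ph <- quick_phantom()
  expect_s3_class(ph, "tet_mesh")
  expect_setequal(unique(ph$region),
                  c("cortical", "trabecular", "tooth", "pdl", "screw"))
  need_sets <- c("bite_occlusal", "condyle_working", "condyle_balancing",
                 paste0("ins_", rep(c("superficial_masseter", "deep_masseter",
                                      "anterior_temporalis",
                                      "posterior_temporalis",
                                      "medial_pterygoid"), 2), "_",
                        rep(c("working", "balancing"), each = 5)))
  expect_true(all(need_sets %in% names(ph$node_sets)))
  expect_length(ph$node_sets$condyle_working, 1L)
  expect_length(ph$node_sets$condyle_balancing, 1L)
  expect_true(all(c("alveolar", "tooth_root", "tooth_root_all", "screws") %in%
                    names(ph$elem_sets)))
  expect_true(all(ph$region[ph$elem_sets$alveolar] == "cortical"))
  expect_true(all(ph$region[ph$elem_sets$tooth_root] == "tooth"))
  # all volumes positive, total volume matches the parametric solid
  vols <- tet_volumes(ph)
  expect_true(all(vols > 0))
  expect_lt(abs(sum(vols) - attr(ph, "analytic_volume")),
            attr(ph, "volume_tol"))
  # working side is Z > 0: working condyle and bite teeth live there
  expect_gt(ph$nodes[ph$node_sets$condyle_working, 3], 0)
  expect_true(all(ph$nodes[ph$node_sets$bite_occlusal, 3] > 0))
  expect_lt(ph$nodes[ph$node_sets$condyle_balancing, 3], 0)
})

test_that("phantom generation is deterministic", {
  a <- make_phantom(quick_spec())
  b <- make_phantom(quick_spec())
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$elems, b$elems)
  expect_identical(a$region, b$region)
  expect_identical(a$node_sets, b$node_sets)
})

test_that("zero-PDL twin is geometry-matched and relabels the socket", {
  sp0 <- quick_spec(); sp0$pdl_thickness <- 0L
  ph0 <- make_phantom(sp0)
  ph3 <- quick_phantom()
  expect_identical(ph0$nodes, ph3$nodes)
  expect_identical(ph0$elems, ph3$elems)
  expect_false(any(ph0$region == "pdl"))
  # every pdl element of the 3-layer phantom is tooth in the twin
  expect_true(all(ph0$region[ph3$region == "pdl"] == "tooth"))
  expect_identical(ph0$region[ph3$region == "cortical"],
                   ph3$region[ph3$region == "cortical"])
})

test_that("every tooth is wrapped by at least 3 PDL layers (ray casting)", {
  ph <- quick_phantom()
  spec <- attr(ph, "spec")
  H <- spec$corpus_height; R <- spec$arch_radius; W <- spec$corpus_width
  half <- spec$corpus_length / 2
  sb <- H - spec$socket_depth
  tm <- spec$pdl_thickness * spec$pdl_layer_mm
  d1 <- spec$socket_offset + spec$socket_length / 2
  to_xyz <- function(s, w, x) {
    phi <- (half - s) / R
    r <- R + (w - W / 2)
    c(x, r * cos(phi), r * sin(phi))
  }
  # rays from inside a tooth block outward through the shell: apical (-x),
  # lingual (-w) and mesial (-s) directions of the first working socket
  rays <- list(
    apical = t(vapply(seq(sb + tm + 0.2, sb - 0.6, length.out = 40),
                      function(x) to_xyz(half - d1, W / 2, x), numeric(3))),
    lingual = t(vapply(seq(W / 2 - spec$socket_width / 2 + tm + 0.2,
                           W / 2 - spec$socket_width / 2 - 0.6,
                           length.out = 40),
                       function(w) to_xyz(half - d1, w, H - 2), numeric(3))),
    mesial = t(vapply(seq(half - d1 - spec$socket_length / 2 + tm + 0.2,
                          half - d1 - spec$socket_length / 2 - 0.6,
                          length.out = 40),
                      function(s) to_xyz(s, W / 2, H - 2), numeric(3))))
  for (nm in names(rays)) {
    pts <- rays[[nm]]
    regions <- apply(pts, 1L, function(p) {
      el <- locate_point(ph, p)
      if (length(el) == 0) NA_character_ else ph$region[el[1L]]
    })
    regions <- regions[!is.na(regions)]
    pdl_elems <- unique(unlist(apply(pts, 1L, function(p) {
      el <- locate_point(ph, p)
      el[ph$region[el] == "pdl"]
    })))
    # ray starts in tooth, crosses >= 3 distinct pdl elements, ends in bone
    expect_equal(regions[1L], "tooth")
    expect_true(utils::tail(regions, 1L) %in% c("cortical", "trabecular"))
    expect_gte(length(pdl_elems), 3L)
    # no direct tooth -> bone transition
    trans <- paste(utils::head(regions, -1), utils::tail(regions, -1))
    expect_false(any(trans %in% c("tooth cortical", "tooth trabecular",
                                  "cortical tooth", "trabecular tooth")))
  }
})

test_that("grayscale fields are smooth, bounded and reproducible", {
  ph <- quick_phantom()
  cort <- which(ph$region == "cortical")
  g1 <- make_grayscale(ph, seed = 4)
  g2 <- make_grayscale(ph, seed = 4)
  g3 <- make_grayscale(ph, seed = 5)
  expect_identical(g1, g2)
  expect_false(identical(g1, g3))
  expect_length(g1, length(cort))

  cal <- calibration_model()
  rng <- (c(1.6e6, 2.4e6) - cal$density_intercept) / cal$density_slope
  expect_true(all(g1 >= rng[1] & g1 <= rng[2]))
  # calibrated E above the floor for (at least) 99% of cortical elements
  E <- calibrate_element(unname(g1), cal)$E
  expect_gte(mean(E > cal$E_floor), 0.99)

  gc_ <- make_grayscale(ph, constant = 1234)
  expect_true(all(gc_ == 1234))
})

test_that("planted in-vivo samples converge to their statistics", {
  iv <- make_invivo("MED", 50000,
                    e1 = list(median = 120, iqr = 60, range = c(20, 300)),
                    emin = list(median = -90, iqr = 50, range = c(-280, -5)),
                    orientation_arc = c(300, 80), seed = 12)
  expect_equal(stats::median(iv$e1), 120, tolerance = 0.02)
  expect_equal(unname(diff(stats::quantile(iv$e1, c(0.25, 0.75)))), 60,
               tolerance = 0.02)
  expect_equal(stats::median(iv$emin), -90, tolerance = 0.02)
  expect_true(all(iv$e1 >= 20 & iv$e1 <= 300))
  # orientations inside the planted arc (which wraps through 0)
  ok <- (iv$theta - 300) %% 360 <= 80
  expect_true(all(ok))

  # minimal sample and determinism
  iv4 <- make_invivo("X", 4, seed = 3)
  expect_equal(nrow(iv4), 4L)
  expect_identical(make_invivo("X", 4, seed = 3), iv4)
  expect_error(make_invivo("X", 3), "n >= 4")
  expect_error(make_invivo("X", 10,
                           e1 = list(median = 100, iqr = 80,
                                     range = c(90, 110))),
               "infeasible")
})
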