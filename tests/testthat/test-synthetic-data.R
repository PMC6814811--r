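test_that("scene generation is deterministic and substream-stable", {
  sp <- scene_spec(seed = 21, n_mitochondria = 3)
  g1 <- generate_scene(sp)
  g2 <- generate_scene(sp)
  expect_identical(g1$truth, g2$truth)
  expect_identical(lapply(g1$scene$traces, `[[`, "vertices"),
                   lapply(g2$scene$traces, `[[`, "vertices"))

  # adding mitochondria leaves earlier ones untouched
  g5 <- generate_scene(scene_spec(seed = 21, n_mitochondria = 5))
  expect_identical(g5$truth[1:3, ], g1$truth)
  expect_identical(g5$scene$traces[[1L]]$vertices,
                   g1$scene$traces[[1L]]$vertices)
})

test_that("spec validation rejects out-of-support distributions", {
  expect_error(scene_spec(arc_distance_nm = c(5, 40)), "arc_distance_nm")
  expect_error(scene_spec(arc_coverage_frac = c(0, 0.5)),
               "arc_coverage_frac")
  expect_error(scene_spec(out_of_range_distance_nm = c(20, 50)),
               "out_of_range")
  expect_error(scene_spec(mito_radius_nm = c(800, 300)), "range")
  expect_error(scene_spec(trace_jitter_nm = -1), "jitter")
})

test_that("ground truth matches the closed form and is recovered end-to-end", {
  g <- generate_scene(concentric_spec())
  cf <- (0.25 * 2 * pi * 512) / (2 * pi * 500 * 12)
  expect_rel_equal(g$truth$ermicc_per_nm, cf, 0.001)
  expect_equal(g$truth$D_nm, 12)

  m <- measure_scene(g$scene)$metrics
  expect_rel_equal(m$ermicc_per_nm, cf, 0.02)
  expect_equal(m$D_nm, 12, tolerance = 0.01)
})

test_that("zero-arc scenes measure as zero contact everywhere", {
  sp <- scene_spec(seed = 5, n_mitochondria = 2, er_arcs_per_mito = 0L)
  g <- generate_scene(sp)
  expect_true(all(g$truth$zero_contact))
  m <- measure_scene(g$scene)$metrics
  expect_true(all(m$L_nm == 0))
  expect_true(all(m$ermicc_per_nm == 0))
  expect_true(all(is.na(m$D_nm)))
})

test_that("measured metrics recover ground truth under tracing jitter", {
  rel_err <- c(); d_err <- c()
  for (seed in 1:10) {
    g <- generate_scene(scene_spec(seed = seed, n_mitochondria = 2))
    m <- measure_scene(g$scene)$metrics
    ok <- g$truth$L_nm > 0
    rel_err <- c(rel_err, abs(m$ermicc_per_nm[ok] /
                                g$truth$ermicc_per_nm[ok] - 1))
    d_err <- c(d_err, abs(m$D_nm[ok] - g$truth$D_nm[ok]))
  }
  expect_lte(median(rel_err), 0.03)
  expect_lte(median(d_err), 1)
})

test_that("rasterization round-trips through contour extraction", {
  g <- generate_scene(concentric_spec(r = 300, d = 15, coverage = 0.3))
  ras <- rasterize_scene(g$scene, pixel_nm = 1)
  sc <- read_label_masks(ras$mom_label, ras$er_label, pixel_size_nm = 1)
  mom <- contactq:::scene_traces(sc, "MOM")[[1L]]
  expect_rel_equal(perimeter(mom), 2 * pi * 300, 0.01)
  expect_length(contactq:::scene_traces(sc, "ER"), 1L)

  # empty ER scene rasterizes to an all-zero ER mask
  g0 <- generate_scene(scene_spec(seed = 2, n_mitochondria = 1,
                                  er_arcs_per_mito = 0L))
  ras0 <- rasterize_scene(g0$scene, pixel_nm = 2)
  expect_true(all(ras0$er_label == 0L))
  expect_error(rasterize_scene(g0$scene, pixel_nm = 0), "pixel_nm")
})

test_that("polyline bands agree with the raster distance-transform oracle", {
  skip_if_not_installed("EBImage")
  for (seed in c(13, 14)) {
    g <- generate_scene(scene_spec(seed = seed, n_mitochondria = 1,
                                   mito_radius_nm = c(150, 250)))
    mom <- contactq:::scene_traces(g$scene, "MOM")[[1L]]
    ers <- contactq:::scene_traces(g$scene, "ER")
    bp <- compute_band_profile(mom, ers)
    bo <- band_profile_raster(mom, ers)
    expect_rel_equal(compute_total_contact_length(bp),
                     compute_total_contact_length(bo), 0.02)
    expect_lt(abs(compute_average_distance(bp) -
                    compute_average_distance(bo)), 0.5)
  }
})
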