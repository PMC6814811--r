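test_that("band profiles bin ER length by midpoint distance", {
  # straight MOM edge along y = 0; parallel ER segment at exact distance 5.5
  mom <- rect_trace(xmax = 1000)
  er <- membrane_trace(rbind(c(100, 5.5), c(300, 5.5)), role = "ER")
  bp <- compute_band_profile(mom, er)
  expect_equal(bp$incremental_nm[6L], 200, tolerance = 1e-9)
  expect_equal(sum(bp$incremental_nm[-6L]), 0)

  # concentric arc: quarter turn at radius 515 around an r = 500 circle
  circ <- circle_trace(500, n = 720L)
  arc <- concentric_arc_trace(500, 15, 0.25, n = 720L)
  bp2 <- compute_band_profile(circ, arc)
  expect_equal(which(bp2$incremental_nm > 0), 15L)
  expect_rel_equal(bp2$incremental_nm[15L], (pi / 2) * 515, 0.005)

  # ER entirely beyond the 30-nm range contributes nothing
  far <- membrane_trace(rbind(c(100, 40), c(300, 40)), role = "ER")
  expect_equal(sum(compute_band_profile(mom, far)$incremental_nm), 0)

  # no ER traces: all-zero profile, not an error
  expect_equal(sum(compute_band_profile(mom)$incremental_nm), 0)
})

test_that("band config enforces its invariants", {
  expect_error(band_config(step_nm = 0), "step_nm")
  expect_error(band_config(n_bands = 0), "n_bands")
  expect_error(band_config(resample_step_nm = 0.6), "resample_step_nm")
  cfg <- band_config(step_nm = 2, n_bands = 15L, resample_step_nm = 1)
  expect_equal(cfg$n_bands, 15L)
})

test_that("L, D and ERMICC follow the printed formulas", {
  mk <- function(l) {
    structure(list(config = band_config(), incremental_nm = l,
                   cumulative_nm = cumsum(l)), class = "band_profile")
  }
  l <- numeric(30); l[10L] <- 30; l[20L] <- 10
  expect_equal(compute_total_contact_length(mk(l)), 40)
  expect_equal(compute_average_distance(mk(l)), 12.5)

  single <- numeric(30); single[7L] <- 123
  expect_equal(compute_average_distance(mk(single)), 7)

  zeros <- mk(numeric(30))
  expect_equal(compute_total_contact_length(zeros), 0)
  expect_true(is.na(compute_average_distance(zeros)))

  expect_equal(compute_ermicc(808.98, 3141.59, 15),
               808.98 / (3141.59 * 15))
  expect_equal(compute_ermicc(200, 10 * 20, 10), 0.1)
  expect_equal(compute_ermicc(0, 400, NA_real_), 0)
  expect_error(compute_ermicc(10, 400, NA_real_), "inconsist")
  expect_error(compute_ermicc(10, 0, 5), "P")
})

test_that("conservation and range invariants hold on random scenes", {
  for (seed in 1:6) {
    g <- generate_scene(scene_spec(seed = seed, n_mitochondria = 2))
    sc <- g$scene
    mom <- contactq:::scene_traces(sc, "MOM")[[1L]]
    ers <- contactq:::scene_traces(sc, "ER")
    bp <- compute_band_profile(mom, ers)
    expect_true(all(bp$incremental_nm >= 0))
    expect_true(all(diff(bp$cumulative_nm) >= -1e-12))
    expect_equal(sum(bp$incremental_nm),
                 bp$cumulative_nm[length(bp$cumulative_nm)],
                 tolerance = 1e-9)
    L <- compute_total_contact_length(bp)
    D <- compute_average_distance(bp)
    if (L > 0) {
      expect_gte(D, bp$config$step_nm)
      expect_lte(D, bp$config$n_bands * bp$config$step_nm)
      expect_equal(compute_ermicc(L, perimeter(mom), D),
                   L / (perimeter(mom) * D))
    }
  }
})

test_that("metrics are invariant under rigid motion and scale as lengths", {
  g <- generate_scene(scene_spec(seed = 9, n_mitochondria = 1))
  sc <- g$scene
  base <- measure_scene(sc)$metrics

  move <- function(tr, ...) contactq:::transform_trace(tr, ...)
  rot <- segmented_scene(lapply(sc$traces, move, angle = 0.83,
                                shift = c(-4321, 9876)),
                         scene_id = "rot")
  rotated <- measure_scene(rot)$metrics
  for (col in c("P_nm", "L_nm", "D_nm", "ermicc_per_nm")) {
    expect_equal(rotated[[col]], base[[col]], tolerance = 1e-6)
  }

  # uniform scaling by s doubles L, P, D and halves ERMICC up to band
  # quantization (bounded by step/D)
  sc2 <- segmented_scene(lapply(sc$traces, move, scale = 2),
                         scene_id = "scaled")
  cfg2 <- band_config(step_nm = 2, n_bands = 30L, resample_step_nm = 0.2)
  scaled <- measure_scene(sc2, cfg2)$metrics
  expect_equal(scaled$P_nm, 2 * base$P_nm, tolerance = 1e-9)
  expect_equal(scaled$L_nm, 2 * base$L_nm, tolerance = 1e-6)
  expect_equal(scaled$D_nm, 2 * base$D_nm, tolerance = 1e-6)
  expect_equal(scaled$ermicc_per_nm, base$ermicc_per_nm / 2,
               tolerance = 1e-6)
})

test_that("moving ER away from the MOM never increases L or decreases D", {
  # arc centred on the top of the circle; rigid upward translation
  # increases every point's distance to the MOM
  circ <- circle_trace(500, n = 720L)
  arc0 <- concentric_arc_trace(500, 8, 0.2, n = 720L,
                               phi0 = pi / 2 - 0.2 * pi)
  prev_L <- Inf; prev_D <- 0
  for (shift in c(0, 4, 8, 12, 16)) {
    arc <- membrane_trace(sweep(arc0$vertices, 2L, c(0, shift), "+"),
                          role = "ER")
    bp <- compute_band_profile(circ, arc)
    L <- compute_total_contact_length(bp)
    D <- compute_average_distance(bp)
    expect_lte(L, prev_L + 1e-9)
    if (L > 0) {
      expect_gte(D, prev_D - 1e-9)
      prev_D <- D
    }
    prev_L <- L
  }
})

test_that("measure_mitochondrion and measure_scene assemble full records", {
  circ <- circle_trace(500, n = 720L)
  m0 <- measure_mitochondrion(circ, list())
  expect_equal(m0$L_nm, 0)
  expect_equal(m0$ermicc_per_nm, 0)
  expect_true(m0$zero_contact)
  expect_true(is.na(m0$D_nm))

  sc <- segmented_scene(list(circ, concentric_arc_trace(500, 15, 0.25,
                                                        n = 720L)),
                        scene_id = "sc", cell_id = "c1", group = "WT")
  res <- measure_scene(sc)
  expect_named(res, c("metrics", "bands"))
  expect_equal(res$metrics$group, "WT")
  expect_equal(nrow(res$bands), 30L)
  expect_equal(res$bands$L_i_nm[30L], res$metrics$L_nm)
  th <- (pi / 2) * 515
  expect_rel_equal(res$metrics$ermicc_per_nm,
                   th / (2 * pi * 500 * 15), 0.01)
})
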