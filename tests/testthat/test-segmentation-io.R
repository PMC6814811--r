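make_square_csv <- function(path, pixel_units = TRUE) {
  df <- data.frame(scene_id = "s1", object_id = "mom_1", role = "MOM",
                   vertex_index = 1:4,
                   x = c(0, 100, 100, 0), y = c(0, 0, 100, 100),
                   closed = TRUE,
                   units = if (pixel_units) "px" else "nm")
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("polyline tables read with pixel calibration and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  make_square_csv(f)
  sc <- read_polyline_table(f, pixel_size_nm = 1)
  expect_s3_class(sc, "segmented_scene")
  expect_equal(perimeter(sc$traces[[1L]]), 400)

  sc2 <- read_polyline_table(f, pixel_size_nm = 2)
  expect_equal(perimeter(sc2$traces[[1L]]), 800)

  # round trip preserves vertices to well below 1e-6 nm
  g <- generate_scene(scene_spec(seed = 3, n_mitochondria = 2))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_polyline_table(g$scene, f2)
  back <- read_polyline_table(f2, pixel_size_nm = g$scene$pixel_size_nm)
  orig <- g$scene$traces[order(vapply(g$scene$traces, `[[`, "", "object_id"))]
  got <- back$traces[order(vapply(back$traces, `[[`, "", "object_id"))]
  for (i in seq_along(orig)) {
    expect_lt(max(abs(orig[[i]]$vertices - got[[i]]$vertices)), 1e-6)
    expect_equal(orig[[i]]$closed, got[[i]]$closed)
  }
})

test_that("malformed polyline tables fail with the offending object named", {
  df <- data.frame(scene_id = "s1", object_id = "er_7", role = "ER",
                   vertex_index = 1L, x = 0, y = 0, closed = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_error(read_polyline_table(f), "er_7")

  df2 <- data.frame(scene_id = "s1", object_id = "x_1", role = "NUCLEUS",
                    vertex_index = 1:2, x = c(0, 1), y = c(0, 1),
                    closed = FALSE)
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_polyline_table(f), "role")

  write.csv(df2[, -3L], f, row.names = FALSE)
  expect_error(read_polyline_table(f), "missing columns")
})

disk_mask <- function(nrow_px, ncol_px, cx, cy, r, label = 1L) {
  m <- matrix(0L, nrow_px, ncol_px)
  for (row in seq_len(nrow_px)) {
    dx2 <- ((seq_len(ncol_px) - 1L) - cx)^2
    sel <- dx2 + ((row - 1L) - cy)^2 <= r^2
    m[row, sel] <- label
  }
  m
}

test_that("extract_contours recovers disk geometry at sub-pixel accuracy", {
  m <- disk_mask(121, 121, 60, 60, 50)
  tr <- extract_contours(m, pixel_size_nm = 1)
  expect_length(tr, 1L)
  expect_true(tr[[1L]]$closed)
  expect_rel_equal(perimeter(tr[[1L]]), 2 * pi * 50, 0.01)
  # orientation normalised counter-clockwise: positive shoelace area
  expect_gt(contactq:::signed_area(tr[[1L]]$vertices), 0)

  big <- disk_mask(441, 441, 220, 220, 200)
  trb <- extract_contours(big, pixel_size_nm = 1)
  expect_rel_equal(abs(contactq:::signed_area(trb[[1L]]$vertices)),
                   pi * 200^2, 0.005)
})

test_that("extract_contours handles tiny regions, holes and border contact", {
  m <- matrix(0L, 5L, 5L)
  m[3L, 3L] <- 1L
  tr <- extract_contours(m, pixel_size_nm = 1)
  expect_length(tr, 1L)
  expect_gt(perimeter(tr[[1L]]), 0)

  # annulus: interior hole ignored with a warning
  ann <- disk_mask(121, 121, 60, 60, 40)
  hole <- disk_mask(121, 121, 60, 60, 15)
  ann[hole > 0] <- 0L
  expect_warning(tra <- extract_contours(ann, pixel_size_nm = 1), "hole")
  expect_length(tra, 1L)
  expect_rel_equal(perimeter(tra[[1L]]), 2 * pi * 40, 0.02)

  border <- matrix(0L, 10L, 10L)
  border[1L, 4:6] <- 1L
  expect_error(extract_contours(border, pixel_size_nm = 1), "border")
})

test_that("read_label_masks builds scenes from written TIFF masks", {
  mom <- disk_mask(161, 161, 80, 80, 50)
  mom[disk_mask(161, 161, 30, 30, 12, 2L) > 0] <- 2L
  f_mom <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(mom, f_mom)

  sc <- read_label_masks(f_mom, pixel_size_nm = 1)
  moms <- contactq:::scene_traces(sc, "MOM")
  expect_length(moms, 2L)
  expect_length(contactq:::scene_traces(sc, "ER"), 0L)

  # all-zero ER mask: scene with MOM traces only
  er0 <- matrix(0L, 161L, 161L)
  f_er <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(er0, f_er)
  sc2 <- read_label_masks(f_mom, f_er, pixel_size_nm = 1)
  expect_length(contactq:::scene_traces(sc2, "ER"), 0L)

  expect_error(read_label_masks(matrix(0L, 4L, 4L)), "empty")
  expect_error(read_label_masks(mom, matrix(0L, 10L, 10L)), "shapes")
})

test_that("contour extraction then rasterization reproduces the mask", {
  m <- disk_mask(121, 121, 60, 60, 25)
  tr <- extract_contours(m, pixel_size_nm = 1)[[1L]]
  refill <- contactq:::fill_polygon(tr$vertices, 0, 0, 1, 121L, 121L)
  agree <- mean((m > 0) == refill)
  expect_gte(agree, 0.99)
})
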