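test_that("manual thresholding puts pixels on the requested vessel side", {
  z <- matrix(0, 8, 8)
  expect_warning(
    fr <- threshold_frame(z, "manual", level = 10, dark_vessels = FALSE),
    "intensity range")
  expect_equal(frame_density(fr), 0)
  # dark-vessel default: darker-than-threshold is foreground
  g <- matrix(c(rep(20, 32), rep(200, 32)), 8, 8)
  fr2 <- threshold_frame(g, "manual", level = 100)
  expect_equal(sum(fr2$pixels), 32)
  expect_true(all(fr2$pixels[g < 100]))
})

test_that("Otsu separates a two-valued image exactly and rejects constants", {
  g <- matrix(20, 10, 10)
  g[, 6:10] <- 200
  fr <- threshold_frame(g, "otsu")
  expect_true(all(fr$pixels[g == 20]))
  expect_true(all(!fr$pixels[g == 200]))
  expect_error(threshold_frame(matrix(7, 5, 5), "otsu"),
               class = "vasculonet_degenerate_input")
})

test_that("thresholding a noisy rendered frame recovers the mask", {
  g <- generate_vascular_graph(40, "tree", seed = 21,
                               region_size_mm = c(300, 300) * 0.0064)
  truth <- render_graph(g, c(300, 300), vessel_width_px = 3)
  gray <- ifelse(truth$pixels, 60, 190)
  set.seed(1)
  gray <- gray + matrix(rnorm(length(gray), sd = 5), nrow(gray))
  fr <- threshold_frame(gray, "otsu")
  expect_lt(mean(fr$pixels != truth$pixels), 0.01)
})

test_that("area filter, connectivity and counts follow particle analysis", {
  px <- 0.0064
  m <- matrix(FALSE, 40, 40)
  m[2, 2:3] <- TRUE                       # 2 px = 8.2e-5 mm^2, excluded
  cs <- label_clusters(binary_frame(m, px))
  expect_equal(cs$n_clusters, 0)
  expect_equal(cs$excluded_count, 1)

  m2 <- matrix(FALSE, 40, 40)
  m2[2:11, 2:11] <- TRUE                  # 100 px blob
  m2[25:34, 25:34] <- TRUE                # second 100 px blob
  cs2 <- label_clusters(binary_frame(m2, px))
  expect_equal(cs2$n_clusters, 2)
  expect_equal(sort(cs2$areas_mm2), rep(100 * px^2, 2))

  # diagonal touch joins under 8-connectivity, splits under 4
  m3 <- matrix(FALSE, 30, 30)
  m3[10:14, 10:14] <- TRUE
  m3[15:19, 15:19] <- TRUE
  expect_equal(label_clusters(binary_frame(m3, px))$n_clusters, 1)
  expect_equal(label_clusters(binary_frame(m3, px), connectivity = 4)$n_clusters, 2)
})

test_that("frame statistics compute densities and the percolation parameter", {
  px <- 0.0064
  full <- binary_frame(matrix(TRUE, 20, 20), px)
  st <- frame_stats(label_clusters(full), full)
  expect_equal(st$rho, 1)
  expect_equal(st$rho_lc, 1)
  expect_equal(st$n_clusters, 1)

  empty <- binary_frame(matrix(FALSE, 20, 20), px)
  st0 <- frame_stats(label_clusters(empty), empty)
  expect_equal(st0$rho, 0)
  expect_equal(st0$rho_lc, 0)

  # 300 px and 100 px blobs in a 1000-px frame: rho 0.4, rho_lc 0.3
  m <- matrix(FALSE, 20, 50)
  m[1:15, 1:20] <- FALSE
  m[1:10, 1:30] <- TRUE   # 300 px
  m[15:19, 35:54 - 10] <- TRUE  # 100 px
  fr <- binary_frame(m, px)
  cs <- label_clusters(fr)
  expect_equal(cs$n_clusters, 2)
  st2 <- frame_stats(cs, fr)
  expect_equal(st2$rho, 0.4)
  expect_equal(st2$rho_lc, 0.3)
})

test_that("cluster-area bookkeeping is internally consistent", {
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(runif(80 * 80) < 0.35, 80, 80)
    fr <- binary_frame(m, 0.0064)
    cs <- label_clusters(fr)
    st <- frame_stats(cs, fr)
    expect_lte(st$rho_lc, st$rho)
    total <- length(m) * fr$px_size_mm^2
    expect_equal(sum(cs$areas_mm2), st$rho * total, tolerance = 1e-12)
    expect_lte(st$largest_area_mm2, st$rho * total + fr$px_size_mm^2)
    # single retained cluster iff rho_lc equals rho
    expect_equal(cs$n_clusters == 1,
                 isTRUE(all.equal(st$rho_lc, st$rho)) && st$rho > 0)
  }
})

test_that("box counting recovers plane and line dimensions", {
  full <- binary_frame(matrix(TRUE, 512, 512))
  expect_equal(box_counting_dimension(full)$d_f, 2, tolerance = 0.05)
  m <- matrix(FALSE, 512, 512)
  m[256, ] <- TRUE
  expect_equal(box_counting_dimension(binary_frame(m))$d_f, 1, tolerance = 0.05)
  expect_error(box_counting_dimension(binary_frame(matrix(FALSE, 300, 300))),
               class = "vasculonet_undefined_estimate")
  expect_error(box_counting_dimension(full, max_box = 600),
               class = "vasculonet_invalid_input")
})

test_that("box counting is stable under whole-box translation", {
  g <- generate_vascular_graph(40, "tree", seed = 31)
  fr <- render_graph(g, c(420, 420), vessel_width_px = 3)
  pat <- fr$pixels[1:292, 1:292]
  a <- b <- matrix(FALSE, 420, 420)
  a[1:292, 1:292] <- pat
  b[129:420, 129:420] <- pat   # translated by one 128-box in each axis
  da <- box_counting_dimension(binary_frame(a), max_box = 128)$d_f
  db <- box_counting_dimension(binary_frame(b), max_box = 128)$d_f
  expect_equal(da, db, tolerance = 0.05)
})

test_that("frames round-trip through PNG", {
  g <- generate_vascular_graph(20, "tree", seed = 41,
                               region_size_mm = c(150, 150) * 0.0064)
  fr <- render_graph(g, c(150, 150), vessel_width_px = 2)
  path <- tempfile(fileext = ".png")
  write_frame_png(fr, path)
  back <- read_frame_png(path, px_size_mm = fr$px_size_mm)
  expect_identical(back$pixels, fr$pixels)
  unlink(path)
})
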