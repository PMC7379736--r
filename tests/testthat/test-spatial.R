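bb_unit <- c(lat_min = 0, lat_max = 1, lon_min = 0, lon_max = 1)

test_that("one site owns the whole box; two sites split at the bisector", {
  m1 <- thiessen_polygons(list(site_location("A", 0.4, 0.3)), bb_unit)
  a <- polygon_areas(m1)
  expect_length(m1$polygons, 1L)
  expect_equal(sum(a) / sum(polygon_areas(m1)), 1)

  m2 <- thiessen_polygons(list(site_location("A", 0.5, 0.25),
                               site_location("B", 0.5, 0.75)), bb_unit)
  a2 <- polygon_areas(m2)
  expect_equal(unname(a2["A"] / sum(a2)), 0.5, tolerance = 1e-9)
  # every vertex of the shared edge sits at lon = 0.5
  shared_a <- m2$polygons$A[abs(m2$polygons$A[, "lon"] - 0.5) < 1e-9, ]
  expect_equal(nrow(shared_a), 2L)
})

test_that("cells tile the box and are permutation invariant", {
  set.seed(55)
  sites <- lapply(1:28, function(i)
    site_location(sprintf("S%02d", i), runif(1, 28, 37.5),
                  runif(1, 90.5, 101)))
  m <- thiessen_polygons(sites)
  a <- polygon_areas(m)
  km_lat <- 111.195
  km_lon <- km_lat * cos(mean(c(27.75, 37.75)) * pi / 180)
  box_area <- (37.75 - 27.75) * km_lat * (101.25 - 90.25) * km_lon
  expect_equal(sum(a), box_area, tolerance = 1e-6)

  m_perm <- thiessen_polygons(rev(sites))
  for (id in names(m$polygons)) {
    p1 <- m$polygons[[id]]; p2 <- m_perm$polygons[[id]]
    expect_equal(nrow(p1), nrow(p2))
    # same vertex set up to rotation of the ring
    o1 <- p1[order(p1[, 1], p1[, 2]), , drop = FALSE]
    o2 <- p2[order(p2[, 1], p2[, 2]), , drop = FALSE]
    expect_equal(o1, o2, tolerance = 1e-9)
  }
})

test_that("Monte-Carlo points land in their nearest site's polygon", {
  set.seed(56)
  sites <- lapply(1:15, function(i)
    site_location(sprintf("S%02d", i), runif(1, 0.05, 0.95),
                  runif(1, 0.05, 0.95)))
  m <- thiessen_polygons(sites, bb_unit)
  slat <- vapply(sites, `[[`, 0, "latitude")
  slon <- vapply(sites, `[[`, 0, "longitude")
  ids <- vapply(sites, `[[`, "", "site_id")
  px <- runif(2000); py <- runif(2000)
  for (i in 1:2000) {
    d2 <- (px[i] - slon)^2 + (py[i] - slat)^2
    o <- order(d2)
    if (d2[o[2]] - d2[o[1]] < 1e-6) next  # skip boundary-epsilon points
    expect_true(oracle_in_convex(px[i], py[i], m$polygons[[ids[o[1]]]]))
  }
})

test_that("degenerate and invalid configurations are handled", {
  col <- list(site_location("A", 0.2, 0.2), site_location("B", 0.5, 0.5),
              site_location("C", 0.8, 0.8))
  m <- thiessen_polygons(col, bb_unit)     # collinear sites still tile
  expect_equal(sum(polygon_areas(m)),
               sum(polygon_areas(thiessen_polygons(col[1], bb_unit))),
               tolerance = 1e-9)

  expect_error(thiessen_polygons(list(site_location("A", 0.5, 0.5),
                                      site_location("B", 0.5, 0.5)),
                                 bb_unit), "duplicate site coordinates")
  expect_error(thiessen_polygons(list(site_location("A", 5, 5)), bb_unit),
               "no site inside")
})

test_that("classify_area splits the box area at the cut", {
  sites <- list(site_location("A", 0.5, 0.25), site_location("B", 0.5, 0.75))
  m <- thiessen_polygons(sites, bb_unit)
  sm <- data.frame(site_id = c("A", "B"), event_year = 1969L,
                   P_high_Rt = c(0.9, 0.2), P_high_Rc = c(0.8, 0.9))
  m <- attach_site_values(m, sm, 1969)
  expect_equal(unname(classify_area(m, "P_high_Rt")["high"]), 0.5,
               tolerance = 1e-9)
  expect_equal(unname(classify_area(m, "P_high_Rc")["high"]), 1.0)
  expect_error(classify_area(thiessen_polygons(sites, bb_unit), "P_high_Rt"),
               "no metric values")
})

test_that("GeoJSON export round-trips polygon vertices and properties", {
  sites <- list(site_location("A", 0.5, 0.25), site_location("B", 0.5, 0.75))
  m <- thiessen_polygons(sites, bb_unit)
  sm <- data.frame(site_id = c("A", "B"), event_year = 1969L,
                   P_high_Rt = c(0.9, 0.2), P_high_Rc = c(0.8, 0.9))
  m <- attach_site_values(m, sm, 1969)
  f <- withr::local_tempfile(fileext = ".geojson")
  export_geojson(m, f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 2L)
  ft <- gj$features[[1L]]
  expect_equal(ft$properties$site_id, "A")
  expect_equal(ft$properties$P_high_Rt, 0.9)
  ring <- ft$geometry$coordinates[[1L]]
  expect_equal(ring[[1L]], ring[[length(ring)]])   # closed ring
  verts <- do.call(rbind, lapply(ring[-length(ring)], unlist))
  orig <- m$polygons$A
  expect_equal(verts[order(verts[, 1], verts[, 2]), ],
               unname(orig[order(orig[, 1], orig[, 2]), ]),
               tolerance = 1e-12)

  m_bare <- thiessen_polygons(sites, bb_unit)
  expect_warning(export_geojson(m_bare, f), "no metric values")
})
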