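# GeoJSON reading/writing and coastline derivation (Stage 0).

write_fixture_geojson <- function(path, features, crs = "EPSG:3035") {
  obj <- list(type = "FeatureCollection")
  if (!is.null(crs))
    obj$crs <- list(type = "name", properties = list(name = crs))
  obj$features <- features
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10), path)
}

gj_square <- function(x0, y0, s = 1, code = "312", extra = list()) {
  ring <- list(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s),
               c(x0, y0))
  list(type = "Feature", properties = c(list(CODE_18 = code), extra),
       geometry = list(type = "Polygon", coordinates = list(ring)))
}

test_that("a valid layer reads into a landcover with ids, codes and areas", {
  path <- withr::local_tempfile(fileext = ".geojson")
  write_fixture_geojson(path, list(gj_square(0, 0), gj_square(1, 0, code = "112"),
                                   gj_square(2, 0, code = "211")))
  map <- read_lulc(path, "CODE_18")
  expect_s3_class(map, "landcover")
  expect_length(map, 3)
  expect_equal(map$ids, c("f0", "f1", "f2"))
  expect_equal(map$codes, c("312", "112", "211"))
  expect_equal(unname(map$areas), rep(1, 3))
})

test_that("multi-part features explode into suffixed single-part patches", {
  path <- withr::local_tempfile(fileext = ".geojson")
  ringA <- list(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  ringB <- list(c(5, 0), c(6, 0), c(6, 1), c(5, 1), c(5, 0))
  mp <- list(type = "Feature", properties = list(CODE_18 = "312"),
             geometry = list(type = "MultiPolygon",
                             coordinates = list(list(ringA), list(ringB))))
  write_fixture_geojson(path, list(mp))
  map <- read_lulc(path, "CODE_18")
  expect_equal(map$ids, c("f0_0", "f0_1"))
  expect_equal(map$codes, c("312", "312"))
})

test_that("a bow-tie feature is repaired into valid positive-area parts", {
  path <- withr::local_tempfile(fileext = ".geojson")
  bow <- list(type = "Feature", properties = list(CODE_18 = "312"),
              geometry = list(type = "Polygon",
                              coordinates = list(list(c(0, 0), c(2, 1), c(2, 0),
                                                      c(0, 1), c(0, 0)))))
  write_fixture_geojson(path, list(gj_square(5, 5), bow))
  map <- read_lulc(path, "CODE_18")
  want <- shapely_eval("
from shapely.geometry import Polygon
from shapely.validation import make_valid
print(make_valid(Polygon([(0,0),(2,1),(2,0),(0,1)])).area)")
  got <- sum(map$areas[startsWith(map$ids, "f1")])
  expect_equal(got, want, tolerance = 1e-9)
  expect_true(all(startsWith(attr(map, "repaired"), "f1")))
})

test_that("schema, CRS, format and empty-layer problems raise clear errors", {
  path <- withr::local_tempfile(fileext = ".geojson")
  write_fixture_geojson(path, list(gj_square(0, 0)))
  expect_error(read_lulc(path, "code_12"), "available fields.*CODE_18")
  write_fixture_geojson(path, list(gj_square(0, 0)), crs = NULL)
  expect_error(read_lulc(path, "CODE_18"), "geographic")
  expect_s3_class(read_lulc(path, "CODE_18", allow_geographic = TRUE),
                  "landcover")
  write_fixture_geojson(path, list())
  expect_error(read_lulc(path, "CODE_18"), "empty")
  expect_error(read_lulc(sub("geojson$", "shp", path), "CODE_18"),
               "format|no such file")
})

test_that("sea-mode coastline is the dissolved sea/land shared boundary", {
  # land square [0,10]x[0,10], sea square [-10,0]x[0,10]
  map <- make_map(list(rect_poly(0, 0, 10, 10), rect_poly(-10, 0, 0, 10)),
                  c("312", "523"))
  co <- derive_coastline(map, sea_codes = "523")
  expect_equal(co$length, 10)
  expect_equal(co$excluded_ids, "p2")
  # every coastline segment lies on the sea patch boundary (zero-area
  # contact with patch interiors)
  sea_segs <- coastband:::poly_segments(map$geoms[[2]])
  expect_equal(coastband:::shared_boundary_length(co$segments, sea_segs),
               co$length)
})

test_that("an L-shaped sea wrapping two sides doubles the coastline length", {
  land <- rect_poly(0, 0, 10, 10)
  sea <- list(matrix(c(-10, -10, 10, -10, 10, 0, 0, 0, 0, 10, -10, 10),
                     ncol = 2, byrow = TRUE))
  map <- make_map(list(land, sea), c("312", "523"))
  co <- derive_coastline(map, sea_codes = "523")
  want <- shapely_eval("
from shapely.geometry import Polygon
land = Polygon([(0,0),(10,0),(10,10),(0,10)])
sea = Polygon([(-10,-10),(10,-10),(10,0),(0,0),(0,10),(-10,10)])
print(land.boundary.intersection(sea.boundary).length)")
  expect_equal(co$length, want, tolerance = 1e-9)
  expect_equal(co$length, 20)
})

test_that("sea-mode length matches the boundary-intersection oracle on random rectangle strips", {
  set.seed(11)
  for (rep in 1:5) {
    # a row of land rectangles of random widths over a common sea rectangle
    xs <- cumsum(c(0, runif(4, 1, 5)))
    geoms <- lapply(seq_len(4), function(i) rect_poly(xs[i], 0, xs[i + 1], 3))
    geoms <- c(geoms, list(rect_poly(min(xs) - 1, -4, max(xs) + 1, 0)))
    map <- make_map(geoms, c(rep("312", 4), "523"))
    co <- derive_coastline(map, sea_codes = "523")
    expect_equal(co$length, max(xs) - min(xs), tolerance = 1e-9)
  }
})

test_that("split-point mode returns a boundary arc of the dissolved polygon", {
  map <- make_map(list(rect_poly(0, 0, 5, 5), rect_poly(5, 0, 10, 5)),
                  c("312", "311"))
  co <- derive_coastline(map, split_points = list(c(0, 0), c(10, 0)))
  # ccw arc from (0,0) to (10,0) on the dissolved 10x5 rectangle is the
  # bottom edge; the cw arc is the complementary path over the top
  expect_equal(co$length, 10)
  co2 <- derive_coastline(map, split_points = list(c(0, 0), c(10, 0)),
                          direction = "cw")
  expect_equal(co2$length, 20)
  expect_error(derive_coastline(map), "sea_codes or split_points")
})

test_that("read-write-read round trip preserves ids, codes, bands and areas", {
  g <- generate_landscape(synth_spec(4, 5, seed = 3))
  res <- run_pipeline(g$map, coast = g$coast)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_outputs(g$map, res$table, path)
  back <- read_lulc(path, "CODE_18")
  expect_equal(back$ids, g$map$ids)
  expect_equal(back$codes, g$map$codes)
  expect_equal(back$areas, g$map$areas, tolerance = 1e-6)
  # the band attribute survives the round trip
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  got_bands <- vapply(obj$features, function(f) f$properties$band, 0)
  expect_equal(got_bands, unname(res$table$band))
  expect_error(write_outputs(g$map, res$table, path, format = "gpkg"),
               "unknown output format")
})
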