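# Stage 4A (cross-tab, endangered hinges) and Stage 4B (barriers).

test_that("cross-tab counts members per (band, TCD) cell and conserves totals", {
  # no members at all
  g0 <- generate_landscape(synth_spec(3, 3, class_weights = c("112" = 1),
                                      seed = 1))
  s0 <- run_stage123(g0$map, g0$coast)
  ct0 <- cross_tabulate(s0$bands, s0$tcd)
  expect_true(all(ct0$counts == 0))
  # single chain to band 8: 8 nonzero cells, all in the TCD-8 column
  fx <- worked_example_chain(1, 8)
  s <- run_stage123(fx$map, fx$coast)
  ct <- cross_tabulate(s$bands, s$tcd, fx$map)
  expect_equal(sum(ct$counts > 0), 8)
  expect_equal(unname(ct$counts[, 8]), c(rep(1L, 8), 0L, 0L))
  expect_equal(sum(ct$counts), sum(s$mosaics$member))
  expect_equal(sum(ct$areas), sum(fx$map$areas))
  # CSV serialization round-trips the counts
  path <- withr::local_tempfile(fileext = ".csv")
  write_crosstab(ct, path)
  back <- utils::read.csv(path)
  expect_equal(unname(as.matrix(back[, -1])), unname(ct$counts))
})

test_that("cross-tab lower triangle (TCD < band) is structurally zero", {
  for (seed in 51:56) {
    g <- random_landscape(seed)
    s <- run_stage123(g$map, g$coast)
    ct <- cross_tabulate(s$bands, s$tcd)
    expect_true(all(ct$counts[lower.tri(ct$counts)] == 0))
    expect_equal(sum(ct$counts), sum(s$mosaics$member))
  }
})

test_that("a chain hinge is flagged with the stranded patches as dependents", {
  fx <- worked_example_chain(1, 3)
  s <- run_stage123(fx$map, fx$coast)
  rep <- suppressWarnings(
    find_endangered(s$mosaics, s$bands, s$graph, s$tcd,
                    band_max = 4, tcd_min = 3))
  # the band-2 patch strands the band-3 patch; band-1 strands both
  expect_setequal(rep$id, c("r1_c1", "r2_c1"))
  r2 <- rep[rep$id == "r2_c1", ]
  expect_equal(r2$dependent_patch_ids[[1]], "r3_c1")
  expect_true(r2$unique_in_band_within_mosaic)
})

test_that("a singular band-2 link between corridors is flagged, redundant links are not", {
  # two deep corridors joined to the coast only through the hinge column:
  # columns 1 and 3 natural at depth but artificial at the hinge row
  art <- c("112" = 1)
  g <- generate_landscape(synth_spec(6, 3, class_weights = art, seed = 1,
                                     motifs = list(hinge(2, 2),
                                                   corridor(1, 1),
                                                   corridor(3, 1))))
  s <- run_stage123(g$map, g$coast)
  rep <- find_endangered(s$mosaics, s$bands, s$graph, s$tcd,
                         band_max = 4, tcd_min = 5)
  expect_true("r2_c2" %in% rep$id)
  flagged <- rep[rep$id == "r2_c2", ]
  expect_true(all(s$bands[flagged$dependent_patch_ids[[1]]] > 2))
  # removal oracle: full Stage-2 re-run with the hinge artificialized
  map2 <- g$map
  map2$codes[match("r2_c2", map2$ids)] <- "112"
  s2 <- run_stage123(map2, g$coast)
  lost <- setdiff(names(which(s$mosaics$member)),
                  c(names(which(s2$mosaics$member)), "r2_c2"))
  expect_setequal(flagged$dependent_patch_ids[[1]], lost)

  # redundant band-2 links: two band-2 patches both feed the same deep
  # corridor, so neither strands anything on its own
  map <- make_map(list(rect_poly(0, 0, 3, 1),    # band-1 shore strip
                       rect_poly(0, 1, 1, 2),    # band-2 link west
                       rect_poly(1, 1, 2, 2),    # band-2 artificial middle
                       rect_poly(2, 1, 3, 2),    # band-2 link east
                       rect_poly(0, 2, 3, 3),    # band-3 wide natural
                       rect_poly(1, 3, 2, 4)),   # band-4 inland
                  c("311", "312", "112", "313", "321", "323"),
                  ids = c("shore", "linkW", "mid", "linkE", "deep", "top"))
  sb <- run_stage123(map, flat_coast(3))
  rep2 <- suppressWarnings(
    find_endangered(sb$mosaics, sb$bands, sb$graph, sb$tcd,
                    band_max = 4, tcd_min = 4))
  expect_false(any(c("linkW", "linkE") %in% rep2$id))
  expect_true("shore" %in% rep2$id)
})

test_that("endangered dependents always match the full Stage-2 removal oracle", {
  for (seed in 61:66) {
    g <- random_landscape(seed)
    s <- run_stage123(g$map, g$coast)
    rep <- suppressWarnings(
      find_endangered(s$mosaics, s$bands, s$graph, s$tcd,
                      band_max = 4, tcd_min = 4))
    for (r in seq_len(nrow(rep))) {
      p <- rep$id[r]
      map2 <- g$map
      map2$codes[match(p, map2$ids)] <- "112"
      s2 <- run_stage123(map2, g$coast)
      lost <- setdiff(names(which(s$mosaics$member)),
                      c(names(which(s2$mosaics$member)), p))
      expect_setequal(rep$dependent_patch_ids[[r]], lost)
      expect_true(all(s$bands[rep$dependent_patch_ids[[r]]] > s$bands[[p]]))
    }
  }
})

test_that("a vacuously wide endangered screen warns", {
  fx <- worked_example_chain(1, 2)
  s <- run_stage123(fx$map, fx$coast)
  expect_warning(find_endangered(s$mosaics, s$bands, s$graph, s$tcd,
                                 band_max = 5, tcd_min = 3),
                 "not selective")
})

test_that("barriers are artificial band-1 patches fronting reachable natural depth", {
  art <- c("112" = 1)
  # artificial band-1 patch fronting a natural chain in bands 2..6
  g <- generate_landscape(synth_spec(6, 1, class_weights = art, seed = 1,
                                     motifs = list(barrier(1, 6))))
  s <- run_stage123(g$map, g$coast)
  rep <- find_barriers(g$map, s$bands, s$graph)
  expect_equal(rep$id, "r1_c1")
  expect_equal(rep$unlocked_depth, 6)
  expect_setequal(rep$unlocked_member_ids[[1]], paste0("r", 2:6, "_c1"))
  expect_true(all(s$bands[rep$unlocked_member_ids[[1]]] >= 2))
  # an artificial band-1 patch with only artificial neighbors is no barrier
  g2 <- generate_landscape(synth_spec(3, 1, class_weights = art, seed = 1))
  s2 <- run_stage123(g2$map, g2$coast)
  expect_equal(nrow(find_barriers(g2$map, s2$bands, s2$graph)), 0)
  # natural band-1 patches are never seeds
  g3 <- worked_example_chain(1, 3)
  s3 <- run_stage123(g3$map, g3$coast)
  expect_equal(nrow(find_barriers(g3$map, s3$bands, s3$graph)), 0)
})

test_that("exclude_already_connected ignores mosaics that already reach the coast", {
  # a wide natural band-2 patch touching a natural band-1 patch (so it is
  # already a TCNLM member) and an artificial band-1 patch
  map <- make_map(list(square_poly(0, 0), square_poly(1, 0),
                       rect_poly(0, 1, 2, 2)),
                  c("311", "112", "312"))
  s <- run_stage123(map, flat_coast(2))
  expect_true(s$mosaics$member[["p3"]])
  rep_off <- find_barriers(map, s$bands, s$graph)
  expect_equal(rep_off$id, "p2")
  rep_on <- find_barriers(map, s$bands, s$graph,
                          exclude_already_connected = TRUE)
  expect_equal(nrow(rep_on), 0)
})

test_that("barrier flags are invariant under patch id permutation", {
  g <- random_landscape(71)
  s <- run_stage123(g$map, g$coast)
  rep1 <- find_barriers(g$map, s$bands, s$graph)
  set.seed(2)
  perm <- sample(length(g$map$ids))
  m2 <- g$map
  m2$ids <- g$map$ids[perm]; m2$codes <- g$map$codes[perm]
  m2$geoms <- g$map$geoms[perm]; m2$areas <- g$map$areas[perm]
  s2 <- run_stage123(m2, g$coast)
  rep2 <- find_barriers(m2, s2$bands, s2$graph)
  expect_setequal(rep1$id, rep2$id)
})
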