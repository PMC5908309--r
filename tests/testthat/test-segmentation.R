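test_that("a blank DAPI raster yields zero nuclei", {
  nmap <- segment_nuclei(matrix(0L, 80, 80), 0.4)
  expect_identical(nmap$n, 0L)
  expect_true(all(nmap$labels == 0L))
})

test_that("well-separated synthetic nuclei are recovered with correct areas", {
  cfg <- synthetic_config(n_cells = 20, field_px = c(600, 600),
                          microns_per_pixel = 0.4, seed = 11)
  g <- generate_field(cfg)
  nmap <- segment_nuclei(g$field$channels$DAPI, 0.4)
  expect_identical(nmap$n, 20L)
  # match detected to true nuclei by centroid (within 3 um)
  truth <- g$truth$cells
  for (i in seq_len(nrow(truth))) {
    d_um <- sqrt((nmap$centroids[, "row"] - truth$center_row[i])^2 +
                 (nmap$centroids[, "col"] - truth$center_col[i])^2) * 0.4
    j <- which.min(d_um)
    expect_lt(d_um[j], 3)
    expect_lt(abs(nmap$areas_um2[j] - truth$area_um2[i]) / truth$area_um2[i],
              0.10)
  }
})

test_that("touching nuclei are split by the watershed", {
  # two disks whose borders touch along a narrow neck
  nr <- 80
  img <- matrix(500L, nr, nr)
  lab <- disk_labels(nr, nr, cbind(c(40, 40), c(25, 44), c(10, 10)))
  img[lab > 0] <- 10000L
  nmap <- segment_nuclei(img, 0.5)
  expect_identical(nmap$n, 2L)
  cents <- nmap$centroids[order(nmap$centroids[, "col"]), ]
  expect_lt(sqrt(sum((cents[1, ] - c(40, 25))^2)) * 0.5, 3)
  expect_lt(sqrt(sum((cents[2, ] - c(40, 44))^2)) * 0.5, 3)
})

test_that("area filtering retains exactly the in-window nuclei", {
  # three square nuclei of 30, 120 and 250 px^2 at 1 um/px
  lab <- matrix(0L, 60, 60)
  lab[2:6, 2:7] <- 1L          # 30 um^2: below window
  lab[20:29, 20:31] <- 2L      # 120 um^2: inside
  lab[40:49, 35:59] <- 3L      # 250 um^2: above
  nmap <- nucleus_label_map(lab, 1)
  filt <- filter_nuclei_by_area(nmap, 50, 200)
  expect_identical(names(filt$areas_um2), "2")
  expect_identical(unname(filt$areas_um2), 120)
  # removal only: surviving pixels unchanged
  expect_identical(filt$labels == 2L, lab == 2L)
  # identity when all areas fit, and idempotence
  all_in <- filter_nuclei_by_area(nmap, 1, 1000)
  expect_identical(all_in$labels, nmap$labels)
  expect_identical(filter_nuclei_by_area(filt, 50, 200)$labels, filt$labels)
  # empty map passes through; inverted bounds are rejected
  empty <- nucleus_label_map(matrix(0L, 5, 5), 1)
  expect_identical(filter_nuclei_by_area(empty, 50, 200)$n, 0L)
  expect_error(filter_nuclei_by_area(nmap, 200, 50), "inverted")
})

test_that("window bounds are inclusive on both sides", {
  lab <- matrix(0L, 40, 60)
  lab[2:6, 2:11] <- 1L     # exactly 50 px^2
  lab[20:29, 20:39] <- 2L  # exactly 200 px^2
  lab[35, 2] <- 3L         # 1 px^2
  nmap <- nucleus_label_map(lab, 1)
  filt <- filter_nuclei_by_area(nmap, 50, 200)
  expect_setequal(names(filt$areas_um2), c("1", "2"))
})

test_that("ring width selection follows the contested-fraction rule", {
  # sparse pair: nearest borders far beyond 12 um -> maximum width
  sparse <- disk_labels(120, 120, cbind(c(30, 90), c(30, 90), c(8, 8)))
  nsp <- nucleus_label_map(sparse, 0.5)
  expect_identical(auto_select_ring_width(nsp), 5L)
  expect_identical(oracle_ring_width(sparse, 0.5), 5L)
  # dense grid: every nucleus has a neighbour border within ~1 um
  centers <- expand.grid(r = c(20, 32, 44, 56), c = c(20, 32, 44, 56))
  dense <- disk_labels(76, 76, cbind(centers$r, centers$c, 5))
  nde <- nucleus_label_map(dense, 0.5)
  wd <- auto_select_ring_width(nde)
  expect_identical(wd, oracle_ring_width(dense, 0.5))
  expect_identical(wd, 1L)
  expect_true(wd >= 1 && wd <= 5)
  expect_error(auto_select_ring_width(nucleus_label_map(matrix(0L, 5, 5), 1)),
               "empty")
})

test_that("ring masks equal the exhaustive border-distance oracle", {
  mpp <- 0.4
  # isolated nucleus at widths 1, 3, 5
  iso <- disk_labels(70, 70, cbind(35, 35, 9))
  niso <- nucleus_label_map(iso, mpp)
  for (w in c(1, 3, 5)) {
    impl <- make_cytoplasm_rings(niso, w)$ring_labels
    expect_identical(impl, oracle_ring_labels(iso, w, mpp))
  }
  # two nuclei ~2 um apart: midline pixels split by nearest-border rule
  pair <- disk_labels(90, 110, cbind(c(45, 45), c(35, 60), c(10, 10)))
  npair <- nucleus_label_map(pair, mpp)
  for (w in c(1, 3, 5)) {
    impl <- make_cytoplasm_rings(npair, w)$ring_labels
    expect_identical(impl, oracle_ring_labels(pair, w, mpp))
  }
  # an elongated (non-convex border geometry) shape as well
  ell <- matrix(0L, 60, 60)
  ell[25:35, 10:50] <- 1L
  ell[28:32, 20:40] <- 1L
  nell <- nucleus_label_map(ell, mpp)
  expect_identical(make_cytoplasm_rings(nell, 3)$ring_labels,
                   oracle_ring_labels(ell, 3, mpp))
})

test_that("rings are monotone in width and never overlap nuclei", {
  iso <- disk_labels(70, 70, cbind(35, 35, 9))
  niso <- nucleus_label_map(iso, 0.4)
  r1 <- make_cytoplasm_rings(niso, 1)$ring_labels
  r3 <- make_cytoplasm_rings(niso, 3)$ring_labels
  expect_true(all(r3[r1 > 0] > 0))          # containment
  expect_gt(sum(r3 > 0), sum(r1 > 0))       # strict growth
  expect_error(make_cytoplasm_rings(niso, 7), "\\[1, 5\\]")
  expect_error(make_cytoplasm_rings(niso, 0.5), "\\[1, 5\\]")
  # generated field: rings within background, each cell's ring near its own
  # nucleus only
  g <- generate_field(synthetic_config(n_cells = 40, field_px = c(760, 760),
                                       microns_per_pixel = 0.4, seed = 5))
  nmap <- segment_nuclei(g$field$channels$DAPI, 0.4)
  rings <- make_cytoplasm_rings(nmap, 4)
  expect_true(all(nmap$labels[rings$ring_labels > 0] == 0L))
})
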