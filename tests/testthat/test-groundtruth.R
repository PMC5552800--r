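make_disk <- function(H, W, r0, c0, radius, value = 1, base = NULL) {
  out <- if (is.null(base)) matrix(0, H, W) else base
  d2 <- outer((seq_len(H) - r0)^2, (seq_len(W) - c0)^2, `+`)
  out[d2 <= radius^2] <- value
  out
}

test_that("average projection is the pixelwise mean", {
  p <- list(matrix(0, 4, 4), matrix(1, 4, 4), matrix(2, 4, 4))
  expect_identical(average_project(p), matrix(1, 4, 4))
  expect_identical(average_project(list(p[[2]], p[[2]])), p[[2]])
  set.seed(1)
  zs <- lapply(1:3, function(i) matrix(runif(64), 8, 8))
  expect_identical(average_project(zs), (zs[[1]] + zs[[2]] + zs[[3]]) / 3)
  expect_error(average_project(list()), "non-empty")
})

test_that("a single bright disk segments into one nucleus", {
  img <- make_disk(64, 64, 32, 32, 10) + 0.02
  lab <- segment_nuclei(img, groundtruth_config())
  expect_identical(sort(unique(as.vector(lab))), c(0L, 1L))
  area <- sum(lab == 1)
  expect_gt(area, 0.8 * pi * 100)
  expect_lt(area, 1.2 * pi * 100)
  expect_identical(lab[32, 32], 1L)
})

test_that("touching nuclei are split by the distance-transform watershed", {
  img <- make_disk(64, 96, 32, 30, 10)
  img <- make_disk(64, 96, 32, 54, 10, base = img)
  img[31:33, 38:46] <- 1   # 3-px bridge fusing the disks
  lab_split <- segment_nuclei(img, groundtruth_config(split_touching = TRUE))
  expect_identical(max(lab_split), 2L)
  expect_false(lab_split[32, 30] == lab_split[32, 54])
  lab_fused <- segment_nuclei(img, groundtruth_config(split_touching = FALSE))
  expect_identical(max(lab_fused), 1L)
})

test_that("empty fields give an empty mask with a warning", {
  ## contrast-free image
  expect_warning(lab <- segment_nuclei(matrix(0.5, 32, 32)), "contrast-free")
  expect_true(all(lab == 0))
  ## a lone speck removed by the size filter
  img <- matrix(0, 32, 32); img[5, 5] <- 1
  expect_warning(lab2 <- segment_nuclei(img, groundtruth_config(
    min_nucleus_area = 25)), "no nuclei")
  expect_true(all(lab2 == 0))
})

test_that("scene nuclei are recovered one-to-one with the simulator truth", {
  sc <- fixture_scene()
  pair <- fixture_pair()
  n_true <- max(sc$truth)
  expect_identical(max(pair$nuclei), n_true)
  ## each true nucleus centroid carries a distinct label
  hits <- integer(0)
  for (k in seq_len(n_true)) {
    pos <- which(sc$nuclei_truth == k, arr.ind = TRUE)
    ctr <- round(colMeans(pos))
    hits <- c(hits, pair$nuclei[ctr[1], ctr[2]])
  }
  expect_identical(sort(hits), 1:n_true)
})

test_that("cells grow from nuclear seeds and keep their seed ids", {
  cyto <- make_disk(64, 64, 32, 32, 16, value = 0.7) + 0.05
  nuclei <- matrix(0L, 64, 64)
  nuclei[make_disk(64, 64, 32, 32, 5) > 0] <- 1L
  cells <- segment_cells(cyto, nuclei, groundtruth_config())
  expect_identical(sort(unique(as.vector(cells))), c(0L, 1L))
  expect_true(all(cells[nuclei == 1] == 1L))
  expect_gte(sum(cells == 1), sum(nuclei == 1))
})

test_that("two seeds partition a fused cytoplasm blob", {
  cyto <- make_disk(64, 96, 32, 34, 16, value = 0.7)
  cyto <- make_disk(64, 96, 32, 60, 16, value = 0.7, base = cyto) + 0.05
  nuclei <- matrix(0L, 64, 96)
  nuclei[make_disk(64, 96, 32, 34, 4) > 0] <- 1L
  nuclei[make_disk(64, 96, 32, 60, 4) > 0] <- 2L
  cells <- segment_cells(cyto, nuclei, groundtruth_config())
  expect_setequal(unique(cells[cells > 0]), c(1L, 2L))
  ## seeds keep their ids; the blob is partitioned without overlap
  expect_true(all(cells[nuclei == 1] == 1L))
  expect_true(all(cells[nuclei == 2] == 2L))
  expect_identical(cells[32, 34], 1L)
  expect_identical(cells[32, 60], 2L)
})

test_that("empty seeds give an empty cell mask with a warning", {
  cyto <- matrix(0.5, 32, 32)
  expect_warning(cells <- segment_cells(cyto, matrix(0L, 32, 32)),
                 "no nuclear seeds")
  expect_true(all(cells == 0))
})

test_that("automatic cell masks agree with simulator truth (Jaccard >= 0.7)", {
  sc <- fixture_scene()
  pair <- fixture_pair()
  for (k in seq_len(max(sc$truth))) {
    inter <- pair$labels[sc$truth == k]
    top <- as.integer(names(which.max(table(inter[inter > 0]))))
    a <- sc$truth == k; b <- pair$labels == top
    expect_gte(sum(a & b) / sum(a | b), 0.7)
  }
})

test_that("training pairs satisfy the per-mode data/label contracts", {
  pair <- fixture_pair()
  expect_identical(dim(pair$data)[3], 3L)
  expect_setequal(unique(pair$labels[pair$labels > 0]),
                  unique(pair$nuclei[pair$nuclei > 0]))
  ## every nucleus pixel keeps its id inside the cell mask
  nz <- pair$nuclei > 0
  expect_true(all(pair$labels[nz] == pair$nuclei[nz]))

  spec5 <- scene_spec(width = 160, height = 160, n_cells = 6,
                      min_center_distance = 38, rng_seed = 8,
                      mode = "multichannel5")
  pair5 <- suppressWarnings(build_training_pairs(generate_scene(spec5)))
  expect_identical(dim(pair5$data)[3], 4L)
  expect_identical(pair5$labels, pair5$nuclei)
})

test_that("an empty scene produces a valid pair with an empty label image", {
  spec <- scene_spec(width = 96, height = 96, n_cells = 0,
                     cell_radius_range = c(8, 10),
                     nucleus_radius_range = c(3, 4), rng_seed = 3)
  sc <- generate_scene(spec)
  pair <- suppressWarnings(build_training_pairs(sc))
  expect_true(all(pair$labels == 0))
  expect_identical(dim(pair$data)[1:2], c(96L, 96L))
})

test_that("raising min_nucleus_area never increases the nucleus count", {
  sc <- fixture_scene()
  nuc <- average_project(sc$nuclei_channel)
  counts <- vapply(c(0, 20, 60, 200, 1000), function(a) {
    lab <- suppressWarnings(
      segment_nuclei(nuc, groundtruth_config(min_nucleus_area = a)))
    max(lab)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
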