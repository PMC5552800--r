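test_that("mirror extension is nine-fold with symmetric reflections", {
  set.seed(1)
  img <- matrix(runif(100 * 200), 100, 200)
  ext <- mirror_extend(img)
  expect_identical(dim(ext), c(300L, 600L))
  expect_identical(ext[101:200, 201:400], img)
  ## reflection index oracle on sampled positions (border pixel included)
  for (i in sample(100, 5)) for (j in sample(200, 5)) {
    expect_identical(ext[101 - i, 200 + j], img[i, j])   # top block
    expect_identical(ext[100 + i, 201 - j], img[i, j])   # left block
    expect_identical(ext[301 - i, 200 + j], img[i, j])   # bottom block
  }
  ## bottom block mirrors the last row first
  expect_identical(ext[201, 201:400], img[100, ])
  expect_identical(ext[300, 201:400], img[1, ])
  ## channels are extended consistently
  arr <- array(img, c(100, 200, 2))
  ext3 <- mirror_extend(arr)
  expect_identical(ext3[, , 1], ext)
})

test_that("random flips move data and label pixels together", {
  set.seed(2)
  data <- array(runif(20 * 30 * 2), c(20, 30, 2))
  label <- matrix(0L, 20, 30); label[3, 5] <- 1L
  data[3, 5, 1] <- 99
  fl <- random_flip(data, label, flip_lr_prob = 1, flip_ud_prob = 1)
  expect_true(fl$flipped_lr && fl$flipped_ud)
  expect_identical(which(fl$label == 1L, arr.ind = TRUE)[1, ],
                   c(row = 18L, col = 26L))
  expect_identical(fl$data[18, 26, 1], 99)
  ## flipping twice with the same forced decisions is the identity
  fl2 <- random_flip(fl$data, fl$label, 1, 1)
  expect_identical(fl2$data, data)
  expect_identical(fl2$label, label)
  ## zero probabilities never flip
  fl0 <- random_flip(data, label, 0, 0)
  expect_identical(fl0$data, data)
})

test_that("random crops take the same window from data and label", {
  set.seed(3)
  coord <- outer(1:40, 1:40, function(r, c) r * 1000 + c)
  data <- array(coord, c(40, 40, 1))
  cr <- random_crop(data, coord, 16)
  expect_identical(cr$data[, , 1], cr$label)
  expect_identical(cr$label,
                   coord[cr$offset[1]:(cr$offset[1] + 15),
                         cr$offset[2]:(cr$offset[2] + 15)])
  ## full-size crop returns the whole image
  cr_full <- random_crop(data, coord, 40)
  expect_identical(cr_full$label, coord)
  expect_error(random_crop(data, coord, 41), "exceeds")
})

test_that("crop offsets are approximately uniform over valid positions", {
  set.seed(4)
  data <- array(0, c(30, 30, 1)); label <- matrix(0, 30, 30)
  n <- 4000
  offs <- replicate(n, random_crop(data, label, 11)$offset[1])
  tab <- tabulate(offs, nbins = 20)
  chi2 <- sum((tab - n / 20)^2 / (n / 20))
  expect_lt(chi2, qchisq(1 - 1e-5, df = 19))
  expect_identical(sort(unique(offs)), 1:20)
})

test_that("normalization maps to [0,1] then centers the median at zero", {
  x <- matrix(c(0, 5, 10), 1, 3)
  expect_equal(normalize_data(x), matrix(c(-0.5, 0, 0.5), 1, 3))
  set.seed(5)
  y <- matrix(rnorm(200), 10, 20)
  ny <- normalize_data(y)
  expect_equal(stats::median(ny), 0)
  expect_true(all(ny >= -1 & ny <= 1))
  ## idempotent up to floating tolerance
  expect_equal(normalize_data(ny), ny, tolerance = 1e-12)
  expect_warning(nz <- normalize_data(matrix(3, 4, 4)), "constant")
  expect_true(all(nz == 0))
})

test_that("weight images balance the classes with the foreground factor", {
  lab <- matrix(c(1, 1, 0, 0), 2, 2)   # N_fg == N_bg
  w <- make_weight_image(lab, 3)
  expect_true(all(w[lab == 1] == 3) && all(w[lab == 0] == 1))
  lab2 <- matrix(0L, 4, 4); lab2[1:4] <- 1L   # N_bg = 3 N_fg
  w2 <- make_weight_image(lab2, 3)
  expect_equal(unique(w2[lab2 == 1]), 9)
  ## factor 1: weighted masses equal exactly
  set.seed(6)
  lab3 <- matrix(rbinom(400, 1, 0.3), 20, 20)
  w3 <- make_weight_image(lab3, 1)
  expect_identical(sum(w3[lab3 == 1]), sum(w3[lab3 == 0]))
  expect_warning(wu <- make_weight_image(matrix(1L, 3, 3)), "single-class")
  expect_true(all(wu == 1))
})

test_that("dataset builds are deterministic and samples satisfy the contract", {
  pair <- fixture_pair()
  cfg <- augment_config(patch_size = 64, patches_per_image = 6, rng_seed = 42)
  ds1 <- suppressWarnings(build_dataset(list(pair), cfg))
  ds2 <- suppressWarnings(build_dataset(list(pair), cfg))
  expect_identical(unclass(ds1), unclass(ds2))
  expect_length(ds1, 6)
  for (s in ds1) {
    expect_identical(dim(s$data), c(64L, 64L, 3L))
    expect_identical(dim(s$label), c(64L, 64L))
    expect_true(all(s$label %in% c(0L, 1L)))
    expect_true(all(s$weight > 0))
    for (c in 1:3) {
      expect_equal(stats::median(s$data[, , c]), 0)
      expect_true(all(abs(s$data[, , c]) <= 1))
    }
    if (any(s$label == 1) && any(s$label == 0))
      expect_identical(sum(s$weight[s$label == 1]),
                       3 * sum(s$weight[s$label == 0]))
  }
})

test_that("dataset serialization round-trips through RDS and TIFF layouts", {
  pair <- fixture_pair()
  ds <- suppressWarnings(build_dataset(
    list(pair), augment_config(patch_size = 48, patches_per_image = 2,
                               rng_seed = 7)))
  f <- withr::local_tempfile(fileext = ".rds")
  write_dataset(ds, f)
  expect_identical(unclass(read_dataset(f)), unclass(ds))
  d <- withr::local_tempdir()
  write_dataset(ds, d, format = "tiff")
  expect_true(file.exists(file.path(d, "sample00001", "data.tif")))
  expect_true(file.exists(file.path(d, "config.yaml")))
  lab <- read_label_tiff(file.path(d, "sample00002", "label.tif"))
  expect_identical(lab, ds[[2]]$label)
})
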