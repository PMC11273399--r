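test_that("binarize thresholds intensities and is idempotent", {
  expect_equal(binarize(matrix(0, 4, 4)), matrix(FALSE, 4, 4))
  img <- matrix(c(0, 255, 255, 0), 2, 2)
  expect_equal(binarize(img, 0), img == 255)
  # random grid equals the elementwise comparison oracle at several thresholds
  set.seed(1)
  g <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  for (t in c(0, 17, 128, 254)) {
    expect_identical(binarize(g, t), g > t)
  }
  b <- binarize(g, 100)
  expect_identical(binarize(b * 255, 0), b)
  # colored multi-channel rasters collapse by channel maximum
  arr <- array(0, c(3, 3, 3))
  arr[1, 1, 2] <- 200
  expect_identical(binarize(arr)[1, 1], TRUE)
  expect_equal(sum(binarize(arr)), 1)
  expect_error(binarize(matrix(numeric(0), 0, 0)), "empty")
})

test_that("opening removes sub-kernel specks and preserves large regions", {
  m <- matrix(FALSE, 120, 120)
  m[60, 60] <- TRUE # isolated speck
  expect_equal(sum(morphological_open(m, 70)), 0)
  big <- make_disc_mask(45, 120, 120, 60, 60)
  kept <- morphological_open(big, 70)
  expect_gt(sum(kept), 0.95 * sum(big))
})

test_that("opening equals the brute-force sliding min/max oracle", {
  withr::with_seed(3, {
    for (size in c(3, 7, 14)) {
      m <- make_blob_mask(4, 60, 60, rmin = 2, rmax = 8)
      expect_identical(morphological_open(m, size), oracle_open(m, size),
                       label = sprintf("element size %d", size))
    }
  })
  # the pipeline's element size on a mid-sized fixture
  sq <- matrix(FALSE, 300, 300)
  sq[30:250, 40:260] <- TRUE
  sq[20:24, 20:24] <- TRUE # speck the element must wipe
  expect_identical(morphological_open(sq, 70), oracle_open(sq, 70))
})

test_that("opening is idempotent and anti-extensive", {
  withr::with_seed(8, {
    for (i in 1:5) {
      m <- make_blob_mask(5, 70, 70, rmin = 2, rmax = 12)
      o <- morphological_open(m, 9)
      expect_identical(morphological_open(o, 9), o)
      expect_true(all(which(o) %in% which(m)))
    }
  })
})

test_that("opening rejects elements larger than the image", {
  expect_error(morphological_open(matrix(TRUE, 10, 10), 70), "larger than")
})

test_that("largest_component keeps the biggest blob with deterministic ties", {
  m <- matrix(FALSE, 40, 40)
  m[2:11, 2:11] <- TRUE    # 100 px
  m[30:34, 30] <- TRUE     # 5 px
  lc <- largest_component(m)
  expect_equal(sum(lc), 100)
  expect_true(all(which(lc) %in% which(m)))
  single <- make_disc_mask(6, 30, 30, 15, 15)
  expect_identical(largest_component(single), single)
  expect_error(largest_component(matrix(FALSE, 5, 5)), "no animal")
  # equal-size tie: the component with the earliest top-left pixel wins
  tie <- matrix(FALSE, 10, 10)
  tie[2:3, 2:3] <- TRUE
  tie[7:8, 7:8] <- TRUE
  expect_identical(which(largest_component(tie)), which(tie)[1:4])
})

test_that("component labelling matches a flood-fill oracle", {
  withr::with_seed(21, {
    for (i in 1:6) {
      m <- make_blob_mask(sample(2:5, 1), 50, 50)
      lab <- pigwt:::label_components_cpp(m, 8L)
      ora <- oracle_label(m, 8)
      expect_equal(attr(lab, "n_components"), max(ora))
      # same partition: label images agree up to renaming
      for (k in seq_len(max(ora)))
        expect_equal(length(unique(lab[ora == k])), 1)
      # the package keeps the same pixels the oracle's largest component has
      counts <- tabulate(ora[ora > 0])
      if (length(unique(counts)) == length(counts)) {
        expect_identical(largest_component(m), ora == which.max(counts))
      }
    }
  })
})

test_that("contour tracing covers exactly the boundary pixels", {
  # single pixel
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  ct <- extract_contour(m1)
  expect_equal(nrow(ct), 1)
  expect_equal(c(ct$row, ct$col), c(3, 3))
  # filled 3x3 square: the 8 border pixels, centre excluded
  m2 <- matrix(FALSE, 5, 5); m2[2:4, 2:4] <- TRUE
  ct2 <- extract_contour(m2)
  expect_equal(nrow(ct2), 8)
  expect_false(any(ct2$row == 3 & ct2$col == 3))
  # random blobs: set equality with the brute-force boundary scan
  withr::with_seed(5, {
    for (i in 1:6) {
      m <- largest_component(make_blob_mask(2, 60, 60, rmin = 4, rmax = 12))
      ct <- extract_contour(m)
      got <- sort(unique(paste(ct$row, ct$col)))
      want <- oracle_boundary_set(m)
      expect_identical(got, sort(unique(paste(want[, 1], want[, 2]))))
      # consecutive points are 8-adjacent and the loop closes
      d <- cbind(diff(c(ct$row, ct$row[1])), diff(c(ct$col, ct$col[1])))
      expect_true(all(pmax(abs(d[, 1]), abs(d[, 2])) <= 1))
    }
  })
})

test_that("contour tracing starts topmost-then-leftmost, clockwise, and is stable", {
  m <- make_disc_mask(8, 30, 30, 15, 15)
  ct <- extract_contour(m)
  top <- which(m, arr.ind = TRUE)
  top <- top[order(top[, 1], top[, 2]), ][1, ]
  expect_equal(unlist(ct[1, ]), c(row = top[[1]], col = top[[2]]))
  expect_gte(ct$col[2], ct$col[1]) # clockwise leaves the start towards the east
  expect_identical(extract_contour(m), ct)
  expect_error(extract_contour(matrix(FALSE, 4, 4)), "empty")
  two <- matrix(FALSE, 9, 9); two[2, 2] <- TRUE; two[7, 7] <- TRUE
  expect_error(extract_contour(two), "multiple components")
})

test_that("mask PNG round-trips exactly", {
  withr::with_seed(4, {
    m <- make_blob_mask(2, 40, 40)
    f <- withr::local_tempfile(fileext = ".png")
    write_mask_png(m, f)
    back <- read_mask_png(f)
    expect_identical(binarize(back, 0), m)
    expect_true(all(back %in% c(0, 255)))
  })
})
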