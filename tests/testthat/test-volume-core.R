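test_that("raw round-trip is the identity for gray, binary and label volumes", {
  tmp <- withr::local_tempdir()
  set.seed(1)
  g <- gray_volume(array(sample.int(256, 16^3, TRUE) - 1L, c(16, 16, 16)),
                   voxel_size = 2.5)
  p <- file.path(tmp, "g.raw")
  write_volume(g, p)
  back <- read_volume(p)
  expect_identical(back$data, g$data)
  expect_equal(back$voxel_size, 2.5)
  expect_equal(back$bits, 8L)

  b <- binary_volume(array(runif(10^3) < 0.4, c(10, 10, 10)), voxel_size = 1.8)
  pb <- file.path(tmp, "b.raw")
  write_volume(b, pb)
  backb <- read_volume(pb)
  expect_identical(array(backb$data > 0, dim(b$data)), b$data)

  l <- label_volume(array(rep(0:300, length.out = 8^3), c(8, 8, 8)))
  pl <- file.path(tmp, "l.raw")
  write_volume(l, pl)
  backl <- read_volume(pl)
  expect_equal(backl$bits, 16L)  # 300 labels need the 16-bit container
  expect_identical(backl$data, l$data)
})

test_that("tiff round-trip is bitwise lossless and matches raw", {
  tmp <- withr::local_tempdir()
  set.seed(2)
  for (bits in c(8L, 16L)) {
    g <- gray_volume(array(sample.int(2^bits, 12 * 10 * 7, TRUE) - 1L,
                           c(12, 10, 7)), voxel_size = 3, bits = bits)
    pt <- file.path(tmp, sprintf("g%d.tif", bits))
    pr <- file.path(tmp, sprintf("g%d.raw", bits))
    write_volume(g, pt)
    write_volume(g, pr)
    vt <- read_volume(pt, meta = list(voxel_size_um = 3))
    vr <- read_volume(pr)
    expect_identical(vt$data, g$data)
    expect_identical(vt$data, vr$data)
    expect_equal(vt$bits, bits)
  }
})

test_that("tiff stacks agree with an independent reader", {
  tmp <- withr::local_tempdir()
  set.seed(3)
  g <- gray_volume(array(sample.int(256, 32 * 32 * 10, TRUE) - 1L,
                         c(32, 32, 10)), voxel_size = 1)
  p <- file.path(tmp, "stack.tif")
  write_volume(g, p)
  v <- read_volume(p, meta = list(voxel_size_um = 1))
  expect_equal(dim(v$data), c(32L, 32L, 10L))
  img <- EBImage::readImage(p)            # independent TIFF reader
  ed <- dim(img)
  expect_equal(prod(ed), 32 * 32 * 10)
  expect_equal(ed[length(ed)], 10)        # 10 frames
  # EBImage normalises 8-bit to [0,1] and stores frames as [x, y]
  expect_equal(round(EBImage::imageData(img)[, , 1] * 255), g$data[, , 1],
               ignore_attr = TRUE)
})

test_that("size arithmetic and unsupported formats are rejected", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "v.raw")
  writeBin(as.raw(rep(0, 4096)), p)
  ok <- read_volume(p, meta = list(nx = 16, ny = 16, nz = 16, bits = 8,
                                   voxel_size_um = 1))
  expect_equal(dim(ok$data), c(16L, 16L, 16L))
  expect_error(read_volume(p, meta = list(nx = 16, ny = 16, nz = 17, bits = 8,
                                          voxel_size_um = 1)),
               "malformed")
  expect_error(read_volume(p, meta = list(nx = 16, ny = 16, nz = 16, bits = 12,
                                          voxel_size_um = 1)),
               "unsupported")
  expect_error(read_volume(file.path(tmp, "missing.raw")), "not found")
})

test_that("crop_voi equals direct indexing and composes additively", {
  set.seed(4)
  g <- gray_volume(array(sample.int(256, 14^3, TRUE) - 1L, c(14, 14, 14)),
                   voxel_size = 2)
  full <- crop_voi(g, c(0, 0, 0), dim(g$data))
  expect_identical(full$data, g$data)
  one <- crop_voi(g, c(0, 0, 0), c(1, 1, 1))
  expect_equal(as.integer(one$data), g$data[1, 1, 1])
  for (i in 1:20) {
    o <- vapply(dim(g$data), function(n) sample.int(n, 1) - 1L, integer(1))
    s <- vapply(dim(g$data) - o, function(n) sample.int(n, 1), integer(1))
    cr <- crop_voi(g, o, s)
    expect_identical(cr$data,
                     g$data[o[1] + seq_len(s[1]), o[2] + seq_len(s[2]),
                            o[3] + seq_len(s[3]), drop = FALSE])
    expect_equal(cr$voxel_size, g$voxel_size)
    # double crop with summed origins
    if (all(s >= 2)) {
      cr2 <- crop_voi(cr, c(1, 1, 1), s - 1L)
      expect_identical(cr2$data, crop_voi(g, o + 1L, s - 1L)$data)
    }
  }
  expect_error(crop_voi(g, c(-1, 0, 0), c(2, 2, 2)), "out of bounds")
  expect_error(crop_voi(g, c(10, 10, 10), c(6, 6, 6)), "out of bounds")
})

test_that("volume constructors enforce their invariants", {
  expect_error(gray_volume(array(-1L, c(2, 2, 2))), "non-negative")
  expect_error(gray_volume(array(300L, c(2, 2, 2)), bits = 8), "bit depth")
  expect_error(gray_volume(array(0L, c(2, 2))), "3D")
  expect_error(binary_volume(array(0L, c(2, 2, 2)), voxel_size = -1),
               "voxel_size")
  lv <- label_volume(array(c(0L, 5L, 9L, 5L, 0L, 0L, 9L, 2L), c(2, 2, 2)))
  expect_equal(lv$n_labels, 3L)
  expect_setequal(unique(as.integer(lv$data)), c(0L, 1L, 2L, 3L))
})
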