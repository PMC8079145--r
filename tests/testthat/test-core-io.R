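test_that("trace tables round-trip bit-exactly and validate their contract", {
  tr <- mkRawTrace(c(1, 1, 1, 0.1, 0.3), bleachEnd = 4L, dt = 1.644)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTraceTable(tr, path)
  back <- readTraceTable(path)
  expect_identical(back@time, tr@time)
  expect_identical(unname(back@bleach), unname(tr@bleach))
  expect_identical(back@background, tr@background)
  expect_identical(back@reference, tr@reference)
  expect_identical(back@bleachEnd, tr@bleachEnd)
  expect_equal(nFrames(back), 5L)

  ## awkward doubles survive the round trip exactly
  tr2 <- mkRawTrace(c(1/3, pi, exp(1), 2^-30, 1 + 2^-50), bleachEnd = 2L)
  writeTraceTable(tr2, path)
  expect_identical(unname(readTraceTable(path)@bleach[, 1]),
                   unname(tr2@bleach[, 1]))
})

test_that("trace reader rejects malformed tables by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,f_bleach,f_background",
               "0,1,0", "1,1,0"), path)
  expect_error(readTraceTable(path, bleachEnd = 2),
               "f_reference", class = "mfFormatError")

  ## non-uniform grid beyond 1%
  writeLines(c("time_s,f_bleach,f_background,f_reference",
               "0,1,0,1", "1,1,0,1", "2.5,1,0,1", "3.5,0,0,1"), path)
  expect_error(readTraceTable(path, bleachEnd = 4), "non-uniform",
               class = "mfValidationError")

  ## missing bleach-end metadata
  writeLines(c("time_s,f_bleach,f_background,f_reference",
               "0,1,0,1", "1,0,0,1"), path)
  expect_error(readTraceTable(path), "bleach_end", class = "mfFormatError")
})

test_that("ROI extraction averages pixel-center disks correctly", {
  ## constant field
  stack <- array(7, dim = c(20, 20, 3))
  rois <- data.frame(center_x = c(10, 3, 17), center_y = c(10, 3, 17),
                     radius = c(4, 2, 2),
                     kind = c("bleach", "background", "reference"))
  tr <- extractRoiTraces(stack, rois, bleachEnd = 2L)
  expect_equal(unname(tr@bleach[, 1]), rep(7, 3))
  expect_equal(tr@background, rep(7, 3))

  ## disk of value 100 on background 10, ROI exactly on the disk
  frame <- matrix(10, 30, 30)
  for (i in 1:30) for (j in 1:30)
    if ((j - 15)^2 + (i - 15)^2 <= 5^2) frame[i, j] <- 100
  stack <- array(frame, dim = c(30, 30, 2))
  stack[, , 2] <- 0
  stack[, , 2][frame == 100] <- 50
  rois <- data.frame(center_x = c(15, 5, 25), center_y = c(15, 5, 25),
                     radius = c(5, 2, 2),
                     kind = c("bleach", "background", "reference"))
  tr <- extractRoiTraces(stack, rois, bleachEnd = 2L)
  expect_equal(unname(tr@bleach[1, 1]), 100)
  expect_equal(unname(tr@bleach[, 1]), c(100, 50))
})

test_that("ROI extraction equals the brute-force per-pixel oracle", {
  set.seed(41)
  for (rep in 1:5) {
    stack <- array(stats::runif(12 * 14 * 3), dim = c(12, 14, 3))
    cx <- stats::runif(1, 5, 9); cy <- stats::runif(1, 5, 8)
    r <- stats::runif(1, 1.5, 3.5)
    rois <- data.frame(center_x = c(cx, 3, 11), center_y = c(cy, 3, 9),
                       radius = c(r, 1.5, 1.5),
                       kind = c("bleach", "background", "reference"))
    tr <- extractRoiTraces(stack, rois, bleachEnd = 2L)
    for (f in 1:3)
      expect_equal(unname(tr@bleach[f, 1]),
                   bruteRoiMean(stack[, , f], cx, cy, r))
  }
})

test_that("ROI extraction rejects out-of-bounds and empty ROIs", {
  stack <- array(1, dim = c(10, 10, 2))
  roisOut <- data.frame(center_x = c(2, 5, 8), center_y = c(2, 5, 8),
                        radius = c(4, 1, 1),
                        kind = c("bleach", "background", "reference"))
  expect_error(extractRoiTraces(stack, roisOut, 2L), "outside",
               class = "mfValidationError")
})

test_that("TIFF stacks round-trip through the reader", {
  stack <- array(stats::runif(8 * 9 * 4), dim = c(8, 9, 4))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:4, function(k) stack[, , k]), path,
                  bits.per.sample = 32L)
  back <- readImageStack(path)
  expect_equal(dim(back), dim(stack))
  expect_equal(back, stack, tolerance = 1e-7)
})

test_that("localization tables validate coordinates and compute field area", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm,channel",
               "0,0,GLT1", "1000,0,GLT1", "0,1000,PSD95"), path)
  map <- readLocalizations(path)
  expect_setequal(channels(map), c("GLT1", "PSD95"))
  expect_equal(map@fieldArea, 1)  # 1000 nm x 1000 nm bounding box = 1 um^2

  writeLines(c("x_nm,y_nm", "0,0"), path)
  expect_error(readLocalizations(path), "channel", class = "mfFormatError")

  writeLines(c("x_nm,y_nm,channel", "-5,0,GLT1"), path)
  expect_error(readLocalizations(path, fieldArea = 1), "non-negative",
               class = "mfValidationError")

  writeLines(c("x_nm,y_nm,channel", "NaN,0,GLT1"), path)
  expect_error(readLocalizations(path, fieldArea = 1), "finite",
               class = "mfValidationError")
})

test_that("localization maps round-trip through write/read", {
  sim <- simulatePointPattern("poisson", area = 1, lambda = 100, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLocalizations(sim$map, path)
  back <- readLocalizations(path, fieldArea = 1)
  expect_identical(back@x, sim$map@x)
  expect_identical(back@y, sim$map@y)
})
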