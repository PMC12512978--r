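# Domain types, NIfTI/JSON I/O, and atlas preprocessing.

test_that("label volumes and masks round-trip through NIfTI", {
  a <- smallAtlas()
  hemi <- extractHemisphere(a, "left")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(hemi, path)
  back <- readLabelVolume(path)
  expect_identical(labelData(back), labelData(hemi))
  expect_lt(max(abs(affineMat(back) - affineMat(hemi))), 1e-5)

  m <- BinaryMask(labelData(hemi) > 0, affineMat(hemi))
  pm <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(m, pm)
  back2 <- readBinaryMask(pm)
  expect_identical(maskData(back2), maskData(m))

  # all-zero volume is a valid, empty label volume
  z <- tinyLabelVolume(array(0L, c(3, 3, 3)))
  pz <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(z, pz)
  expect_identical(labelSet(readLabelVolume(pz)), integer(0))
})

test_that("non-integer-valued volumes are rejected as label volumes", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  arr <- array(0, c(2, 2, 2)); arr[1] <- 2.5
  thalaseg:::.writeNiftiVolume(arr, diag(4), path)
  expect_error(readLabelVolume(path), "integer")
  expect_error(readLabelVolume(file.path(tempdir(), "does_not_exist.nii")),
               "not found")
})

test_that("tensor fields round-trip and are floored to SPD", {
  p <- patientFixture()
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeTensorField(p$field, path)
  back <- readTensorField(path)
  expect_equal(back@tensors, p$field@tensors, tolerance = 1e-5)
  idx <- which(maskData(back@support), arr.ind = TRUE)
  mins <- apply(idx, 1, function(v) {
    D <- thalaseg:::.sym6ToMat(back@tensors[v[1], v[2], v[3], ])
    min(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
  })
  expect_gt(min(mins), 0)
})

test_that("subnucleus tables round-trip through JSON and validate", {
  tb <- subnucleusData(smallAtlas())
  st <- SubnucleusTable(tb, atlasId = "rt")
  path <- withr::local_tempfile(fileext = ".json")
  writeSubnucleusTable(st, path)
  back <- readSubnucleusTable(path)
  expect_equal(subnucleusData(back), subnucleusData(st))
  expect_identical(atlasId(back), "rt")

  bad <- tb
  bad$label[bad$hemisphere == "left"][2] <- bad$label[bad$hemisphere == "left"][1]
  expect_error(SubnucleusTable(bad), "duplicate")
})

test_that("thalamus isolation removes excluded nuclei and small components", {
  a <- makeAtlas(6, 2, 1, seed = 3, atlasId = "gen", includeGeniculate = TRUE)
  hemi <- extractHemisphere(a, "left")
  tb <- a@table
  gIds <- subnucleusData(tb)$label[grepl("geniculate", subnucleusData(tb)$name)]
  expect_true(any(labelData(hemi) %in% gIds))
  iso <- isolateThalamus(hemi, tb,
                         excludedNames = c("medial_geniculate",
                                           "lateral_geniculate"),
                         minComponentVoxels = 1L)
  expect_false(any(labelData(iso) %in% gIds))
  expect_error(isolateThalamus(hemi, tb, excludedNames = "no_such_nucleus"),
               "not in table")

  # label with a 5x5x4 body and a 3-voxel speck; threshold removes the speck
  labs <- array(0L, c(12, 8, 6))
  labs[2:6, 2:6, 2:5] <- 1L          # 100-voxel body
  labs[10, 2, 2] <- 1L; labs[10, 3, 2] <- 1L; labs[10, 2, 3] <- 1L
  vol <- tinyLabelVolume(labs)
  tab <- SubnucleusTable(data.frame(label = 1L, name = "n1",
                                    class = "other", hemisphere = "left"))
  out <- isolateThalamus(vol, tab, minComponentVoxels = 10L)
  # brute-force component oracle: the body voxels survive, the speck dies
  expect_equal(sum(labelData(out) == 1L), 100L)
  expect_identical(labelData(out)[10, 2, 2], 0L)
  # threshold 1 is a no-op
  noop <- isolateThalamus(vol, tab, minComponentVoxels = 1L)
  expect_identical(labelData(noop), labs)
  # never increases any label's voxel count
  expect_lte(sum(labelData(out) == 1L), sum(labs == 1L))
  # emptying a label entirely warns
  tiny <- array(0L, c(4, 4, 4)); tiny[1, 1, 1] <- 1L
  expect_warning(
    isolateThalamus(tinyLabelVolume(tiny), tab, minComponentVoxels = 5L),
    "emptied")
})

test_that("hemisphere extraction returns disjoint nonempty sides", {
  a <- smallAtlas()
  left <- extractHemisphere(a, "left")
  right <- extractHemisphere(a, "right")
  expect_true(any(labelData(left) > 0))
  expect_true(any(labelData(right) > 0))
  expect_false(any(labelData(left) > 0 & labelData(right) > 0))

  empty <- tinyLabelVolume(array(0L, c(2, 2, 2)))
  b <- a
  b@right <- empty
  expect_error(extractHemisphere(b, "right"), "empty")
})

test_that("region masks are class unions, disjoint, with additive counts", {
  for (a in list(smallAtlas(), secondAtlas())) {
    hemi <- extractHemisphere(a, "left")
    motor <- buildRegionMask(hemi, a@table, "motor", "left")
    sensory <- buildRegionMask(hemi, a@table, "sensory", "left")
    expect_false(any(maskData(motor) & maskData(sensory)))
    tb <- subnucleusData(a)
    mlab <- tb$label[tb$hemisphere == "left" & tb$class == "motor"]
    # union count equals the sum of member label counts (labels disjoint)
    expect_identical(sum(maskData(motor)),
                     sum(vapply(mlab, function(l) sum(labelData(hemi) == l),
                                integer(1))))
  }
  # atlas with one motor label: region mask equals that label's mask
  a1 <- makeAtlas(4, 1, 1, seed = 9)
  hemi <- extractHemisphere(a1, "left")
  tb <- subnucleusData(a1)
  ml <- tb$label[tb$hemisphere == "left" & tb$class == "motor"]
  motor <- buildRegionMask(hemi, a1@table, "motor", "left")
  expect_identical(maskData(motor),
                   array(labelData(hemi) == ml, dim(labelData(hemi))))
  noSens <- SubnucleusTable(data.frame(label = 1L, name = "m", class = "motor",
                                       hemisphere = "left"))
  expect_error(buildRegionMask(hemi, noSens, "sensory"), "no subnuclei")
})

test_that("packaged atlas metadata drives counts and configurations", {
  md <- atlasMetadata()
  expect_setequal(md$abbreviation,
                  c("Jak08", "Ewt17", "Iln17", "Igl18", "Sar19", "Dng20"))
  expect_true(all(md$total >= 10 & md$total <= 46))
  jak <- md[md$abbreviation == "Jak08", ]
  a <- makeAtlas(jak$total, jak$motor, jak$sensory, seed = 11,
                 atlasId = "Jak08s")
  tb <- subnucleusData(a)
  expect_identical(sum(tb$hemisphere == "left" & tb$class == "motor"), 6L)
  expect_identical(sum(tb$hemisphere == "left" & tb$class == "sensory"), 4L)
  expect_identical(subnucleiCount(a@table), 32L)
  sar <- md[md$abbreviation == "Sar19", ]
  expect_identical(subnucleiCount(smallAtlas()@table), sar$total)
  single <- SubnucleusTable(data.frame(label = 1L, name = "s",
                                       class = "other", hemisphere = "left"))
  expect_identical(subnucleiCount(single), 1L)
})
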