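# Synthetic-data generator: determinism, ground-truth structure, tensor
# properties, VTA masks, cohort manifests.

test_that("atlas generation is deterministic and partitions the thalamus", {
  a1 <- makeAtlas(10, 4, 1, seed = 7)
  a2 <- makeAtlas(10, 4, 1, seed = 7)
  expect_identical(labelData(a1@left), labelData(a2@left))
  expect_identical(labelData(a1@right), labelData(a2@right))
  expect_identical(subnucleusData(a1), subnucleusData(a2))

  tb <- subnucleusData(a1)
  expect_identical(sum(tb$hemisphere == "left"), 10L)
  expect_identical(sum(tb$hemisphere == "left" & tb$class == "motor"), 4L)
  expect_identical(sum(tb$hemisphere == "left" & tb$class == "sensory"), 1L)

  # labels partition each hemisphere: every thalamic voxel exactly one label
  for (side in c("left", "right")) {
    lab <- labelData(extractHemisphere(a1, side))
    expect_setequal(setdiff(unique(as.vector(lab)), 0L), 1:10)
  }
})

test_that("patient generation respects the transform and surface noise", {
  a <- smallAtlas()
  # identity transform, zero noise: mask equals re-voxelized atlas support
  pat0 <- makePatient(a, "left", similarityTransform(), surfaceNoiseSd = 0,
                      seed = 1)
  hemi <- extractHemisphere(a, "left")
  reference <- transformLabels(hemi, similarityTransform(), pat0$mask)
  expect_identical(maskData(pat0$mask),
                   array(labelData(reference) > 0L,
                         dim(labelData(reference))))
  expect_identical(labelData(pat0$truth@labels), labelData(reference))
  expect_equal(voxelSize(pat0$mask), c(1, 1, 2))

  # the truth stores exactly the requested transform
  p <- patientFixture()
  expect_identical(p$truth@transform@translation, c(3, -2, 1))
  expect_identical(p$truth@transform@scale, 1.05)

  # truth labels partition the mask
  expect_identical(labelData(p$truth@labels) > 0L, maskData(p$mask))

  # volume within 15 % of scale^3 x atlas volume at zero noise
  tf <- p$transform
  patz <- makePatient(a, "left", tf, surfaceNoiseSd = 0, seed = 1)
  atlasVol <- sum(labelData(hemi) > 0) * prod(voxelSize(hemi))
  patVol <- sum(maskData(patz$mask)) * prod(voxelSize(patz$mask))
  expect_lt(abs(patVol - tf@scale^3 * atlasVol) / (tf@scale^3 * atlasVol),
            0.15)

  expect_error(makePatient(a, "left",
                           similarityTransform(scale = 1.5)))
  # supplied grid too small for the transformed thalamus
  smallGrid <- tinyMask(array(FALSE, c(4, 4, 4)))
  expect_error(makePatient(a, "left", similarityTransform(), seed = 1,
                           grid = smallGrid), "outside")
})

test_that("tensor fields have per-region structure and stay SPD", {
  p <- patientFixture()
  idx <- which(maskData(p$field@support), arr.ind = TRUE)
  mins <- apply(idx, 1, function(v) {
    D <- thalaseg:::.sym6ToMat(p$field@tensors[v[1], v[2], v[3], ])
    min(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
  })
  expect_gt(min(mins), 0)   # SPD over the full field

  # zero noise: all voxels of a region share one tensor exactly
  truth0 <- p$truth
  truth0@tensorParams <- lapply(truth0@tensorParams, function(x) {
    x$noiseSd <- 0; x
  })
  f0 <- makeTensorField(truth0, grid = p$mask, seed = 1)
  lab <- labelData(p$truth@labels)
  l1 <- labelSet(p$truth@labels)[1]
  sel <- which(lab == l1 & maskData(p$mask), arr.ind = TRUE)
  comps <- t(apply(sel, 1, function(v) f0@tensors[v[1], v[2], v[3], ]))
  expect_lt(max(apply(comps, 2, function(x) diff(range(x)))), 1e-12)

  # isotropic parameters give FA = 0 everywhere in that region
  truthIso <- p$truth
  truthIso@tensorParams <- lapply(truthIso@tensorParams, function(x) {
    x$eigenvalues <- c(1e-3, 1e-3, 1e-3); x$noiseSd <- 0; x
  })
  fIso <- makeTensorField(truthIso, grid = p$mask, seed = 1)
  v <- sel[1, ]
  K <- tensorShapeInvariants(fIso@tensors[v[1], v[2], v[3], ])
  expect_equal(unname(K), c(3e-3, 0, 0), tolerance = 1e-9)

  # orthogonal principal directions: within-region dyadic spread is
  # smaller than the between-region dyadic distance
  labs <- labelSet(p$truth@labels)[1:2]
  truth2 <- p$truth
  truth2@tensorParams[[as.character(labs[1])]]$direction <- c(1, 0, 0)
  truth2@tensorParams[[as.character(labs[2])]]$direction <- c(0, 1, 0)
  f2 <- makeTensorField(truth2, grid = p$mask, seed = 2)
  dyadOf <- function(v) orientationDyadic(f2@tensors[v[1], v[2], v[3], ])
  sel1 <- which(lab == labs[1] & maskData(p$mask), arr.ind = TRUE)
  sel2 <- which(lab == labs[2] & maskData(p$mask), arr.ind = TRUE)
  U1 <- lapply(seq_len(nrow(sel1)), function(i) dyadOf(sel1[i, ]))
  U2 <- lapply(seq_len(nrow(sel2)), function(i) dyadOf(sel2[i, ]))
  mean1 <- Reduce(`+`, U1) / length(U1)
  mean2 <- Reduce(`+`, U2) / length(U2)
  within1 <- mean(vapply(U1, function(u) sqrt(sum((u - mean1)^2)), 1))
  between <- sqrt(sum((mean1 - mean2)^2))
  expect_lt(within1, between)
})

test_that("VTA masks are voxelized ellipsoids", {
  grid <- tinyMask(array(FALSE, c(21, 21, 21)), origin = c(-10, -10, -10))
  v <- makeVta(c(0, 0, 0), c(2, 2, 2), grid)
  expect_equal(sum(maskData(v)), 4 / 3 * pi * 8, tolerance = 0.25)
  inner <- makeVta(c(0, 0, 0), c(1, 1, 1), grid)
  expect_true(all(maskData(v)[maskData(inner)]))          # nesting
  expect_gt(sum(maskData(v)), sum(maskData(inner)))
  expect_error(makeVta(c(100, 0, 0), c(2, 2, 2), grid), "empty")
})

test_that("cohorts are deterministic with correctly paired VTAs", {
  a <- smallAtlas()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- makeCohort(5, a, seed = 1, dir = d1)
  c2 <- makeCohort(5, a, seed = 1, dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  expect_identical(labelData(c1$patients[[3]]$truth@labels),
                   labelData(c2$patients[[3]]$truth@labels))

  tb <- subnucleusData(a)
  motorIds <- tb$label[tb$hemisphere == "left" & tb$class == "motor"]
  for (p in c1$patients) {
    outs <- vapply(p$vtas, function(v) v$outcome, character(1))
    expect_identical(sum(outs == "therapeutic"), 1L)
    expect_true(sum(outs == "paresthesia") <= 4L)
    # therapeutic VTA centre lies inside the true motor region
    th <- p$vtas[[which(outs == "therapeutic")]]
    vox <- round(worldToVoxelMat(matrix(th$center, 1),
                                 affineMat(p$mask)))
    expect_true(labelData(p$truth@labels)[vox[1], vox[2], vox[3]] %in%
                  motorIds)
  }

  # reload from manifest and audit the therapeutic/paresthesia pairing
  back <- loadCohort(file.path(d1, "manifest.json"))
  expect_identical(length(back$patients), 5L)
  for (i in seq_along(back$patients)) {
    expect_identical(maskData(back$patients[[i]]$mask),
                     maskData(c1$patients[[i]]$mask))
    outs <- vapply(back$patients[[i]]$vtas, function(v) v$outcome,
                   character(1))
    expect_identical(sum(outs == "therapeutic"), 1L)
  }
})
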