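# ABS, tensor invariants, DTIBS distance and k-means, seed sensitivity.

test_that("ABS reproduces atlas labels when the patient equals the support", {
  hemi <- extractHemisphere(smallAtlas(), "left")
  patient <- BinaryMask(labelData(hemi) > 0, affineMat(hemi))
  seg <- absSegment(patient, hemi)
  expect_identical(labelData(segmentationLabels(seg)), labelData(hemi))
  expect_identical(seg@method, "ABS")
})

test_that("ABS nearest-boundary assignment matches brute force with low-id ties", {
  # labelled voxels at known spots; patient mask includes unlabelled voxels
  labs <- array(0L, c(9, 5, 5))
  labs[3, 3, 3] <- 2L   # 1 mm from the query at (4,3,3)
  labs[7, 3, 3] <- 7L   # 3 mm away
  vol <- tinyLabelVolume(labs)
  mask <- array(FALSE, c(9, 5, 5))
  mask[3, 3, 3] <- TRUE; mask[7, 3, 3] <- TRUE; mask[4, 3, 3] <- TRUE
  seg <- absSegment(tinyMask(mask), vol)
  expect_identical(labelData(segmentationLabels(seg))[4, 3, 3], 2L)

  # equidistant between labels 3 and 9: lowest id wins
  labs2 <- array(0L, c(9, 5, 5))
  labs2[3, 3, 3] <- 9L; labs2[7, 3, 3] <- 3L
  mask2 <- labs2 > 0; mask2[5, 3, 3] <- TRUE
  seg2 <- absSegment(tinyMask(mask2), tinyLabelVolume(labs2))
  expect_identical(labelData(segmentationLabels(seg2))[5, 3, 3], 3L)

  # random small instances against a brute-force nearest-label scan
  set.seed(7)
  for (rep in 1:5) {
    d <- c(12, 10, 8)
    labs <- array(0L, d)
    n <- 30
    pos <- cbind(sample(d[1], n, TRUE), sample(d[2], n, TRUE),
                 sample(d[3], n, TRUE))
    labs[pos] <- sample(1:5, n, TRUE)
    mask <- labs > 0
    extra <- cbind(sample(d[1], 15, TRUE), sample(d[2], 15, TRUE),
                   sample(d[3], 15, TRUE))
    mask[extra] <- TRUE
    vol <- tinyLabelVolume(labs)
    seg <- absSegment(tinyMask(mask), vol)
    segArr <- labelData(segmentationLabels(seg))
    labelled <- which(labs > 0, arr.ind = TRUE)
    for (q in which(mask & labs == 0)) {
      qi <- arrayInd(q, d)
      d2 <- rowSums(sweep(labelled, 2, as.vector(qi))^2)
      best <- min(d2)
      cand <- labs[labelled[d2 <= best + 1e-9, , drop = FALSE]]
      expect_identical(segArr[qi], min(cand))
    }
    # full coverage of the mask, nothing outside it
    expect_identical(segArr > 0L, mask)
  }
})

test_that("tensor shape invariants are correct and rotation-invariant", {
  K <- tensorShapeInvariants(diag(3) * 1e-3)
  expect_equal(unname(K), c(3e-3, 0, 0), tolerance = 1e-12)

  # near-rank-one tensor after epsilon flooring: FA -> 1, mode -> 1
  eps <- 1e-9
  K1 <- tensorShapeInvariants(diag(c(1, eps, eps)))
  expect_gt(K1[["fa"]], 0.999)
  expect_gt(K1[["mode"]], 0.999)
  # closed form on the floored eigenvalues
  l <- c(1, eps, eps); md <- mean(l)
  faRef <- sqrt(3 / 2) * sqrt(sum((l - md)^2) / sum(l^2))
  expect_equal(K1[["fa"]], faRef, tolerance = 1e-9)

  # planar tensor has mode -> -1
  expect_lt(tensorShapeInvariants(diag(c(1, 1, eps)))[["mode"]], -0.999)
  # zero tensor is defined as (0, 0, 0)
  expect_equal(unname(tensorShapeInvariants(matrix(0, 3, 3))), c(0, 0, 0))

  set.seed(5)
  D <- crossprod(matrix(rnorm(9), 3, 3)) * 1e-3
  for (i in 1:10) {
    R <- randomRotationMatrix()
    expect_equal(tensorShapeInvariants(R %*% D %*% t(R)),
                 tensorShapeInvariants(D), tolerance = 1e-9)
  }
})

test_that("orientation dyadic is sign-invariant with unit Frobenius norm", {
  U <- orientationDyadic(diag(c(3, 1, 1)))
  expect_equal(unclass(U), diag(c(1, 0, 0)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sqrt(sum(U^2)), 1, tolerance = 1e-12)

  # e1 and -e1 give identical dyadics
  set.seed(6)
  e1 <- rnorm(3); e1 <- e1 / sqrt(sum(e1^2))
  D1 <- tcrossprod(e1) * 2 + diag(3) * 0.5
  expect_equal(orientationDyadic(D1), orientationDyadic(D1),
               tolerance = 1e-12)

  # orthogonal principal directions are sqrt(2) apart in Frobenius norm
  Ua <- orientationDyadic(diag(c(3, 1, 1)))
  Ub <- orientationDyadic(diag(c(1, 3, 1)))
  expect_equal(sqrt(sum((Ua - Ub)^2)), sqrt(2), tolerance = 1e-12)

  expect_true(attr(orientationDyadic(diag(3)), "degenerate"))
  expect_false(attr(orientationDyadic(diag(c(2, 1, 1))), "degenerate"))
})

test_that("the DTIBS distance decomposes into its three terms", {
  x <- c(1, 2, 3)
  D <- diag(c(2, 1, 1)) * 1e-3
  # at the centroid with the cluster's own tensor the distance is 0
  expect_equal(dtibsDistance(x, D, x, diag(3), D), 0, tolerance = 1e-9)

  # identity covariance and identical tensors reduce to Euclidean distance
  cen <- c(4, 6, 3)
  dref <- sqrt(sum((x - cen)^2))
  # the covariance ridge (1e-4 relative) shifts the Mahalanobis term by
  # ~5e-5 relative, hence the 1e-3 tolerance on these reductions
  expect_equal(dtibsDistance(x, D, cen, diag(3), D), dref,
               tolerance = 1e-3)

  # alpha = 1 with equal shapes but orthogonal orientations: the
  # orientation term is weighted out, leaving the Mahalanobis term
  D2 <- diag(c(1, 2, 1)) * 1e-3        # same invariants, rotated
  expect_equal(dtibsDistance(x, D, cen, diag(3), D2, alpha = 1), dref,
               tolerance = 1e-3)
  # alpha = 0 adds exactly the sqrt(2) dyadic separation
  expect_equal(dtibsDistance(x, D, cen, diag(3), D2, alpha = 0),
               dref + sqrt(2), tolerance = 1e-3)
  # hand-computed three-term sum at alpha = 0.5
  expect_equal(dtibsDistance(x, D, cen, diag(3), D2, alpha = 0.5),
               dref + 0.5 * sqrt(2), tolerance = 1e-3)
  expect_error(dtibsDistance(x, D, cen, diag(3), D, alpha = 2))
})

test_that("DTIBS reduces to spatial k-means on a uniform tensor field", {
  # uniform tensors: only the spatial term distinguishes clusters
  mask <- tinyMask(array(TRUE, c(12, 12, 4)))
  labs <- array(1L, c(12, 12, 4))
  truth <- new("SyntheticTruth", transform = similarityTransform(),
               labels = tinyLabelVolume(labs),
               tensorParams = list(`1` = list(
                 eigenvalues = c(1e-3, 1e-3, 1e-3),
                 direction = c(1, 0, 0), noiseSd = 0)),
               vtaSpec = list())
  field <- makeTensorField(truth, grid = mask, seed = 1)
  seeds <- rbind(c(2.5, 2.5, 1.5), c(8.5, 8.5, 1.5))
  res <- dtibsSegment(mask, field, seeds, convTol = Inf)
  expect_identical(res$state@iterations, 1L)
  # one iteration with identity covariances = the seed Voronoi partition
  w <- worldCoordinates(mask)
  d1 <- sqrt(rowSums(sweep(w, 2, seeds[1, ])^2))
  d2 <- sqrt(rowSums(sweep(w, 2, seeds[2, ])^2))
  voronoi <- ifelse(d1 <= d2, 1L, 2L)
  expect_identical(res$state@assignments, voronoi)
})

test_that("DTIBS centroid updates equal direct averaging and it terminates", {
  p <- patientFixture()
  res <- dtibsSegment(p$mask, p$field, p$seeds, maxIter = 50L)
  expect_lte(res$state@iterations, 50L)
  st <- res$state
  w <- voxelToWorldMat(which(maskData(p$mask) & maskData(p$field@support),
                             arr.ind = TRUE), affineMat(p$mask))
  for (k in seq_len(nrow(st@centroids))) {
    sel <- st@assignments == k
    if (sum(sel) > 0)
      expect_equal(st@centroids[k, ],
                   colMeans(w[sel, , drop = FALSE]), tolerance = 1e-9)
  }
  # every supported voxel is assigned exactly once
  expect_identical(length(st@assignments), sum(maskData(p$mask)))
})

test_that("DTIBS recovers the true segmentation on well-separated tensors", {
  p <- patientFixture()
  res <- dtibsSegment(p$mask, p$field, p$seeds)
  truthLab <- labelData(p$truth@labels)[maskData(p$mask)]
  segLab <- labelData(segmentationLabels(res$segmentation))[maskData(p$mask)]
  expect_gte(ariOf(truthLab, segLab), 0.9)
})

test_that("seed sensitivity is deterministic and stable at radius zero", {
  p <- patientFixture()
  s1 <- seedSensitivity(p$mask, p$field, p$seeds, nRuns = 4, radius = 0,
                        seed = 3)
  expect_equal(s1$meanAri, 1)
  expect_equal(s1$meanModalAgreement, 1)
  s2 <- seedSensitivity(p$mask, p$field, p$seeds, nRuns = 4, radius = 1.5,
                        seed = 3)
  s3 <- seedSensitivity(p$mask, p$field, p$seeds, nRuns = 4, radius = 1.5,
                        seed = 3)
  expect_identical(s2$assignments, s3$assignments)
  expect_identical(s2$meanAri, s3$meanAri)
})
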