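# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small default atlas (Saranathan-like configuration: 10 subnuclei,
# 4 motor, 1 sensory).
smallAtlas <- function() {
  fixture("smallAtlas", function()
    makeAtlas(10, 4, 1, seed = 7, atlasId = "synthA"))
}

secondAtlas <- function() {
  fixture("secondAtlas", function()
    makeAtlas(13, 2, 3, seed = 8, atlasId = "synthB"))
}

# One synthetic patient with known transform, plus tensor field and seeds
# derived from the truth registration.
patientFixture <- function() {
  fixture("patient", function() {
    a <- smallAtlas()
    th <- 12 * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    tf <- similarityTransform(R, c(3, -2, 1), 1.05)
    pat <- makePatient(a, "left", tf, surfaceNoiseSd = 0.4, seed = 5)
    truth <- pat$truth
    truth@tensorParams <- defaultTensorParams(labelSet(truth@labels))
    field <- makeTensorField(truth, grid = pat$mask, seed = 6)
    hemi <- extractHemisphere(a, "left")
    registered <- transformLabels(hemi, tf, pat$mask)
    list(atlas = a, transform = tf, mask = pat$mask, truth = truth,
         field = field, registered = registered,
         seeds = atlasSeedStatistics(registered, field))
  })
}

# A tiny labelled volume on a unit grid for hand-checkable cases.
tinyLabelVolume <- function(labels, voxel = c(1, 1, 1), origin = c(0, 0, 0)) {
  affine <- rbind(cbind(diag(voxel), origin), c(0, 0, 0, 1))
  LabelVolume(labels, affine)
}

tinyMask <- function(mask, voxel = c(1, 1, 1), origin = c(0, 0, 0)) {
  affine <- rbind(cbind(diag(voxel), origin), c(0, 0, 0, 1))
  BinaryMask(mask, affine)
}

randomRotationMatrix <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, pi)
  Kx <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
}

ariOf <- function(a, b) mclust::adjustedRandIndex(a, b)

# Independent oracle: exact two-sided signed-rank p by explicit enumeration
# of all 2^n sign assignments (midranks, zeros removed first).
bruteWilcoxonP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wAll <- signs %*% r
  pLower <- mean(wAll <= wObs + 1e-9)
  pUpper <- mean(wAll >= wObs - 1e-9)
  min(1, 2 * min(pLower, pUpper))
}

# Six synthetic atlases configured with the published per-atlas counts.
sixAtlases <- function() {
  fixture("sixAtlases", function() {
    md <- atlasMetadata()
    lapply(seq_len(nrow(md)), function(i)
      makeAtlas(md$total[i], md$motor[i], md$sensory[i], seed = 100 + i,
                atlasId = md$abbreviation[i]))
  })
}
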