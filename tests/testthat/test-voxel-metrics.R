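test_that("sample entropy matches the brute-force template-pair oracle", {
  # ramp example plus random series of varying length
  ramp <- 1:10
  res <- sampleEntropy(ramp, m = 2, rFactor = 0.6)
  orc <- sampenOracle(ramp, m = 2, rFactor = 0.6)
  expect_equal(res$nMatchesMPlus1, orc$A)
  expect_equal(res$nMatchesM, orc$B)
  expect_equal(res$value, orc$value)

  set.seed(21)
  for (k in 1:10) {
    x <- rnorm(sample(30:80, 1))
    m <- sample(2:3, 1)
    res <- sampleEntropy(x, m = m, rFactor = 0.6)
    orc <- sampenOracle(x, m = m, rFactor = 0.6)
    expect_equal(res$nMatchesMPlus1, orc$A)
    expect_equal(res$nMatchesM, orc$B)
    expect_equal(res$value, orc$value)
  }
})

test_that("sample entropy of a constant series is exactly zero", {
  expect_identical(sampleEntropy(rep(1, 100), m = 3)$value, 0)
  expect_identical(sampleEntropy(rep(-3.7, 40), m = 2)$value, 0)
})

test_that("sample entropy edge cases: short series, affine invariance, monotone in r", {
  expect_error(sampleEntropy(1:4, m = 3), "too short")
  set.seed(22)
  x <- rnorm(100)
  a <- sampleEntropy(x)$value
  b <- sampleEntropy(5 - 3 * x)$value  # r scales with SD
  expect_equal(a, b)
  # SampEn nonincreasing as rFactor grows (more templates match)
  vals <- vapply(c(0.2, 0.4, 0.6, 1.0, 1.5), function(rf)
    sampleEntropy(x, rFactor = rf)$value, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("sampen map equals voxelwise application and orders noise above sinusoid", {
  set.seed(23)
  dims <- c(3, 3, 2); Tn <- 60
  arr <- array(rnorm(prod(dims) * Tn), c(dims, Tn))
  slow <- sin(2 * pi * seq_len(Tn) / 40)
  for (i in 1:3) arr[i, 1, 1, ] <- slow + 0.05 * rnorm(Tn)  # predictable region
  vol <- VolumeSeries(arr, trSeconds = 2)
  mp <- sampenMap(vol, m = 2, rFactor = 0.6)
  flat <- matrix(arr, ncol = Tn)
  for (v in c(1, 10, 18)) {
    expect_equal(mapData(mp)[v], sampleEntropy(flat[v, ], m = 2)$value)
  }
  sinVox <- c(1, 4, 7)  # [i, 1, 1] linear indices
  expect_gt(mean(mapData(mp)[-sinVox][mapMask(mp)[-sinVox]]),
            mean(mapData(mp)[sinVox]))
  # all-constant volume -> all zeros
  cvol <- VolumeSeries(array(2, c(2, 2, 1, 20)), trSeconds = 2)
  expect_true(all(mapData(sampenMap(cvol)) == 0))
})

test_that("raw ICC matches the pairwise squared-correlation oracle", {
  # 3 voxels: r12 = 1, r13 = 0 -> ICC(1) = 1
  t1 <- sin(seq_len(32)); t2 <- 2 * t1 + 3
  t3 <- rep(c(1, -1), 16) - mean(rep(c(1, -1), 16))
  t3 <- residuals(lm(t3 ~ t1))  # orthogonalise exactly
  arr <- array(0, c(3, 1, 1, 32))
  arr[1, 1, 1, ] <- t1; arr[2, 1, 1, ] <- t2; arr[3, 1, 1, ] <- t3
  mp <- iccMap(VolumeSeries(arr, trSeconds = 2))
  expect_equal(mapData(mp)[1, 1, 1], 1, tolerance = 1e-10)

  # all-identical series -> every raw ICC = V - 1
  same <- array(rep(rnorm(20), each = 8), c(2, 2, 2, 20))
  expect_equal(as.numeric(mapData(iccMap(VolumeSeries(same, trSeconds = 2)))),
               rep(7, 8), tolerance = 1e-10)

  # random 4x4x4x60 phantom vs explicit double loop
  set.seed(24)
  arr2 <- array(rnorm(4 * 4 * 4 * 60), c(4, 4, 4, 60))
  mp2 <- iccMap(VolumeSeries(arr2, trSeconds = 2))
  flat <- matrix(arr2, ncol = 60)
  V <- nrow(flat)
  icc <- numeric(V)
  for (i in seq_len(V)) {
    s <- 0
    for (j in seq_len(V)) if (j != i) s <- s + cor(flat[i, ], flat[j, ])^2
    icc[i] <- s
  }
  expect_equal(as.numeric(mapData(mp2)), icc, tolerance = 1e-10)
})

test_that("ICC is invariant to per-voxel linear rescaling", {
  set.seed(25)
  arr <- array(rnorm(2 * 2 * 2 * 40), c(2, 2, 2, 40))
  a1 <- iccMap(VolumeSeries(arr, trSeconds = 2))
  flat <- matrix(arr, ncol = 40)
  flat <- flat * runif(8, 0.5, 4) + rnorm(8)
  a2 <- iccMap(VolumeSeries(array(flat, c(2, 2, 2, 40)), trSeconds = 2))
  expect_equal(mapData(a1), mapData(a2), tolerance = 1e-10)
})

test_that("z-score normalisation yields mean 0 / SD 1 and handles constants", {
  set.seed(26)
  mp <- VoxelMap(array(rnorm(27, 5, 3), c(3, 3, 3)), kind = "icc_raw")
  z <- normalizeZscoreMap(mp)
  expect_equal(mean(mapData(z)), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(mapData(z)^2)), 1, tolerance = 1e-12)
  expect_identical(mapKind(z), "icc_norm")
  # hand z-score on 3 values with population SD
  m3 <- array(0, c(3, 1, 1)); m3[, 1, 1] <- c(1, 2, 3)
  z3 <- normalizeZscoreMap(VoxelMap(m3, kind = "stat"))
  expect_equal(as.numeric(mapData(z3)), (c(1, 2, 3) - 2) / sqrt(2 / 3))
  cst <- normalizeZscoreMap(VoxelMap(array(4, c(2, 2, 1)), kind = "stat"))
  expect_true(all(mapData(cst) == 0))
})

test_that("Gaussian smoothing matches the analytic kernel and preserves constants", {
  # single impulse, 2 mm voxels, 10 mm FWHM: profile within 1% of Gaussian
  arr <- array(0, c(21, 21, 21)); arr[11, 11, 11] <- 1
  sm <- smoothMapGaussian(VoxelMap(arr, voxelSizeMm = c(2, 2, 2)), 10)
  sig <- 10 / (2 * sqrt(2 * log(2))) / 2
  prof <- mapData(sm)[, 11, 11]
  kern <- dnorm(seq(-10, 10), sd = sig); kern <- kern / sum(kern)
  theo <- kern * sum(prof) / sum(kern)
  # separable smoothing of an impulse: axis profile proportional to kernel
  expect_lt(max(abs(prof / max(prof) - kern / max(kern))), 0.01)
  # fwhm -> 0 returns the input unchanged
  expect_equal(mapData(smoothMapGaussian(VoxelMap(arr), 0)), arr)
  # uniform map unchanged under mask-aware normalisation
  u <- VoxelMap(array(3, c(6, 6, 6)))
  expect_equal(mapData(smoothMapGaussian(u, 8)), mapData(u), tolerance = 1e-10)
})

test_that("binarise-and-overlap equals the set-algebra oracle", {
  set.seed(27)
  dims <- c(5, 5, 4)
  maps <- lapply(1:4, function(i) VoxelMap(array(runif(prod(dims)), dims)))
  thr <- runif(4, 0.3, 0.7)
  ov <- binarizeAndOverlap(maps, thr)
  expect_identical(mapKind(ov), "mask")
  manual <- Reduce(`&`, lapply(1:4, function(i) mapData(maps[[i]]) >= thr[i]))
  expect_equal(mapData(ov), array(as.numeric(manual), dims))
  # identical masks -> overlap is that mask; disjoint -> empty
  a <- VoxelMap(array(rep(c(1, 0), 50), c(10, 5, 2)))
  expect_equal(mapData(binarizeAndOverlap(list(a, a), c(0.5, 0.5))),
               array(as.numeric(mapData(a) >= 0.5), c(10, 5, 2)))
  b <- VoxelMap(array(rep(c(0, 1), 50), c(10, 5, 2)))
  expect_true(all(mapData(binarizeAndOverlap(list(a, b), c(0.5, 0.5))) == 0))
})
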