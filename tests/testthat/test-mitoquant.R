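test_that("maximum projection matches a brute-force per-pixel loop", {
  m <- matrix(1:6, 2, 3)
  expect_identical(maxProject(m), m)                       # 2D passthrough
  a <- array(0, dim = c(2, 2, 2))
  a[1, 1, ] <- c(2, 5)
  expect_equal(maxProject(a)[1, 1], 5)
  set.seed(1)
  st <- array(runif(6 * 7 * 4), dim = c(6, 7, 4))
  oracle <- matrix(0, 6, 7)
  for (r in 1:6) for (c in 1:7) oracle[r, c] <- max(st[r, c, ])
  expect_equal(maxProject(st), oracle)
  expect_error(maxProject(array(0, dim = c(2, 2, 0))), "slice")
})

test_that("background correction removes flat and slowly varying fields", {
  expect_error(backgroundCorrect(matrix(1, 5, 5), sigma = 0), "sigma")
  const <- matrix(7, 40, 40)
  expect_true(all(backgroundCorrect(const) == 0))
  # a bright impulse is essentially preserved: the wide-Gaussian estimate
  # assigns it only the kernel's central weight ~ 1/(2 pi sigma^2)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1000
  got <- backgroundCorrect(imp, sigma = 3)[21, 21]
  expect_equal(got, 1000 * (1 - 1 / (2 * pi * 9)), tolerance = 0.01)
  # slowly varying ramp: residual mean well below the ramp amplitude
  ramp <- matrix(rep(seq(0, 100, length.out = 60), each = 60), 60, 60)
  res <- backgroundCorrect(ramp, sigma = 10)
  expect_lt(mean(res[, 16:45]), 5)   # interior, away from edge effects
})

test_that("Otsu equals the exhaustive between-class-variance maximizer", {
  bruteOtsu <- function(x, nBins = 256L) {
    breaks <- seq(min(x), max(x), length.out = nBins + 1L)
    centers <- (breaks[-1] + breaks[-(nBins + 1)]) / 2
    idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
                nBins)
    best <- -Inf; bestEdge <- NA_real_
    for (k in 1:(nBins - 1)) {            # threshold at breaks[k + 1]
      g1 <- x[idx <= k]; g2 <- x[idx > k]
      if (!length(g1) || !length(g2)) {
        v <- 0
      } else {
        m1 <- mean(centers[idx[idx <= k]]); m2 <- mean(centers[idx[idx > k]])
        v <- length(g1) * length(g2) * (m1 - m2)^2
      }
      if (v > best + 1e-9) { best <- v; bestEdge <- breaks[k + 1] }
    }
    bestEdge
  }
  # two-point mass: returned edge separates the classes exactly
  x <- c(rep(0, 50), rep(100, 50))
  thr <- otsuThreshold(x)
  expect_true(all((x > thr) == (x == 100)))
  # 8-value toy histogram and random images against the brute-force oracle
  toy <- rep(c(1, 2, 3, 4, 20, 21, 22, 40), times = c(9, 7, 6, 3, 4, 6, 2, 1))
  expect_equal(otsuThreshold(toy), bruteOtsu(toy))
  set.seed(11)
  for (i in 1:5) {
    x <- c(rnorm(300, 10, 2), rnorm(120, 30, 4))
    expect_equal(otsuThreshold(x), bruteOtsu(x))
  }
  expect_error(otsuThreshold(matrix(3, 4, 4)), "degenerate")
})

test_that("cell segmentation recovers the true cell", {
  p <- generateScene(noiselessConfig(seed = 5))
  mem <- backgroundCorrect(getChannel(p$scene, "membrane"))
  expect_identical(segmentCell(mem), cellMask(p$truth))
  # two blobs: only the larger survives
  img <- matrix(0, 60, 60)
  img[10:30, 10:30] <- 100   # 21 x 21
  img[45:52, 45:52] <- 100   # 8 x 8
  mk <- segmentCell(img)
  expect_true(all(mk[10:30, 10:30]))
  expect_false(any(mk[45:52, 45:52]))
  # default SNR: Jaccard >= 0.9 against truth
  p2 <- generateScene(snrConfig(seed = 6))
  mem2 <- backgroundCorrect(maxProject(getChannel(p2$scene, "membrane")))
  expect_gte(jaccard(segmentCell(mem2), cellMask(p2$truth)), 0.9)
  expect_error(segmentCell(matrix(1, 5, 5)), "degenerate")
})

test_that("mitochondria segmentation recovers the true mask", {
  p <- generateScene(noiselessConfig(seed = 5))
  tom <- backgroundCorrect(getChannel(p$scene, "tom20"))
  expect_identical(segmentMitochondria(tom, cellMask(p$truth)),
                   mitoMask(p$truth))
  expect_error(segmentMitochondria(tom, matrix(FALSE, 192, 192)), "empty")
  p2 <- generateScene(snrConfig(seed = 6))
  tom2 <- backgroundCorrect(maxProject(getChannel(p2$scene, "tom20")))
  cm <- segmentCell(backgroundCorrect(maxProject(getChannel(p2$scene,
                                                            "membrane"))))
  expect_gte(jaccard(segmentMitochondria(tom2, cm), mitoMask(p2$truth)),
             0.85)
})

test_that("the enrichment ratio is the masked-mean quotient and scales out intensity", {
  # uniform reporter -> exactly 1
  img <- matrix(5, 10, 10)
  cell <- matrix(TRUE, 10, 10)
  mito <- matrix(FALSE, 10, 10); mito[3:5, 3:5] <- TRUE
  r <- enrichmentRatio(img, mito, cell, guardPx = 0L, erodePx = 0L)
  expect_equal(r$ratio, 1)
  # constructed arithmetic: mito pixels 20, cytosol pixels 10 -> 2.0
  img2 <- matrix(10, 10, 10); img2[mito] <- 20
  r2 <- enrichmentRatio(img2, mito, cell, pixelSize = 0.5,
                        guardPx = 0L, erodePx = 0L)
  expect_equal(r2$ratio, 2)
  expect_equal(r2$cell_area, 100 * 0.25)
  expect_equal(r2$mito_area, 9 * 0.25)
  # scale equivariance
  r3 <- enrichmentRatio(3.7 * img2, mito, cell, guardPx = 0L, erodePx = 0L)
  expect_equal(r3$ratio, r2$ratio)
  # degenerate inputs
  expect_error(enrichmentRatio(img2, matrix(FALSE, 10, 10), cell),
               "mitochondrial")
  expect_error(enrichmentRatio(img2, cell, cell), "cytosolic")
})

test_that("QC verdicts enumerate their reasons", {
  p <- generateScene(sceneConfig(seed = 3))
  q <- qcCheck(cellMask(p$truth), mitoMask(p$truth))
  expect_true(q$pass)
  q2 <- qcCheck(cellMask(p$truth), matrix(FALSE, 192, 192))
  expect_false(q2$pass)
  expect_true("mito_area_out_of_range" %in% q2$reasons)
  big <- matrix(TRUE, 50, 50); mito <- matrix(FALSE, 50, 50)
  mito[20:30, 20:30] <- TRUE
  q3 <- qcCheck(big, mito)
  expect_false(q3$pass)
  expect_true(all(c("cell_area_out_of_range", "cell_touches_border")
                  %in% q3$reasons))
})

test_that("the noiseless pipeline is exact and QC catches blank marker channels", {
  p <- generateScene(noiselessConfig(enrichment = 3, seed = 5))
  q <- quantifyScene(p$scene)
  expect_equal(q$ratio, 3, tolerance = 1e-9)
  expect_true(q$qc_pass)
  # multiplying the reporter channel leaves the ratio unchanged
  s2 <- p$scene
  s2@channels$pink1 <- 4.2 * s2@channels$pink1
  expect_equal(quantifyScene(s2)$ratio, q$ratio, tolerance = 1e-9)
  # blank tom20 -> excluded with a QC reason instead of an error
  s3 <- p$scene
  s3@channels$tom20 <- matrix(0, 192, 192)
  q3 <- quantifyScene(s3)
  expect_false(q3$qc_pass)
  expect_match(q3$qc_reasons, "mito_area_out_of_range")
})

test_that("enrichment recovery is within 10 percent across the dynamic range", {
  for (enr in c(0.5, 2, 5)) {
    b <- generateBatch(snrConfig(enrichment = enr), 8, seed = 42)
    s <- attr(quantifyBatch(b), "summary")
    expect_equal(s$n_pass, 8L)
    expect_lt(abs(s$mean_ratio - enr) / enr, 0.10)
  }
})

test_that("increasing true enrichment strictly increases the estimated median", {
  med <- vapply(c(1, 2, 3), function(enr) {
    b <- generateBatch(snrConfig(enrichment = enr), 6, seed = 24)
    attr(quantifyBatch(b), "summary")$median_ratio
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})
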