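test_that("thinning reduces simple shapes to their medial line", {
  # 3-px-wide horizontal bar -> a single-row line
  bar <- matrix(FALSE, 20, 60); bar[9:11, 5:54] <- TRUE
  sk <- skeletonizeMask(bar)
  expect_equal(unique(which(sk, arr.ind = TRUE)[, 1]), 10L)
  # a disk collapses to at most a few central pixels
  disk <- matrix(FALSE, 31, 31)
  for (r in 1:31) for (c in 1:31)
    disk[r, c] <- (r - 16)^2 + (c - 16)^2 <= 100
  skd <- skeletonizeMask(disk)
  expect_lte(sum(skd), 6)
  expect_true(all(which(skd, arr.ind = TRUE)[, 1] %in% 13:19))
  # empty mask -> empty skeleton
  expect_false(any(skeletonizeMask(matrix(FALSE, 5, 5))))
})

test_that("thinning preserves the number of connected components", {
  for (sd in c(1L, 9L)) for (md in c("networked", "fragmented")) {
    p <- generateScene(sceneConfig(mitoMode = md, seed = sd))
    mask <- mitoMask(p$truth)
    sk <- skeletonizeMask(mask)
    nm <- max(EBImage::bwlabel(EBImage::Image(mask * 1)))
    g <- skeletonToGraph(sk, 0.1)
    # bwlabel is 4-connected, our graph is 8-connected; the 8-connected
    # count can only be smaller or equal
    expect_lte(g@nComponents, nm)
    expect_gt(g@nComponents, 0L)
  }
})

test_that("the branch graph matches hand-enumerated toy shapes", {
  # 11-pixel horizontal line: one branch of 10 orthogonal steps
  line <- matrix(FALSE, 5, 20); line[3, 5:15] <- TRUE
  g <- skeletonToGraph(line, pixelSize = 1)
  expect_equal(length(g@branches), 1L)
  expect_equal(g@branchLengths, 10)
  expect_equal(sum(g@nodes$type == "endpoint"), 2L)
  expect_equal(g@nComponents, 1L)
  # T: bar on row 10 (cols 3-11), stem col 7 (rows 11-14). the junction is
  # the 4-pixel cluster {(10,6),(10,7),(10,8),(11,7)}; three branches of 3
  # steps each run from the cluster boundary to the tips
  tshape <- matrix(FALSE, 20, 20)
  tshape[10, 3:11] <- TRUE; tshape[11:14, 7] <- TRUE
  gt <- skeletonToGraph(tshape, pixelSize = 1)
  expect_equal(length(gt@branches), 3L)
  expect_equal(sort(gt@branchLengths), c(3, 3, 3))
  expect_equal(sum(gt@nodes$type == "endpoint"), 3L)
  expect_gte(sum(gt@nodes$type == "junction"), 1L)
  expect_equal(gt@nComponents, 1L)
  # X crossing: 4 arms of 6 steps responding to one junction cluster
  x <- matrix(FALSE, 21, 21); x[11, 4:18] <- TRUE; x[4:18, 11] <- TRUE
  gx <- skeletonToGraph(x, pixelSize = 1)
  expect_equal(length(gx@branches), 4L)
  expect_equal(sort(gx@branchLengths), rep(6, 4))
  # two disjoint lines -> 2 components
  two <- matrix(FALSE, 10, 20); two[2, 2:8] <- TRUE; two[8, 2:8] <- TRUE
  expect_equal(skeletonToGraph(two, 1)@nComponents, 2L)
  # diagonal steps count sqrt(2)
  diag5 <- matrix(FALSE, 10, 10); for (i in 1:5) diag5[i + 2, i + 2] <- TRUE
  expect_equal(skeletonToGraph(diag5, 2)@branchLengths, 4 * sqrt(2) * 2)
  # isolated pixels are zero-length components
  iso <- matrix(FALSE, 5, 5); iso[2, 2] <- TRUE; iso[4, 4] <- TRUE
  gi <- skeletonToGraph(iso, 1)
  expect_equal(length(gi@branches), 0L)
  expect_equal(gi@nComponents, 2L)
  # a thinnable 2x2 solid block is rejected
  blk <- matrix(FALSE, 8, 8); blk[3:4, 3:4] <- TRUE
  expect_error(skeletonToGraph(blk, 1), "2x2")
})

test_that("morphology statistics follow the defining arithmetic", {
  line <- matrix(FALSE, 5, 20); line[3, 5:15] <- TRUE
  st <- morphologyStats(line, pixelSize = 0.1)
  expect_equal(st$footprint, 11 * 0.01)
  expect_equal(st$summed_branch_length, 1.0)
  expect_equal(st$mean_branch_length, 1.0)
  expect_equal(st$n_individuals, 1L)
  expect_equal(st$n_networks, 0L)
  expect_warning(st0 <- morphologyStats(matrix(FALSE, 5, 5), 1), "empty")
  expect_true(st0$empty_mask)
  expect_equal(st0$summed_branch_length, 0)
  # a mask equal to its own (orthogonal) skeleton: footprint tracks length
  expect_equal(st$footprint, (st$summed_branch_length / 0.1 + 1) * 0.1^2)
})

test_that("morphology statistics are invariant under rotation and translation", {
  p <- generateScene(sceneConfig(seed = 4))
  mask <- mitoMask(p$truth)
  # on a fixed skeleton, rotation leaves every branch length unchanged
  sk <- skeletonizeMask(mask)
  g <- skeletonToGraph(sk, 0.1)
  gr <- skeletonToGraph(rot90mask(sk), 0.1)
  expect_equal(sum(gr@branchLengths), sum(g@branchLengths),
               tolerance = 1e-12)
  expect_equal(sort(gr@branchLengths), sort(g@branchLengths),
               tolerance = 1e-12)
  expect_equal(gr@nComponents, g@nComponents)
  # thinning from the mask is sequential, so rotating the mask may change
  # the scan order; the statistics agree to within a percent or so
  st <- morphologyStats(mask, 0.1)
  str <- morphologyStats(rot90mask(mask), 0.1)
  expect_equal(str$summed_branch_length, st$summed_branch_length,
               tolerance = 0.02)
  expect_equal(str$footprint, st$footprint)
  st180 <- morphologyStats(mask[nrow(mask):1, ncol(mask):1], 0.1)
  expect_equal(st180$summed_branch_length, st$summed_branch_length,
               tolerance = 0.02)
  # translation: embed shifted
  big <- matrix(FALSE, 250, 250)
  big[30 + seq_len(nrow(mask)), 17 + seq_len(ncol(mask))] <- mask
  stt <- morphologyStats(big, 0.1)
  expect_equal(stt$summed_branch_length, st$summed_branch_length)
  expect_equal(stt$footprint, st$footprint)
})

test_that("deleting a whole branch never increases summed branch length", {
  two <- matrix(FALSE, 12, 30)
  two[3, 2:25] <- TRUE; two[9, 5:20] <- TRUE
  full <- morphologyStats(two, 1)$summed_branch_length
  one <- two; one[9, ] <- FALSE
  expect_lt(morphologyStats(one, 1)$summed_branch_length, full)
})

test_that("fragmented networks have shorter branches; footprint is recovered", {
  pn <- generateScene(sceneConfig(mitoMode = "networked", seed = 3))
  pf <- generateScene(sceneConfig(mitoMode = "fragmented", seed = 3))
  qn <- quantifyScene(pn$scene); qf <- quantifyScene(pf$scene)
  sn <- morphologyStats(attr(qn, "masks")$mito, 0.1)
  sf <- morphologyStats(attr(qf, "masks")$mito, 0.1)
  expect_lt(sf$mean_branch_length, sn$mean_branch_length)
  expect_gt(sf$n_individuals + sf$n_networks,
            2 * (sn$n_individuals + sn$n_networks))
  expect_lt(abs(sn$footprint - pn$truth@footprint) / pn$truth@footprint, 0.15)
  expect_lt(abs(sf$footprint - pf$truth@footprint) / pf$truth@footprint, 0.15)
})

test_that("estimated summed branch length tracks generator truth across scenes", {
  est <- numeric(0); tru <- numeric(0)
  lengths <- c(60, 90, 120, 150)
  for (i in seq_len(8)) {
    L <- lengths[(i - 1) %% 4 + 1]
    p <- generateScene(sceneConfig(mitoTotalLength = L, seed = 100 + i))
    q <- quantifyScene(p$scene)
    est <- c(est, morphologyStats(attr(q, "masks")$mito,
                                  0.1)$summed_branch_length)
    tru <- c(tru, p$truth@summedBranchLength)
  }
  expect_gte(cor(est, tru), 0.9)
})
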