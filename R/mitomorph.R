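# shift a logical/numeric matrix so element (r,c) becomes m(r+dr, c+dc);
# out-of-range cells are FALSE/0
.shiftMat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1L, 1L - dr):min(h, h - dr)
  cs <- max(1L, 1L - dc):min(w, w - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

# 8-neighborhood in the Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
.zsOffsets <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                   c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

.neighborStack <- function(m) {
  lapply(.zsOffsets, function(o) .shiftMat(m, o[1L], o[2L]))
}

# number of 0->1 transitions around the circular sequence P2..P9,P2
.transitionCount <- function(nb) {
  a <- matrix(0, nrow(nb[[1L]]), ncol(nb[[1L]]))
  for (i in seq_len(8L)) {
    p <- nb[[i]]
    q <- nb[[if (i == 8L) 1L else i + 1L]]
    a <- a + (!p & q)
  }
  a
}


# TRUE when the pixel's foreground 8-neighbours (at least two) form a
# single mutually 8-connected component: removing such a pixel preserves
# connectivity, so a minimal skeleton contains none
.redundantPixel <- function(m, r, c) {
  nbOffsets <- do.call(rbind, .zsOffsets)
  rr <- r + nbOffsets[, 1L]; cc <- c + nbOffsets[, 2L]
  okn <- rr >= 1L & rr <= nrow(m) & cc >= 1L & cc <= ncol(m)
  okn[okn] <- m[cbind(rr[okn], cc[okn])]
  k <- which(okn)
  if (length(k) < 2L) return(FALSE)
  comp <- integer(8L); cid <- 0L
  for (s in k) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cid
      adj <- k[comp[k] == 0L &
                 abs(nbOffsets[k, 1L] - nbOffsets[v, 1L]) <= 1L &
                 abs(nbOffsets[k, 2L] - nbOffsets[v, 2L]) <= 1L]
      stack <- c(stack, adj)
    }
  }
  cid == 1L
}

#' Skeletonize a binary mask by iterative thinning
#'
#' Zhang-Suen-style two-subiteration thinning to a one-pixel-wide,
#' 8-connected skeleton, followed by a conservative cleanup pass that
#' removes redundant pixels left in 2x2 blocks when their removal does not
#' break local connectivity. Thinning preserves connectivity, so the
#' skeleton has the same number of connected components as the mask.
#'
#' @param mask logical matrix
#' @return logical skeleton matrix (empty for an empty mask)
#' @export
skeletonizeMask <- function(mask) {
  if (is.null(dim(mask)) || length(dim(mask)) != 2L)
    stop("'mask' must be a 2D matrix")
  m <- mask > 0
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- .neighborStack(m)
      b <- Reduce(`+`, nb)
      a <- .transitionCount(nb)
      if (pass == 1L) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(nb[[1L]] & nb[[3L]] & nb[[5L]]) &
          !(nb[[3L]] & nb[[5L]] & nb[[7L]])
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(nb[[1L]] & nb[[3L]] & nb[[7L]]) &
          !(nb[[1L]] & nb[[5L]] & nb[[7L]])
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # reduction to a minimal skeleton: iteratively remove any pixel with at
  # least two foreground 8-neighbours that form a single mutually
  # 8-connected component among themselves. removing such a "simple" pixel
  # cannot disconnect the skeleton, and the pass dissolves the redundant
  # corner and domino patterns of rasterised digital curves (including
  # residual 2x2 blocks) that would otherwise inflate neighbour counts
  # into spurious junctions. endpoints (single neighbour) are never
  # removed, and the scan order is fixed, so the result is deterministic.
  repeat {
    removedAny <- FALSE
    px <- which(m, arr.ind = TRUE)
    for (i in seq_len(nrow(px))) {
      r <- px[i, 1L]; c <- px[i, 2L]
      if (!m[r, c]) next
      if (.redundantPixel(m, r, c)) {
        m[r, c] <- FALSE
        removedAny <- TRUE
      }
    }
    if (!removedAny) break
  }
  m
}

# pixel ids, neighbor lists and component labels for a skeleton
.skeletonTopology <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  if (n == 0L)
    return(list(px = px, nbrs = list(), deg = integer(0),
                comp = integer(0), nComp = 0L))
  lin <- px[, 1L] + (px[, 2L] - 1L) * h
  idmap <- integer(h * w)
  idmap[lin] <- seq_len(n)
  nbrs <- vector("list", n)
  for (o in .zsOffsets) {
    rr <- px[, 1L] + o[1L]; cc <- px[, 2L] + o[2L]
    okv <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    nid <- integer(n)
    nid[okv] <- idmap[rr[okv] + (cc[okv] - 1L) * h]
    hit <- which(nid > 0L)
    for (i in hit) nbrs[[i]] <- c(nbrs[[i]], nid[i])
  }
  nbrs <- lapply(nbrs, function(v) if (is.null(v)) integer(0) else sort(v))
  deg <- lengths(nbrs)
  comp <- integer(n); nComp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    nComp <- nComp + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- nComp
      stack <- c(stack, nbrs[[v]][comp[nbrs[[v]]] == 0L])
    }
  }
  list(px = px, nbrs = nbrs, deg = deg, comp = comp, nComp = nComp)
}

.stepLengths <- function(path, pixelSize) {
  if (nrow(path) < 2L) return(0)
  d <- abs(diff(path))
  sum(ifelse(rowSums(d) == 2L, sqrt(2), 1)) * pixelSize
}

#' Build a branch graph from a one-pixel-wide skeleton
#'
#' Classifies skeleton pixels by 8-neighbour count (1 = endpoint, >= 3 =
#' junction), traces branches between node pixels through degree-2 chains,
#' and measures each branch as the sum of its steps: one pixel size per
#' orthogonal step, sqrt(2) pixel sizes per diagonal step. Closed loops
#' with no node pixel become a single circular branch. Isolated pixels
#' contribute zero-length components counted in \code{nComponents}.
#'
#' @param skeleton logical skeleton mask (from
#'   \code{\link{skeletonizeMask}})
#' @param pixelSize micrometres per pixel
#' @return a \linkS4class{SkeletonGraph}
#' @export
skeletonToGraph <- function(skeleton, pixelSize = 1) {
  .assertScalar(pixelSize, "pixelSize", positive = TRUE)
  m <- skeleton > 0
  blocks <- m & .shiftMat(m, 0L, 1L) & .shiftMat(m, 1L, 0L) &
    .shiftMat(m, 1L, 1L)
  if (any(blocks)) {
    # a 2x2 block is tolerated only when none of its pixels is removable:
    # that configuration is an irreducible 4-way crossing, which the
    # junction-cluster merge below treats as a single node. any removable
    # pixel means the input is not a minimal one-pixel-wide skeleton.
    idx <- which(blocks, arr.ind = TRUE)
    for (i in seq_len(nrow(idx))) {
      for (o in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
        r <- idx[i, 1L] + o[1L]; c <- idx[i, 2L] + o[2L]
        if (m[r, c] && .redundantPixel(m, r, c))
          stop("precondition failed: input contains a thinnable 2x2 solid block and is not a one-pixel-wide skeleton")
      }
    }
  }
  topo <- .skeletonTopology(m)
  n <- nrow(topo$px)
  branches <- list(); lengths <- numeric(0)
  if (n > 0L) {
    # adjacent junction pixels act as one junction node: without this
    # merge, 8-connectivity splits every T or X crossing into a cluster of
    # degree->=3 pixels and spurious one-pixel branches between them
    isJunction <- topo$deg >= 3L
    cluster <- integer(n)
    cid <- 0L
    for (s in which(isJunction)) {
      if (cluster[s] != 0L) next
      cid <- cid + 1L
      stack <- s
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (cluster[v] != 0L) next
        cluster[v] <- cid
        jn <- topo$nbrs[[v]][isJunction[topo$nbrs[[v]]] &
                               cluster[topo$nbrs[[v]]] == 0L]
        stack <- c(stack, jn)
      }
    }
    nodeIds <- which(topo$deg == 1L | isJunction)
    visited <- new.env(hash = TRUE, parent = emptyenv())
    ekey <- function(i, j) paste0(min(i, j), "-", max(i, j))
    sameCluster <- function(i, j)
      isJunction[i] && isJunction[j] && cluster[i] == cluster[j]
    traceFrom <- function(start, second) {
      path <- c(start, second)
      assign(ekey(start, second), TRUE, envir = visited)
      prev <- start; cur <- second
      while (topo$deg[cur] == 2L) {
        nxt <- setdiff(topo$nbrs[[cur]], prev)
        if (length(nxt) != 1L) break
        if (exists(ekey(cur, nxt), envir = visited)) break
        assign(ekey(cur, nxt), TRUE, envir = visited)
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      path
    }
    for (nd in nodeIds) {
      for (nb in topo$nbrs[[nd]]) {
        if (sameCluster(nd, nb)) next
        if (exists(ekey(nd, nb), envir = visited)) next
        path <- traceFrom(nd, nb)
        branches[[length(branches) + 1L]] <- topo$px[path, , drop = FALSE]
      }
    }
    # pure cycles: degree-2 pixels none of whose edges were traversed
    for (s in seq_len(n)) {
      if (topo$deg[s] != 2L) next
      untouched <- !any(vapply(topo$nbrs[[s]], function(nb)
        exists(ekey(s, nb), envir = visited), logical(1L)))
      if (!untouched) next
      path <- traceFrom(s, topo$nbrs[[s]][1L])
      # close the loop explicitly for the length computation
      if (length(path) > 2L &&
          path[length(path)] != s &&
          s %in% topo$nbrs[[path[length(path)]]]) {
        assign(ekey(path[length(path)], s), TRUE, envir = visited)
        path <- c(path, s)
      }
      branches[[length(branches) + 1L]] <- topo$px[path, , drop = FALSE]
    }
    lengths <- vapply(branches, .stepLengths, numeric(1L),
                      pixelSize = pixelSize)
    keep <- lengths > 0
    branches <- branches[keep]
    lengths <- lengths[keep]
  }
  nodes <- data.frame(row = integer(0), col = integer(0),
                      type = character(0))
  if (n > 0L) {
    isNode <- topo$deg == 1L | topo$deg >= 3L
    if (any(isNode))
      nodes <- data.frame(row = topo$px[isNode, 1L],
                          col = topo$px[isNode, 2L],
                          type = ifelse(topo$deg[isNode] == 1L,
                                        "endpoint", "junction"))
  }
  new("SkeletonGraph", nodes = nodes, branches = branches,
      branchLengths = lengths, nComponents = topo$nComp,
      pixelSize = pixelSize)
}

# remove spur branches (shorter than pruneLen, hanging off a junction)
.pruneSpurs <- function(skel, graph, pruneLen) {
  if (pruneLen <= 0 || length(graph@branches) == 0L) return(skel)
  degAt <- function(r, c) {
    s <- 0L
    for (o in .zsOffsets) {
      rr <- r + o[1L]; cc <- c + o[2L]
      if (rr >= 1L && rr <= nrow(skel) && cc >= 1L && cc <= ncol(skel) &&
          skel[rr, cc]) s <- s + 1L
    }
    s
  }
  out <- skel
  for (i in seq_along(graph@branches)) {
    if (graph@branchLengths[i] >= pruneLen) next
    b <- graph@branches[[i]]
    d1 <- degAt(b[1L, 1L], b[1L, 2L])
    d2 <- degAt(b[nrow(b), 1L], b[nrow(b), 2L])
    if (d1 >= 3L && d2 == 1L) {
      out[b[-1L, , drop = FALSE]] <- FALSE
    } else if (d2 >= 3L && d1 == 1L) {
      out[b[-nrow(b), , drop = FALSE]] <- FALSE
    }
  }
  out
}

#' Mitochondrial network morphology statistics
#'
#' MiNA-style summary of a binary mitochondrial mask: the mask is thinned
#' to a skeleton, short spurs are pruned, and the branch graph yields the
#' summed and mean branch length. The footprint is the foreground area of
#' the mask itself. Components without any junction count as "individuals",
#' components with at least one junction as "networks".
#'
#' @param mitoMask logical mask
#' @param pixelSize micrometres per pixel
#' @param prunePx prune spur branches shorter than this many pixels
#'   (default 2; 0 disables pruning)
#' @return one-row data.frame: mean_branch_length, summed_branch_length,
#'   footprint, n_branches, n_individuals, n_networks, empty_mask
#' @export
morphologyStats <- function(mitoMask, pixelSize = 1, prunePx = 2) {
  .assertScalar(pixelSize, "pixelSize", positive = TRUE)
  m <- mitoMask > 0
  if (!any(m)) {
    warning("empty mitochondrial mask: all morphology statistics are zero")
    return(data.frame(mean_branch_length = 0, summed_branch_length = 0,
                      footprint = 0, n_branches = 0L, n_individuals = 0L,
                      n_networks = 0L, empty_mask = TRUE))
  }
  skel <- skeletonizeMask(m)
  graph <- skeletonToGraph(skel, pixelSize)
  if (prunePx > 0) {
    pruned <- .pruneSpurs(skel, graph, prunePx * pixelSize)
    if (!identical(pruned, skel))
      graph <- skeletonToGraph(pruned, pixelSize)
    skel <- pruned
  }
  topo <- .skeletonTopology(skel)
  junctionComp <- unique(topo$comp[topo$deg >= 3L])
  nNetworks <- length(junctionComp)
  nIndividuals <- topo$nComp - nNetworks
  nb <- length(graph@branchLengths)
  summed <- sum(graph@branchLengths)
  data.frame(
    mean_branch_length = if (nb > 0L) summed / nb else 0,
    summed_branch_length = summed,
    footprint = sum(m) * pixelSize^2,
    n_branches = nb,
    n_individuals = nIndividuals,
    n_networks = nNetworks,
    empty_mask = FALSE)
}
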