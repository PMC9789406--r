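# Midline extraction from binarized top-view masks and body-frame coordinates.

#' Resample a polyline to points equally spaced in arc length
#'
#' Linear interpolation along the cumulative arc length of `path`; the two
#' endpoints are preserved exactly.
#'
#' @param path numeric matrix (>= 2 rows) of ordered (x, y) points.
#' @param n number of output points (>= 2), default 100.
#' @return an `n x 2` matrix.
#' @export
resample_midline <- function(path, n = 100L) {
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop_field("path", "needs at least 2 points")
  if (n < 2L) stop_field("n", "must be >= 2")
  seg <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop_field("path", "zero-length path")
  # drop duplicated points so approx() has strictly increasing abscissae
  keep <- c(TRUE, seg > 0)
  s <- s[keep]; path <- path[keep, , drop = FALSE]
  target <- seq(0, total, length.out = n)
  out <- cbind(stats::approx(s, path[, 1], xout = target)$y,
               stats::approx(s, path[, 2], xout = target)$y)
  out[1, ] <- path[1, ]
  out[n, ] <- path[nrow(path), ]
  unname(out)
}

# --- Zhang-Suen thinning --------------------------------------------------
# Binary skeletonization of a 0/1 matrix. Implemented here because no
# installed imaging package exposes 2-D thinning; the classic two-subiteration
# algorithm is used, vectorized over the image.
zhang_suen_thin <- function(img) {
  img <- (img != 0) * 1L
  pad <- function(m) {
    out <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
    out[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    out
  }
  m <- pad(img)
  nr <- nrow(m); nc <- ncol(m)
  core_r <- 2:(nr - 1L); core_c <- 2:(nc - 1L)
  shift <- function(m, dr, dc) m[core_r + dr, core_c + dc]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift(m, -1L, 0L); p3 <- shift(m, -1L, 1L); p4 <- shift(m, 0L, 1L)
      p5 <- shift(m, 1L, 1L); p6 <- shift(m, 1L, 0L); p7 <- shift(m, 1L, -1L)
      p8 <- shift(m, 0L, -1L); p9 <- shift(m, -1L, -1L)
      p <- m[core_r, core_c]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1L) {
        cond <- p == 1 & b >= 2 & b <= 6 & seqs == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- p == 1 & b >= 2 & b <= 6 & seqs == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        changed <- TRUE
        sub <- m[core_r, core_c]
        sub[cond] <- 0L
        m[core_r, core_c] <- sub
      }
    }
    if (!changed) break
  }
  m[core_r, core_c]
}

# 8-neighbour offsets
.nbr8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

skeleton_graph <- function(skel) {
  pix <- which(skel != 0, arr.ind = TRUE)
  key <- paste(pix[, 1], pix[, 2])
  idx <- seq_len(nrow(pix))
  names(idx) <- key
  nbrs <- vector("list", nrow(pix))
  for (i in idx) {
    cand <- paste(pix[i, 1] + .nbr8[, 1], pix[i, 2] + .nbr8[, 2])
    nbrs[[i]] <- unname(idx[cand[cand %in% key]])
  }
  list(pix = pix, nbrs = nbrs)
}

# Breadth-first search from one endpoint to another; the returned pixel
# index sequence is simple by construction and robust to the occasional
# double-linked corner a thinning pass can leave behind.
walk_path <- function(g, from, to) {
  n <- length(g$nbrs)
  prev <- integer(n)
  seen <- logical(n)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    if (cur == to) break
    for (nb in g$nbrs[[cur]]) {
      if (!seen[nb]) {
        seen[nb] <- TRUE
        prev[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  if (!seen[to]) return(NULL)
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

#' Extract an ordered midline path from a binarized top-view mask
#'
#' The largest connected foreground component is skeletonized (Zhang-Suen
#' thinning), spur branches shorter than `spur_frac` of the total skeleton
#' size are pruned, and the resulting simple path is returned ordered from
#' the endpoint nearest `head_hint` (typically the digitized nose) to the far
#' endpoint.
#'
#' @param mask binary matrix (rows = y image rows, columns = x); non-zero is
#'   foreground.
#' @param head_hint length-2 numeric `(x, y)` = (column, row) near the head.
#' @param spur_frac branches shorter than this fraction of the skeleton pixel
#'   count are pruned before the path is traced (default 0.05).
#' @return matrix of ordered (x, y) pixel coordinates, nose end first.
#' @export
midline_from_mask <- function(mask, head_hint, spur_frac = 0.05) {
  mask <- (as.matrix(mask) != 0) * 1L
  if (!any(mask != 0)) stop("empty mask: no foreground pixels", call. = FALSE)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  big <- which.max(tab)
  if (tab[big] < 100L) stop("largest component has fewer than 100 pixels", call. = FALSE)
  comp <- (lab == big) * 1L
  skel <- zhang_suen_thin(comp)
  for (pass in 1:3) {
    g <- skeleton_graph(skel)
    deg <- lengths(g$nbrs)
    ends <- which(deg <= 1L)
    if (length(ends) <= 2L) break
    # prune spurs: walk from each endpoint until a junction; remove short walks
    npix <- nrow(g$pix)
    pruned <- FALSE
    for (e in ends) {
      path <- e; prev <- 0L; cur <- e
      repeat {
        nxt <- setdiff(g$nbrs[[cur]], prev)
        if (length(nxt) != 1L) break
        # stop at a junction pixel
        if (lengths(g$nbrs)[nxt] > 2L) { path <- c(path, nxt); break }
        prev <- cur; cur <- nxt; path <- c(path, cur)
      }
      if (length(path) - 1L < spur_frac * npix) {
        drop <- path[-length(path)]  # keep the junction pixel
        skel[g$pix[drop, , drop = FALSE]] <- 0L
        pruned <- TRUE
      }
    }
    if (!pruned) break
  }
  g <- skeleton_graph(skel)
  deg <- lengths(g$nbrs)
  ends <- which(deg <= 1L)
  if (length(ends) > 2L) {
    stop(sprintf("skeleton has %d endpoints after pruning (branched midline)",
                 length(ends)), call. = FALSE)
  }
  if (length(ends) == 0L) stop("skeleton is a closed loop; cannot order midline", call. = FALSE)
  # head_hint is (x, y) = (col, row)
  d2 <- (g$pix[ends, 2] - head_hint[1])^2 + (g$pix[ends, 1] - head_hint[2])^2
  start <- ends[which.min(d2)]
  far <- if (length(ends) == 2L) ends[ends != start] else start
  path <- walk_path(g, start, far)
  if (is.null(path) || length(path) < 2L) {
    stop("could not trace a simple skeleton path between the endpoints", call. = FALSE)
  }
  cbind(x = g$pix[path, 2], y = g$pix[path, 1])
}

#' Body-frame lateral displacement
#'
#' Defines the travel axis as the principal direction of the nose's
#' displacement over the trial and returns the signed perpendicular
#' displacement of every midline point relative to that axis, standardized to
#' BL. Positive values are to the animal's left (90 deg counterclockwise from
#' the direction of net travel).
#'
#' @param ml a [midline_sequence()] (>= 2 frames).
#' @return list with `lateral` (frames x points matrix, BL), `axis` (unit
#'   vector of travel), `origin`, and `time_s`.
#' @export
body_frame <- function(ml) {
  nf <- dim(ml$xy)[1]
  if (nf < 2L) stop_field("ml", "needs at least 2 frames")
  nose <- ml$xy[, 1, ]
  centered <- sweep(nose, 2, colMeans(nose))
  if (all(abs(centered) < 1e-12)) {
    # no net displacement: fall back to lateral variance of the whole body
    pts <- rbind(ml$xy[, , 1], ml$xy[, , 2])
    allxy <- cbind(as.vector(ml$xy[, , 1]), as.vector(ml$xy[, , 2]))
    centered <- sweep(allxy, 2, colMeans(allxy))
    if (all(abs(centered) < 1e-12)) {
      stop("no definable travel axis: zero net displacement and zero lateral variance",
           call. = FALSE)
    }
  }
  pc <- svd(centered, nu = 0, nv = 2)
  axis <- pc$v[, 1]
  # orient the axis with the net nose displacement
  disp <- nose[nf, ] - nose[1, ]
  if (sum(disp * axis) < 0) axis <- -axis
  normal <- c(-axis[2], axis[1])  # left of travel
  origin <- colMeans(nose)
  lateral <- ((ml$xy[, , 1] - origin[1]) * normal[1] +
                (ml$xy[, , 2] - origin[2]) * normal[2]) / ml$body_length
  list(lateral = lateral, axis = axis, origin = origin, time_s = ml$time_s)
}
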