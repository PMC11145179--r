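# Low-level spatial search primitives shared by the graph, clustering and
# interaction stages. All distances are Euclidean in micrometers (1 um = 1 px).

# Ring of grid-bin offsets at Chebyshev radius r.
.ring_offsets <- function(r) {
  if (r == 0L) return(matrix(0L, 1L, 2L))
  xs <- (-r):r
  top <- cbind(xs, -r)
  bot <- cbind(xs, r)
  if (r > 0L && (2L * r - 1L) > 0L) {
    ys <- (-r + 1L):(r - 1L)
    lef <- cbind(rep(-r, length(ys)), ys)
    rig <- cbind(rep(r, length(ys)), ys)
    rbind(top, bot, lef, rig)
  } else rbind(top, bot)
}

# Grid index structure: bins of side h over the bounding box.
.make_grid <- function(x, y, h) {
  x0 <- min(x); y0 <- min(y)
  bx <- as.integer(floor((x - x0) / h))
  by <- as.integer(floor((y - y0) / h))
  nbx <- max(bx) + 1L
  key <- bx + by * nbx + 1L
  members <- split(seq_along(x), key)
  list(bx = bx, by = by, nbx = nbx, nby = max(by) + 1L, members = members)
}

.grid_lookup <- function(grid, cx, cy) {
  if (cx < 0L || cy < 0L || cx >= grid$nbx || cy >= grid$nby) return(integer(0))
  grid$members[[as.character(cx + cy * grid$nbx + 1L)]] %||% integer(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' k-nearest-neighbor indices
#'
#' Grid-accelerated exact k-NN search. Ties in distance are broken by
#' ascending `ids` so results are deterministic even with equidistant or
#' duplicated coordinates.
#'
#' @param x,y numeric coordinates (um).
#' @param k number of neighbors (excluding the point itself).
#' @param ids tie-break keys, default `seq_along(x)`.
#' @return integer matrix, one row per point, `k` columns of neighbor row
#'   indices ordered by (distance, id).
#' @export
knn_index <- function(x, y, k, ids = seq_along(x)) {
  n <- length(x)
  if (n < k + 1L) stop("need at least k + 1 points for k-NN search")
  span <- max(diff(range(x)), diff(range(y)), 1e-9)
  h <- max(span / max(1, floor(sqrt(n / 2))), 1e-9)
  g <- .make_grid(x, y, h)
  out <- matrix(0L, n, k)
  max_ring <- g$nbx + g$nby + 2L
  for (i in seq_len(n)) {
    cand <- integer(0)
    r <- 0L
    res <- NULL
    while (r <= max_ring) {
      off <- .ring_offsets(r)
      for (j in seq_len(nrow(off))) {
        cand <- c(cand, .grid_lookup(g, g$bx[i] + off[j, 1L], g$by[i] + off[j, 2L]))
      }
      cc <- cand[cand != i]
      if (length(cc) >= k) {
        d2 <- (x[cc] - x[i])^2 + (y[cc] - y[i])^2
        ord <- order(d2, ids[cc])[seq_len(k)]
        # safe stop: all points within (r-1)*h are guaranteed collected
        if (sqrt(d2[ord[k]]) <= (r - 1L) * h) {
          res <- cc[ord]
          break
        }
      }
      r <- r + 1L
    }
    if (is.null(res)) { # scanned the whole grid
      cc <- cand[cand != i]
      d2 <- (x[cc] - x[i])^2 + (y[cc] - y[i])^2
      res <- cc[order(d2, ids[cc])[seq_len(k)]]
    }
    out[i, ] <- res
  }
  out
}

#' Fixed-radius neighbor lists
#'
#' @param x,y numeric coordinates (um).
#' @param r radius (um); neighbors at distance exactly `r` are included.
#' @return list of integer vectors of neighbor indices (self excluded),
#'   sorted ascending; the relation is symmetric.
#' @export
radius_neighbors <- function(x, y, r) {
  n <- length(x)
  g <- .make_grid(x, y, r)
  out <- vector("list", n)
  r2 <- r * r
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1L:1L) for (dy in -1L:1L) {
      cand <- c(cand, .grid_lookup(g, g$bx[i] + dx, g$by[i] + dy))
    }
    cand <- cand[cand != i]
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    out[[i]] <- sort(cand[d2 <= r2])
  }
  out
}

#' Density-based spatial clustering (DBSCAN)
#'
#' Textbook DBSCAN with grid-accelerated neighborhood queries. The
#' `min_pts` count includes the point itself (scikit-learn convention).
#'
#' @param x,y coordinates (um).
#' @param eps neighborhood radius (um).
#' @param min_pts minimum neighborhood size (self included) for a core point.
#' @return integer vector of cluster labels, 0 for noise.
#' @export
dbscan_labels <- function(x, y, eps, min_pts) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  nb <- radius_neighbors(x, y, eps)
  core <- vapply(nb, length, integer(1)) + 1L >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]; head <- head + 1L
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

# Level-synchronous BFS from `source` over adjacency list `adj` (sorted
# integer vectors), stopping at the first level containing a target.
# Predecessors are canonical: frontier nodes are expanded in ascending id
# order, so pred[v] is the smallest-id predecessor on a shortest path.
# Returns NULL if no target is reachable.
.bfs_nearest <- function(adj, source, is_target, max_depth = Inf) {
  n <- length(adj)
  dist <- rep(-1L, n)
  pred <- rep(0L, n)
  dist[source] <- 0L
  frontier <- source
  d <- 0L
  repeat {
    hits <- frontier[is_target[frontier]]
    if (length(hits)) return(list(dist = d, targets = sort(hits), pred = pred))
    if (d >= max_depth) return(NULL)
    nxt <- integer(0)
    for (u in sort(frontier)) {
      nb <- adj[[u]]
      new <- nb[dist[nb] < 0L]
      if (length(new)) {
        dist[new] <- d + 1L
        pred[new] <- u
        nxt <- c(nxt, new)
      }
    }
    if (!length(nxt)) return(NULL)
    frontier <- nxt
    d <- d + 1L
  }
}

# Walk canonical predecessors from target back to the source.
.bfs_path <- function(pred, source, target) {
  path <- target
  v <- target
  while (v != source) {
    v <- pred[v]
    if (v == 0L) stop("broken predecessor chain")
    path <- c(v, path)
  }
  path
}

# Shoelace polygon area; `xy` is a matrix of vertices in order.
.polygon_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L])) / 2
}

# Convex-hull boundary polygon of a point set (alpha-shape fallback).
.hull_polygon <- function(x, y) {
  idx <- grDevices::chull(x, y)
  cbind(x = x[idx], y = y[idx])
}

#' Optimal label matching between two clusterings
#'
#' Finds the one-to-one mapping of labels in `b` onto labels in `a` that
#' maximizes the number of agreeing cells (exact assignment by dynamic
#' programming over label subsets for up to 15 labels, greedy beyond).
#'
#' @param a,b label vectors of equal length.
#' @return list with `map` (named vector: label of `b` -> label of `a`) and
#'   `agreement` (fraction of cells whose mapped label agrees).
#' @export
match_labels <- function(a, b) {
  stopifnot(length(a) == length(b))
  la <- sort(unique(a)); lb <- sort(unique(b))
  C <- table(factor(b, levels = lb), factor(a, levels = la))
  k <- max(length(la), length(lb))
  M <- matrix(0, k, k)
  M[seq_along(lb), seq_along(la)] <- C
  if (k <= 15L) {
    full <- bitwShiftL(1L, k) - 1L
    dp <- rep(-Inf, full + 1L)
    dp[1L] <- 0
    masks <- 0:full
    pc <- vapply(masks, function(m) sum(bitwAnd(bitwShiftR(m, 0:(k - 1L)), 1L)), numeric(1))
    for (m in order(pc)) {
      mask <- masks[m]
      i <- pc[m]          # next row to assign is i + 1
      if (i >= k) next
      for (c in seq_len(k)) {
        bit <- bitwShiftL(1L, c - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          nm <- bitwOr(mask, bit)
          v <- dp[mask + 1L] + M[i + 1L, c]
          if (v > dp[nm + 1L]) dp[nm + 1L] <- v
        }
      }
    }
    # reconstruct assignment by walking masks backwards
    assign_col <- integer(k)
    mask <- full
    for (i in k:1) {
      for (c in seq_len(k)) {
        bit <- bitwShiftL(1L, c - 1L)
        if (bitwAnd(mask, bit) != 0L) {
          prev <- bitwAnd(mask, bitwNot(bit))
          if (isTRUE(all.equal(dp[mask + 1L], dp[prev + 1L] + M[i, c]))) {
            assign_col[i] <- c
            mask <- prev
            break
          }
        }
      }
    }
  } else {
    assign_col <- integer(k)
    Mw <- M
    for (step in seq_len(k)) {
      pos <- which(Mw == max(Mw), arr.ind = TRUE)[1L, ]
      assign_col[pos[1L]] <- pos[2L]
      Mw[pos[1L], ] <- -Inf
      Mw[, pos[2L]] <- -Inf
    }
  }
  map <- stats::setNames(rep(NA, length(lb)), lb)
  for (i in seq_along(lb)) {
    c <- assign_col[i]
    if (c <= length(la)) map[i] <- la[c]
  }
  mapped <- unname(map[as.character(b)])
  list(map = map, agreement = mean(!is.na(mapped) & mapped == a))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions; 1 for identical
#' partitions (up to label permutation), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(if (sij == maxi) 1 else 0)
  (sij - expected) / (maxi - expected)
}
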