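# Binary thinning and skeleton-graph extraction.
#
# The skeletonizer is a vectorized Zhang-Suen thinning; the resulting 1-px
# centerline is converted to a geometric graph (igraph) whose edges connect
# 8-neighboring skeleton pixels, with redundant diagonals (those bridged by a
# shared 4-neighbor) removed so lengths are not double counted. Lateral steps
# measure pixel_size, diagonal steps sqrt(2) * pixel_size — the convention is
# fixed for bit-reproducibility.

#' Zhang-Suen thinning of a binary raster
#'
#' @param bw logical or 0/1 matrix \[ix, iy\]
#' @param max_iter safety bound on thinning passes
#' @return logical matrix of the 1-pixel-wide skeleton
#' @export
thin_binary <- function(bw, max_iter = 200L) {
  w <- nrow(bw); h <- ncol(bw)
  img <- matrix(0L, w + 2L, h + 2L)
  img[2:(w + 1), 2:(h + 1)] <- (bw > 0) * 1L
  ci <- 2:(w + 1); cj <- 2:(h + 1)
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (step in 1:2) {
      p <- img[ci, cj]
      p2 <- img[ci, cj - 1]; p3 <- img[ci + 1, cj - 1]
      p4 <- img[ci + 1, cj]; p5 <- img[ci + 1, cj + 1]
      p6 <- img[ci, cj + 1]; p7 <- img[ci - 1, cj + 1]
      p8 <- img[ci - 1, cj]; p9 <- img[ci - 1, cj - 1]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        del <- p == 1 & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        del <- p == 1 & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      if (any(del)) {
        sub <- img[ci, cj]; sub[del] <- 0L; img[ci, cj] <- sub
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[ci, cj] > 0
}

#' Build a skeleton graph from a binary neurite raster
#'
#' Thins the raster, links 8-neighboring skeleton pixels into an igraph
#' (lateral edge weight = `pixel_size_um`, diagonal = `sqrt(2) *
#' pixel_size_um`; diagonals bridged by a shared lateral neighbor are
#' dropped), prunes terminal spurs shorter than `spur_min_um`, and decomposes
#' the result into segments: maximal paths between nodes of degree != 2
#' ("sections"). Total length equals the sum of edge weights and, exactly,
#' the sum of segment lengths.
#'
#' @param mask binary matrix \[ix, iy\]
#' @param pixel_size_um micrometers per pixel
#' @param spur_min_um prune terminal branches shorter than this (default 1)
#' @return a `skeleton_graph`: list with `graph`, `coords_um`, `degree`,
#'   `total_length_um`, `segments` (each with `path`, `polyline_um`,
#'   `length_um`), `n_segments`, `pixel_size_um`
#' @export
skeletonize <- function(mask, pixel_size_um, spur_min_um = 1) {
  skel <- thin_binary(mask)
  empty <- structure(list(graph = igraph::make_empty_graph(directed = FALSE),
                          coords_um = matrix(numeric(0), 0, 2),
                          degree = integer(0), total_length_um = 0,
                          segments = list(), n_segments = 0L,
                          pixel_size_um = pixel_size_um),
                     class = "skeleton_graph")
  if (!any(skel)) return(empty)

  w <- nrow(skel); h <- ncol(skel)
  id <- matrix(0L, w, h)
  pix <- which(skel)
  id[pix] <- seq_along(pix)
  ix <- ((pix - 1L) %% w) + 1L
  iy <- ((pix - 1L) %/% w) + 1L

  nb_id <- function(dx, dy) {
    jx <- ix + dx; jy <- iy + dy
    ok <- jx >= 1L & jx <= w & jy >= 1L & jy <= h
    out <- integer(length(pix))
    out[ok] <- id[cbind(jx[ok], jy[ok])]
    out
  }
  e_r <- nb_id(1L, 0L); e_d <- nb_id(0L, 1L)
  e_dr <- nb_id(1L, 1L); e_ur <- nb_id(1L, -1L)
  # a diagonal is redundant when either shared 4-neighbor is also skeleton
  dr_ok <- e_dr > 0 & !(e_r > 0 | e_d > 0)
  u_up <- nb_id(0L, -1L)
  ur_ok <- e_ur > 0 & !(e_r > 0 | u_up > 0)

  from <- c(seq_along(pix)[e_r > 0], seq_along(pix)[e_d > 0],
            seq_along(pix)[dr_ok], seq_along(pix)[ur_ok])
  to <- c(e_r[e_r > 0], e_d[e_d > 0], e_dr[dr_ok], e_ur[ur_ok])
  wt <- c(rep(pixel_size_um, sum(e_r > 0) + sum(e_d > 0)),
          rep(sqrt(2) * pixel_size_um, sum(dr_ok) + sum(ur_ok)))

  g <- igraph::make_graph(rbind(from, to), n = length(pix), directed = FALSE)
  igraph::E(g)$weight <- wt
  coords <- cbind(px_to_um(ix, pixel_size_um), px_to_um(iy, pixel_size_um))

  pruned <- prune_spurs(g, coords, spur_min_um)
  g <- pruned$graph
  keep <- pruned$keep
  coords <- coords[keep, , drop = FALSE]
  if (igraph::vcount(g) == 0 || igraph::ecount(g) == 0) return(empty)

  segs <- extract_segments(g, coords)
  structure(list(graph = g, coords_um = coords,
                 degree = igraph::degree(g),
                 total_length_um = sum(igraph::E(g)$weight),
                 segments = segs, n_segments = length(segs),
                 pixel_size_um = pixel_size_um),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %.1f um total in %d segments (%d nodes)\n",
              x$total_length_um, x$n_segments, nrow(x$coords_um)))
  invisible(x)
}

# Iteratively delete terminal chains shorter than spur_min_um that end at a
# junction (degree >= 3); short isolated components are removed too. Chain
# lengths are recomputed from pixel-centre coordinates (adjacent skeleton
# pixels are exactly 1 or sqrt(2) pixels apart, so this equals the edge
# weights).
prune_spurs <- function(g, coords, spur_min_um, max_rounds = 6L) {
  keep_orig <- seq_len(igraph::vcount(g))
  cc <- coords
  for (round in seq_len(max_rounds)) {
    deg <- igraph::degree(g)
    leaves <- which(deg == 1)
    adj <- igraph::as_adj_list(g)
    drop <- integer(0)
    for (lf in leaves) {
      path <- lf; len <- 0
      prev <- -1L; cur <- lf
      repeat {
        nbrs <- as.integer(adj[[cur]])
        nxt <- nbrs[nbrs != prev]
        if (length(nxt) != 1L) break         # junction, leaf or isolated
        len <- len + sqrt(sum((cc[nxt, ] - cc[cur, ])^2))
        if (len >= spur_min_um) break
        prev <- cur; cur <- nxt
        if (deg[cur] != 2L) break
        path <- c(path, cur)
      }
      ended_at_junction <- deg[cur] > 2L
      if (len < spur_min_um && ended_at_junction) drop <- c(drop, path)
    }
    # also drop tiny isolated components
    comp <- igraph::components(g)
    csize_len <- tapply(seq_len(igraph::vcount(g)), comp$membership,
                        function(vs) {
      sub <- igraph::induced_subgraph(g, vs)
      sum(igraph::E(sub)$weight)
    })
    for (nm in names(csize_len)[csize_len < spur_min_um]) {
      drop <- c(drop, which(comp$membership == as.integer(nm)))
    }
    drop <- unique(drop)
    if (!length(drop)) break
    keep_orig <- keep_orig[-drop]
    cc <- cc[-drop, , drop = FALSE]
    g <- igraph::delete_vertices(g, drop)
  }
  list(graph = g, keep = keep_orig)
}

# Decompose into maximal degree-2 chains between terminals (degree != 2).
# Pure cycles (components where every node has degree 2) form one segment.
# Each edge belongs to exactly one segment, so segment lengths sum to the
# graph total exactly.
extract_segments <- function(g, coords) {
  deg <- igraph::degree(g)
  adj_e <- igraph::as_adj_edge_list(g)
  ends_m <- igraph::ends(g, igraph::E(g), names = FALSE)
  ew <- igraph::E(g)$weight
  other_end <- function(eid, v) {
    if (ends_m[eid, 1] == v) ends_m[eid, 2] else ends_m[eid, 1]
  }
  visited_e <- logical(igraph::ecount(g))
  segs <- list()
  walk <- function(start, first_edge) {
    eid <- as.integer(first_edge)
    cur <- other_end(eid, start)
    path <- c(start, cur); len <- ew[eid]; visited_e[eid] <<- TRUE
    while (deg[cur] == 2L) {
      es_c <- as.integer(adj_e[[cur]])
      nxt_i <- which(!visited_e[es_c])
      if (!length(nxt_i)) break              # closed a cycle
      eid <- es_c[nxt_i[1]]
      visited_e[eid] <<- TRUE
      len <- len + ew[eid]
      cur <- other_end(eid, cur)
      path <- c(path, cur)
    }
    list(path = path, polyline_um = coords[path, , drop = FALSE],
         length_um = len)
  }
  terminals <- which(deg != 2L)
  for (t in terminals) {
    for (e in as.integer(adj_e[[t]])) {
      if (!visited_e[e]) segs[[length(segs) + 1L]] <- walk(t, e)
    }
  }
  # remaining unvisited edges belong to pure cycles
  while (any(!visited_e)) {
    e0 <- which(!visited_e)[1]
    v0 <- as.integer(ends_m[e0, 1])
    segs[[length(segs) + 1L]] <- walk(v0, e0)
  }
  segs
}
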