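#' Thin a binary mask to its morphological skeleton
#'
#' Zhang-Suen iterative thinning: boundary pixels are peeled in two alternating
#' sub-iterations until the shape is reduced to a one-pixel-wide skeleton that
#' preserves connectivity.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same size containing the skeleton.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.logical(mask)
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbors clockwise from north (rows grow downward)
      p2 <- shift(m, 1L, 0L);  p3 <- shift(m, 1L, -1L)
      p4 <- shift(m, 0L, -1L); p5 <- shift(m, -1L, -1L)
      p6 <- shift(m, -1L, 0L); p7 <- shift(m, -1L, 1L)
      p8 <- shift(m, 0L, 1L);  p9 <- shift(m, 1L, 1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- m & b >= 2 & b <= 6 & a == 1
      if (step == 1L) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L), drop = FALSE]
}

# Longest geodesic chain through one connected skeleton fragment.
# coords: n x 2 matrix (x = col, y = row) of skeleton pixels, 8-connected.
# Returns list(path = ordered coords along the chain, length = geodesic
# length in physical units given per-axis pixel sizes sx, sy).
skeleton_chain <- function(coords, sx = 1, sy = 1) {
  n <- nrow(coords)
  if (n == 1L) return(list(path = coords, length = 0))
  dx <- outer(coords[, 1L], coords[, 1L], "-")
  dy <- outer(coords[, 2L], coords[, 2L], "-")
  adj <- abs(dx) <= 1 & abs(dy) <= 1
  diag(adj) <- FALSE
  wmat <- sqrt((dx * sx)^2 + (dy * sy)^2)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(path = coords[1L, , drop = FALSE], length = 0))
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- wmat[idx]
  d <- igraph::distances(g)
  d[!is.finite(d)] <- -1
  ends <- which(d == max(d), arr.ind = TRUE)[1L, ]
  path <- igraph::shortest_paths(g, from = ends[1L], to = ends[2L],
                                 output = "vpath")$vpath[[1L]]
  path <- as.integer(path)
  list(path = coords[path, , drop = FALSE], length = max(d))
}

#' Reconstruct a single skeleton chain from a (possibly fragmented) mask
#'
#' The mask is thinned to its skeleton; each connected fragment is reduced to
#' its longest geodesic chain; fragment chains are then greedily bridged at
#' their endpoints -- nearest admissible endpoint pair first -- when the gap is
#' shorter than `max_gap_px` and the bridge direction deviates less than
#' `max_angle_deg` from both fragment end tangents. Echoes of elongated fish
#' are frequently fragmented, and the bridged chain recovers the full body
#' length.
#'
#' @param mask Logical matrix (nonempty).
#' @param sx,sy Physical pixel size along x (columns) and y (rows); lengths
#'   are returned in the same unit.
#' @param max_gap_px Maximum endpoint gap bridged, in pixels.
#' @param max_angle_deg Maximum deviation between a bridge and each fragment's
#'   end tangent, degrees. The default (65) admits bridges across the crest
#'   of an undulating body (where the local tangent can deviate ~40 degrees
#'   from the travel axis) while still rejecting near-perpendicular bridges
#'   between distinct parallel bodies.
#' @return List with `chains` (list of ordered coordinate matrices),
#'   `chain_lengths`, `length` (the longest chain's geodesic length, physical
#'   units), `n_fragments` (fragments before bridging) and `n_bridges`.
#' @export
reconstruct_skeleton <- function(mask, sx = 1, sy = 1,
                                 max_gap_px = 20, max_angle_deg = 65) {
  stopifnot(any(mask))
  skel <- thin_mask(mask)
  if (!any(skel)) {  # shapes thinner than 2 px can vanish; keep the mask
    skel <- mask
  }
  lab <- label_components(skel)
  nfrag <- max(lab)
  chains <- vector("list", nfrag)
  for (i in seq_len(nfrag)) {
    idx <- which(lab == i, arr.ind = TRUE)
    coords <- cbind(x = idx[, 2L], y = idx[, 1L])
    chains[[i]] <- skeleton_chain(coords, sx, sy)
  }

  end_tangent <- function(path, from_end) {
    # outward direction at a chain end, averaged over up to 5 pixels
    n <- nrow(path)
    k <- min(5L, n)
    if (n < 2L) return(NULL)
    if (from_end == "tail") {
      v <- path[n, ] - path[n - k + 1L, ]
    } else {
      v <- path[1L, ] - path[k, ]
    }
    v / sqrt(sum(v^2))
  }
  angle_between <- function(u, v) {
    acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
  }

  n_bridges <- 0L
  repeat {
    if (length(chains) < 2L) break
    best <- NULL
    for (i in seq_along(chains)) for (j in seq_along(chains)) {
      if (i >= j) next
      for (ei in c("head", "tail")) for (ej in c("head", "tail")) {
        pi_ <- chains[[i]]$path
        pj <- chains[[j]]$path
        a <- if (ei == "head") pi_[1L, ] else pi_[nrow(pi_), ]
        b <- if (ej == "head") pj[1L, ] else pj[nrow(pj), ]
        gap <- sqrt(sum((a - b)^2))
        if (gap >= max_gap_px || gap == 0) next
        dir_ab <- (b - a) / gap
        ti <- end_tangent(pi_, if (ei == "head") "head" else "tail")
        tj <- end_tangent(pj, if (ej == "head") "head" else "tail")
        if (!is.null(ti) && angle_between(ti, dir_ab) >= max_angle_deg) next
        if (!is.null(tj) && angle_between(tj, -dir_ab) >= max_angle_deg) next
        if (is.null(best) || gap < best$gap) {
          best <- list(i = i, j = j, ei = ei, ej = ej, gap = gap, a = a, b = b)
        }
      }
    }
    if (is.null(best)) break
    ci <- chains[[best$i]]; cj <- chains[[best$j]]
    pi_ <- ci$path; pj <- cj$path
    if (best$ei == "head") pi_ <- pi_[nrow(pi_):1L, , drop = FALSE]
    if (best$ej == "tail") pj <- pj[nrow(pj):1L, , drop = FALSE]
    bridge_len <- sqrt(((best$a[1L] - best$b[1L]) * sx)^2 +
                       ((best$a[2L] - best$b[2L]) * sy)^2)
    merged <- list(path = rbind(pi_, pj),
                   length = ci$length + cj$length + bridge_len)
    chains[[best$i]] <- merged
    chains[[best$j]] <- NULL
    n_bridges <- n_bridges + 1L
  }

  lens <- vapply(chains, `[[`, numeric(1L), "length")
  list(chains = lapply(chains, `[[`, "path"),
       chain_lengths = lens,
       length = max(lens),
       n_fragments = nfrag,
       n_bridges = n_bridges)
}
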