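# Grey-level texture matrices over a discretized ROI. All matrices use the
# 13 unique 3D directions at distance 1 (symmetric co-occurrence), zones use
# 26-connectivity, and the distance-zone map uses city-block distance to the
# ROI border (border voxels have distance 1), following the common IBSI
# conventions.

directions13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# aligned sub-arrays of `a` at offset d (src voxel and its d-neighbour)
shifted_pair <- function(a, d) {
  D <- dim(a)
  rng <- lapply(1:3, function(ax) {
    if (d[ax] >= 0) {
      list(src = seq_len(D[ax] - d[ax]), dst = seq_len(D[ax] - d[ax]) + d[ax])
    } else {
      list(src = seq_len(D[ax] + d[ax]) - d[ax], dst = seq_len(D[ax] + d[ax]))
    }
  })
  list(src = a[rng[[1]]$src, rng[[2]]$src, rng[[3]]$src, drop = FALSE],
       dst = a[rng[[1]]$dst, rng[[2]]$dst, rng[[3]]$dst, drop = FALSE])
}

glcm_one <- function(bins, d, ng) {
  p <- shifted_pair(bins, d)
  keep <- p$src > 0L & p$dst > 0L
  a <- p$src[keep]; b <- p$dst[keep]
  if (length(a) == 0L) return(matrix(0, ng, ng))
  M <- matrix(tabulate(a + (b - 1L) * ng, nbins = ng * ng), ng, ng)
  M + t(M)
}

glrlm_one <- function(bins_vec, coords, d, ng, D) {
  a0 <- which(d != 0)[1]
  t <- coords[, a0] * sign(d[a0])
  lid <- coords - outer(t, d)
  off <- max(D) + 1L
  M1 <- 3L * max(D) + 3L
  key <- (lid[, 1] + off) + (lid[, 2] + off) * M1 + (lid[, 3] + off) * M1^2
  ord <- order(key, t)
  g <- bins_vec[ord]; k <- key[ord]; tt <- t[ord]
  n <- length(g)
  new_run <- c(TRUE, k[-1] != k[-n] | g[-1] != g[-n] | tt[-1] != tt[-n] + 1)
  run_id <- cumsum(new_run)
  len <- tabulate(run_id)
  grey <- g[new_run]
  keep <- grey > 0L
  len <- len[keep]; grey <- grey[keep]
  if (length(len) == 0L) return(matrix(0, ng, 1))
  maxlen <- max(len)
  matrix(tabulate(grey + (len - 1L) * ng, nbins = ng * maxlen), ng, maxlen)
}

# connected zones (26-connectivity) of equal grey level within the mask;
# returns per-zone grey level, size, and minimum border distance
roi_zones <- function(bins, dmap, ng) {
  D <- dim(bins)
  in_idx <- which(bins > 0L)
  nvox <- length(in_idx)
  vid <- integer(length(bins))
  vid[in_idx] <- seq_len(nvox)
  edges_from <- integer(0); edges_to <- integer(0)
  for (r in seq_len(nrow(directions13))) {
    d <- directions13[r, ]
    p <- shifted_pair(bins, d)
    keep <- p$src > 0L & p$src == p$dst
    if (!any(keep)) next
    # linear indices of src and dst voxels inside the cropped window
    idx <- shifted_pair(array(seq_along(bins), D), d)
    edges_from <- c(edges_from, vid[idx$src[keep]])
    edges_to <- c(edges_to, vid[idx$dst[keep]])
  }
  comp <- if (length(edges_from) > 0) {
    gr <- igraph::graph_from_edgelist(cbind(edges_from, edges_to),
                                      directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, nvox - igraph::vcount(gr)))
    igraph::components(gr)$membership
  } else {
    seq_len(nvox)
  }
  zs <- tabulate(comp)
  zg <- integer(max(comp)); zd <- integer(max(comp))
  bins_in <- bins[in_idx]; d_in <- dmap[in_idx]
  zg[comp] <- bins_in                     # same grey across a zone
  o <- order(comp, d_in)
  first <- !duplicated(comp[o])
  zd[comp[o][first]] <- d_in[o][first]    # min distance per zone
  list(grey = zg, size = zs, dist = zd)
}

# city-block distance to the ROI border (border voxel = 1), by peeling
border_distance_map <- function(mask_arr) {
  D <- dim(mask_arr)
  dmap <- array(0L, D)
  cur <- mask_arr
  k <- 1L
  while (any(cur)) {
    pad <- array(FALSE, D + 2L)
    pad[2:(D[1] + 1), 2:(D[2] + 1), 2:(D[3] + 1)] <- cur
    inner <- pad[1:D[1], 2:(D[2] + 1), 2:(D[3] + 1)] &
      pad[3:(D[1] + 2), 2:(D[2] + 1), 2:(D[3] + 1)] &
      pad[2:(D[1] + 1), 1:D[2], 2:(D[3] + 1)] &
      pad[2:(D[1] + 1), 3:(D[2] + 2), 2:(D[3] + 1)] &
      pad[2:(D[1] + 1), 2:(D[2] + 1), 1:D[3]] &
      pad[2:(D[1] + 1), 2:(D[2] + 1), 3:(D[3] + 2)]
    shell <- cur & !inner
    dmap[shell] <- k
    cur <- cur & !shell
    k <- k + 1L
  }
  dmap
}

ngtdm_build <- function(bins, ng) {
  D <- dim(bins)
  inm <- bins > 0L
  g_num <- array(as.numeric(bins), D)
  g_num[!inm] <- 0
  ind <- array(as.numeric(inm), D)
  S <- array(0, D); C <- array(0, D)
  add_shift <- function(acc, a, d) {
    out <- array(0, dim(a))
    p <- shifted_pair(array(seq_along(a), dim(a)), d)
    out[p$src] <- out[p$src] + a[p$dst]
    out[p$dst] <- out[p$dst] + a[p$src]
    acc + out
  }
  for (r in seq_len(nrow(directions13))) {
    d <- directions13[r, ]
    S <- add_shift(S, g_num, d)
    C <- add_shift(C, ind, d)
  }
  valid <- inm & C > 0
  g <- bins[valid]
  nbar <- S[valid] / C[valid]
  ni <- tabulate(g, nbins = ng)
  si <- numeric(ng)
  contrib <- abs(g - nbar)
  si_agg <- tapply(contrib, factor(g, levels = seq_len(ng)), sum)
  si[!is.na(si_agg)] <- si_agg[!is.na(si_agg)]
  list(n_i = ni, s_i = si, n_valid = sum(ni))
}

#' Build the grey-level texture matrices of a discretized ROI
#'
#' Computes, from a [discretize()] result: symmetric distance-1 co-occurrence
#' matrices and run-length matrices for the 13 unique 3D directions,
#' size-zone and distance-zone matrices over 26-connected equal-grey zones
#' (zone distance = minimum city-block distance to the ROI border, border
#' voxels at distance 1), and the neighbourhood grey-tone difference vectors
#' over the full 26-neighbourhood.
#'
#' @param d An `edr_discrete` object from [discretize()].
#' @return An object of class `edr_texture_matrices`.
#' @export
texture_matrices <- function(d) {
  stopifnot(inherits(d, "edr_discrete"))
  bins <- d$bins
  ng <- d$n_bins
  if (sum(bins > 0L) < 2) abort("discretized ROI must have >= 2 voxels")
  D <- dim(bins)
  glcm <- lapply(seq_len(nrow(directions13)), function(r) {
    glcm_one(bins, directions13[r, ], ng)
  })
  coords <- arrayInd(seq_along(bins), D)
  bins_vec <- as.integer(bins)
  glrlm <- lapply(seq_len(nrow(directions13)), function(r) {
    glrlm_one(bins_vec, coords, directions13[r, ], ng, D)
  })
  dmap <- border_distance_map(bins > 0L)
  zones <- roi_zones(bins, dmap, ng)
  glszm <- matrix(tabulate(zones$grey + (zones$size - 1L) * ng,
                           nbins = ng * max(zones$size)), ng, max(zones$size))
  gldzm <- matrix(tabulate(zones$grey + (zones$dist - 1L) * ng,
                           nbins = ng * max(zones$dist)), ng, max(zones$dist))
  ngtdm <- ngtdm_build(bins, ng)
  structure(list(glcm = glcm, glrlm = glrlm, glszm = glszm, gldzm = gldzm,
                 ngtdm = ngtdm, n_bins = ng, n_voxels = sum(bins > 0L)),
            class = "edr_texture_matrices")
}
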