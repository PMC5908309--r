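# Brute-force oracles, deliberately independent of the package internals:
# plain-R distance scans, flood fills and permutation enumeration used to
# cross-check the compiled geometry and the spot/statistics implementations.

# Exhaustive per-pixel nearest-nucleus scan: for every background pixel the
# Euclidean distance (pixel centres) to every nucleus is computed by full
# scan. Returns per background pixel the nearest distance and label (equal
# distances resolve to the lower label) and the distance to the nearest
# OTHER nucleus.
oracle_nearest <- function(labels, mpp) {
  ids <- sort(unique(labels[labels > 0]))
  bg <- which(labels == 0, arr.ind = TRUE)
  dk <- sapply(ids, function(k) {
    np <- which(labels == k, arr.ind = TRUE)
    d2 <- outer(bg[, 1], np[, 1], "-")^2 + outer(bg[, 2], np[, 2], "-")^2
    sqrt(apply(d2, 1, min)) * mpp
  })
  dk <- matrix(dk, nrow = nrow(bg))
  wmin <- apply(dk, 1, which.min)  # first minimum = lower label on ties
  best <- dk[cbind(seq_len(nrow(bg)), wmin)]
  second <- apply(dk, 1, function(z) if (length(z) > 1) sort(z)[2] else Inf)
  list(bg = bg, best_um = best, who = ids[wmin], second_um = second)
}

# ring assignment from the oracle scan: pixels within width_um of their
# nearest nucleus, assigned to it
oracle_ring_labels <- function(labels, width_um, mpp) {
  on <- oracle_nearest(labels, mpp)
  ring <- matrix(0L, nrow(labels), ncol(labels))
  sel <- on$best_um <= width_um
  ring[on$bg[sel, , drop = FALSE]] <- on$who[sel]
  ring
}

# the ring-width decision rule applied literally via the oracle scan:
# widest w in widths with median per-cell contested ring fraction < 0.2
oracle_ring_width <- function(labels, mpp, widths = 1:5) {
  on <- oracle_nearest(labels, mpp)
  ids <- sort(unique(labels[labels > 0]))
  best <- min(widths)
  for (w in sort(widths)) {
    inring <- on$best_um <= w
    if (!any(inring)) next
    frac <- sapply(ids, function(k) {
      tot <- sum(inring & on$who == k)
      if (tot == 0) return(NA_real_)
      sum(inring & on$who == k & on$second_um <= w) / tot
    })
    if (isTRUE(median(frac, na.rm = TRUE) < 0.2)) best <- w
  }
  best
}

# 8-connected flood fill in plain R (queue-based)
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (jj in seq_len(nc)) for (ii in seq_len(nr)) {
    if (mask[ii, jj] && lab[ii, jj] == 0L) {
      cur <- cur + 1L
      queue <- list(c(ii, jj))
      lab[ii, jj] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ni <- p[1] + di; nj <- p[2] + dj
          if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            queue[[length(queue) + 1L]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# threshold -> 8-connected components -> area filter -> per-cell counts,
# restricted to ring masks, ownership by rounded centroid with majority
# fallback; mirrors the documented detection contract
oracle_puncta_counts <- function(cc3, ring_labels, thr, min_a, max_a, mpp) {
  mask <- (cc3 > thr) & (ring_labels > 0L)
  lab <- oracle_label8(mask)
  counts <- integer(0)
  if (max(lab) == 0L) return(counts)
  for (s in seq_len(max(lab))) {
    pix <- which(lab == s, arr.ind = TRUE)
    a <- nrow(pix) * mpp^2
    if (a < min_a || a > max_a) next
    ctr <- colMeans(pix)
    own <- ring_labels[round(ctr[1]), round(ctr[2])]
    if (own == 0L) {
      rl <- ring_labels[pix]
      own <- as.integer(names(which.max(table(rl[rl > 0L]))))
    }
    key <- as.character(own)
    counts[key] <- if (key %in% names(counts)) counts[[key]] + 1L else 1L
  }
  counts
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# --- small constructed inputs ------------------------------------------

# label raster with one filled disk per (row, col, radius_px) row
disk_labels <- function(nr, nc, disks) {
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(disks))) {
    rr <- seq_len(nr); cc <- seq_len(nc)
    d2 <- outer((rr - disks[i, 1])^2, (cc - disks[i, 2])^2, "+")
    lab[d2 <= disks[i, 3]^2] <- i
  }
  lab
}

# 64 x 64 spot tile at 0.4 um/px: one central nucleus, implementation ring
# mask, and blobs of prescribed pixel counts placed on 8 angular slots in
# the perinuclear ring (far enough apart never to touch). Returns the CC3
# raster, the rings object and the per-slot rendered areas.
make_spot_tile <- function(seed, mpp = 0.4, thr = 10000, amp = 30000) {
  set.seed(seed)
  nr <- 64L
  lab <- disk_labels(nr, nr, cbind(32, 32, 8))
  nmap <- nucleus_label_map(lab, mpp)
  rings <- make_cytoplasm_rings(nmap, 5)
  cc3 <- matrix(round(rnorm(nr * nr, 500, 50)), nr, nr)
  cc3[cc3 < 0] <- 0L
  storage.mode(cc3) <- "integer"
  # candidate blob pixel counts: in-window sizes plus the 0.1 and 6.0 um^2
  # decoys (1 px = 0.16 um^2 < 0.2; 38 px = 6.08 um^2 > 5)
  sizes_px <- c(sample(2:30, 6, replace = TRUE), 1L, 38L)
  slots <- sample(8L)  # randomise which slot carries which blob
  angles <- (slots - 1) * pi / 4
  rendered <- numeric(0)
  for (i in seq_along(sizes_px)) {
    ctr <- c(32 + round(14 * cos(angles[i])), 32 + round(14 * sin(angles[i])))
    g <- expand.grid(di = -5:5, dj = -5:5)
    g <- g[order(g$di^2 + g$dj^2, g$dj, g$di), ]
    px <- cbind(ctr[1] + g$di, ctr[2] + g$dj)[seq_len(sizes_px[i]), ,
                                              drop = FALSE]
    cc3[px] <- amp
    rendered <- c(rendered, sizes_px[i] * mpp^2)
  }
  list(cc3 = cc3, rings = rings, rendered_areas = rendered, thr = thr,
       mpp = mpp)
}
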