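# Independent brute-force oracles. Each reimplements a primitive from its
# mathematical definition, with no shared code with the package internals.

# grayscale erosion/dilation by explicit double loops; structuring element
# restricted to the image domain at borders (same convention as the package)
oracle_gray_erode <- function(img, dx, dy, h) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- Inf
    for (s in seq_along(dx)) {
      ii <- i + dy[s]; jj <- j + dx[s]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      v <- img[ii, jj] - h[s]
      if (v < best) best <- v
    }
    out[i, j] <- best
  }
  out
}

oracle_gray_dilate <- function(img, dx, dy, h) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- -Inf
    for (s in seq_along(dx)) {
      ii <- i - dy[s]; jj <- j - dx[s]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      v <- img[ii, jj] + h[s]
      if (v > best) best <- v
    }
    out[i, j] <- best
  }
  out
}

oracle_ball_se <- function(radius) {
  r <- ceiling(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  keep <- off$dx^2 + off$dy^2 <= radius^2
  list(dx = off$dx[keep], dy = off$dy[keep],
       h = sqrt(radius^2 - (off$dx^2 + off$dy^2)[keep]))
}

oracle_rolling_ball <- function(img, radius) {
  se <- oracle_ball_se(radius)
  img - pmin(img, oracle_gray_dilate(oracle_gray_erode(img, se$dx, se$dy, se$h),
                                     se$dx, se$dy, se$h))
}

# Otsu by exhaustive scan: for each of the 255 inter-bin cuts of a 256-bin
# histogram over [min, max], compute between-class variance from scratch
oracle_otsu_threshold <- function(raster) {
  lo <- min(raster); hi <- max(raster)
  nb <- 256
  bin <- pmin(nb - 1, floor((raster - lo) / (hi - lo) * nb))
  best_k <- NA; best_v <- -Inf
  for (k in 0:(nb - 2)) {
    left <- bin <= k
    n0 <- sum(left); n1 <- sum(!left)
    if (n0 == 0 || n1 == 0) v <- 0
    else {
      mu0 <- mean(bin[left]); mu1 <- mean(bin[!left])
      v <- n0 * n1 * (mu0 - mu1)^2
    }
    if (v > best_v + 1e-9) { best_v <- v; best_k <- k }
  }
  lo + (best_k + 1) * (hi - lo) / nb
}

# connected-component labeling by explicit flood fill; relabeled to match
# column-major first-encounter order
oracle_label_components <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    nb <- cbind(rep(-1:1, each = 3), rep(-1:1, 3))
    nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (s in seq_len(nrow(nb))) {
        ii <- p[1] + nb[s, 1]; jj <- p[2] + nb[s, 2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (mask[ii, jj] && lab[ii, jj] == 0) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# winding-number point-in-polygon (signed angle accumulation)
oracle_winding_inside <- function(px, py, polygon) {
  vapply(seq_along(px), function(k) {
    dxs <- polygon[, 1] - px[k]; dys <- polygon[, 2] - py[k]
    ang <- atan2(dys, dxs)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi # winding number != 0
  }, logical(1))
}

# two-sided exact rank-sum p by enumeration over all choose(n, na) splits,
# measured as deviation of the group-A rank sum from its mean
oracle_ranksum_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  splits <- utils::combn(n, na)
  ws <- apply(splits, 2, function(idx) sum(r[idx]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# textbook BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m); out[o] <- adj
  out
}

# greedy nearest-pair bipartite matching between detections and truth
match_count <- function(det, truth, max_dist) {
  if (nrow(det) == 0 || nrow(truth) == 0) return(0L)
  d <- sqrt(outer(det$x, truth$x, "-")^2 + outer(det$y, truth$y, "-")^2)
  n <- 0L
  repeat {
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
    if (!is.finite(d[m]) || d[m] > max_dist) break
    n <- n + 1L
    d[m[1], ] <- Inf; d[, m[2]] <- Inf
  }
  n
}

# per-pixel disk rasterization from the definition (pixel centre within
# radius of any centre)
oracle_disk_pixels <- function(h, w, centers, radius) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    x <- j - 0.5; y <- i - 0.5
    for (k in seq_len(nrow(centers))) {
      if ((x - centers[k, 1])^2 + (y - centers[k, 2])^2 <= radius^2) {
        m[i, j] <- TRUE; break
      }
    }
  }
  m
}
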