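## Independent brute-force oracles. These deliberately avoid the code
## paths used by the package (EBImage filtering, vectorized rasterizers)
## so that agreement is evidence, not tautology.

## shift-based binary dilation: OR of the mask translated by every active
## kernel offset, out-of-bounds contributions ignored
bfDilate <- function(m, kern) {
  r <- (nrow(kern) - 1L) / 2L
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  for (dy in -r:r) for (dx in -r:r) {
    if (kern[dy + r + 1L, dx + r + 1L] == 0) next
    ys <- max(1L, 1L - dy):min(H, H - dy)
    xs <- max(1L, 1L - dx):min(W, W - dx)
    out[ys + dy, xs + dx] <- out[ys + dy, xs + dx] | m[ys, xs]
  }
  out
}

## erosion by duality with the reflected kernel (same border convention:
## neighbors outside the image do not constrain the minimum)
bfErode <- function(m, kern) {
  !bfDilate(!m, kern[rev(seq_len(nrow(kern))), rev(seq_len(ncol(kern)))])
}

bfClose <- function(m, kern) bfErode(bfDilate(m, kern), kern)

## the interface formula composed from the brute-force primitives
bfInterface <- function(labels, kern) {
  IT <- labels == 1L
  IS <- labels == 2L
  Tc <- bfClose(IT, kern)
  Sc <- bfClose(IS, kern)
  band <- xor(bfDilate(Sc, kern), bfErode(Sc, kern))
  band & Sc & bfDilate(Tc, kern)
}

## queue-based flood fill component recount
bfComponents <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(0,-1), c(0,1), c(1,0))
  nxt <- 0L
  for (y in seq_len(H)) for (x in seq_len(W)) {
    if (!mask[y, x] || lab[y, x] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(y, x)); lab[y, x] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        ny <- p[1] + nb[k, 1]; nx <- p[2] + nb[k, 2]
        if (ny >= 1 && ny <= H && nx >= 1 && nx <= W &&
            mask[ny, nx] && lab[ny, nx] == 0L) {
          lab[ny, nx] <- nxt
          queue[[length(queue) + 1]] <- c(ny, nx)
        }
      }
    }
  }
  lab
}

## CIE L from sRGB by the standard formulas (D65), independent of
## grDevices::convertColor
bfLightness <- function(r, g, b) {
  lin <- function(u) ifelse(u <= 0.04045, u / 12.92,
                            ((u + 0.055) / 1.055)^2.4)
  R <- lin(r); G <- lin(g); B <- lin(b)
  Y <- 0.2126390 * R + 0.7151687 * G + 0.0721923 * B
  f <- ifelse(Y > (6 / 29)^3, Y^(1 / 3), Y * (29 / 6)^2 / 3 + 4 / 29)
  116 * f - 16
}

## average precision by exhaustive threshold enumeration
bfAveragePrecision <- function(scores, truth) {
  P <- sum(truth)
  thr <- sort(unique(scores), decreasing = TRUE)
  prevRec <- 0; ap <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(sel & truth)
    prec <- tp / sum(sel)
    rec <- tp / P
    ap <- ap + prec * (rec - prevRec)
    prevRec <- rec
  }
  ap
}

## hypergeometric upper tail by direct summation of choose() terms
bfHyperTail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

## scalar-loop even-odd point-in-polygon (crossing count per pixel)
bfPointInPolygon <- function(x, y, poly) {
  n <- nrow(poly)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    yi <- poly[i, 2]; yj <- poly[j, 2]
    xi <- poly[i, 1]; xj <- poly[j, 1]
    if ((yi > y) != (yj > y)) {
      xcross <- (xj - xi) * (y - yi) / (yj - yi) + xi
      if (x < xcross) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

randomMask <- function(h, w, p = 0.4) matrix(runif(h * w) < p, h, w)

## random multilabel raster with spatially coherent blobs of each class
randomLabelRaster <- function(h, w) {
  lab <- matrix(0L, h, w)
  for (cl in 1:2) {
    nblob <- sample(1:3, 1)
    for (b in seq_len(nblob)) {
      cy <- runif(1, 1, h); cx <- runif(1, 1, w)
      rad <- runif(1, 3, min(h, w) / 3)
      ys <- matrix(rep(seq_len(h), w), h, w)
      xs <- matrix(rep(seq_len(w), each = h), h, w)
      lab[(ys - cy)^2 + (xs - cx)^2 <= rad^2] <- cl
    }
  }
  lab
}
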