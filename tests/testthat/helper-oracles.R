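# Independent brute-force oracles used across the suite.
# These deliberately avoid EBImage and the package's own primitives: they
# implement grayscale/binary morphology straight from the definition
# (min/max over structuring-element translates, intersection convention at
# the borders), connected components by explicit BFS, and region growing by
# queue-based flood fill.

oracle_shift <- function(x, dr, dc, fill) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- x[rs - dr, cs - dc]
  out
}

oracle_erode <- function(x, kern) {
  r <- (nrow(kern) - 1L) / 2L
  out <- matrix(Inf, nrow(x), ncol(x))
  for (i in -r:r) for (j in -r:r) {
    if (kern[i + r + 1L, j + r + 1L] > 0) {
      out <- pmin(out, oracle_shift(x, -i, -j, Inf))
    }
  }
  out
}

oracle_dilate <- function(x, kern) {
  r <- (nrow(kern) - 1L) / 2L
  out <- matrix(-Inf, nrow(x), ncol(x))
  for (i in -r:r) for (j in -r:r) {
    if (kern[i + r + 1L, j + r + 1L] > 0) {
      out <- pmax(out, oracle_shift(x, i, j, -Inf))
    }
  }
  out
}

oracle_open <- function(x, kern) oracle_dilate(oracle_erode(x, kern), kern)
oracle_close <- function(x, kern) oracle_erode(oracle_dilate(x, kern), kern)
oracle_tophat <- function(x, kern) x - oracle_open(x, kern)

# 8-connected component count/labels by BFS flood fill
oracle_label_bfs <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- (p - 1L) %% nr + 1L
      pc <- (p - 1L) %/% nr + 1L
      for (k in seq_len(nrow(offs))) {
        qr <- pr + offs$dr[k]; qc <- pc + offs$dc[k]
        if (qr >= 1 && qr <= nr && qc >= 1 && qc <= nc &&
              mask[qr, qc] && lab[qr, qc] == 0L) {
          lab[qr, qc] <- nxt
          queue <- c(queue, (qc - 1L) * nr + qr)
        }
      }
    }
  }
  lab
}

# interval-membership BFS flood fill from a seed mask (8-connectivity);
# seed pixels always belong to the result
oracle_flood_fill <- function(pixels, seed, lo, hi) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  region <- seed
  queue <- which(seed)
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    pr <- (p - 1L) %% nr + 1L
    pc <- (p - 1L) %/% nr + 1L
    for (dr in -1:1) for (dc in -1:1) {
      qr <- pr + dr; qc <- pc + dc
      if ((dr != 0 || dc != 0) && qr >= 1 && qr <= nr && qc >= 1 &&
            qc <= nc && !region[qr, qc] &&
            pixels[qr, qc] >= lo && pixels[qr, qc] <= hi) {
        region[qr, qc] <- TRUE
        queue <- c(queue, (qc - 1L) * nr + qr)
      }
    }
  }
  region
}

# digital disc mask centred in an n x n frame
disc_mask <- function(radius, n = 2L * radius + 11L, center = (n + 1) / 2) {
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  sqrt((rr - center)^2 + (cc - center)^2) <= radius
}

random_mask <- function(nr, nc, p = 0.4) matrix(stats::runif(nr * nc) < p, nr, nc)
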