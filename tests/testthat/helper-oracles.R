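# Independent brute-force oracles; deliberately naive implementations,
# kept free of the package's own computation paths.

# Horn slope at one cell, clamped-edge neighbourhood, degrees
oracle_horn_slope <- function(z, r, c, cell) {
  nr <- nrow(z); nc <- ncol(z)
  g <- function(i, j) z[min(max(i, 1), nr), min(max(j, 1), nc)]
  a <- g(r - 1, c - 1); b <- g(r - 1, c); cc <- g(r - 1, c + 1)
  d <- g(r, c - 1);                      f <- g(r, c + 1)
  gg <- g(r + 1, c - 1); h <- g(r + 1, c); i <- g(r + 1, c + 1)
  gx <- ((cc + 2 * f + i) - (a + 2 * d + gg)) / (8 * cell)
  gy <- ((gg + 2 * h + i) - (a + 2 * b + cc)) / (8 * cell)
  atan(sqrt(gx^2 + gy^2)) * 180 / pi
}

# GLCM of a window by direct pair enumeration
oracle_glcm <- function(window, n_levels, offsets, symmetric) {
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(window); nc <- ncol(window)
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        i2 <- i + dr; j2 <- j + dc
        if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc) {
          a <- window[i, j] + 1L; b <- window[i2, j2] + 1L
          counts[a, b] <- counts[a, b] + 1
          if (symmetric) counts[b, a] <- counts[b, a] + 1
        }
      }
    }
  }
  counts / sum(counts)
}

# the five statistics by explicit double loop
oracle_texture_stats <- function(P) {
  n <- nrow(P)
  s <- c(asm = 0, contrast = 0, dissimilarity = 0, entropy = 0,
         homogeneity = 0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      p <- P[i, j]
      d <- (i - 1) - (j - 1)
      s["asm"] <- s["asm"] + p^2
      s["contrast"] <- s["contrast"] + p * d^2
      s["dissimilarity"] <- s["dissimilarity"] + p * abs(d)
      if (p > 0) s["entropy"] <- s["entropy"] - p * log(p)
      s["homogeneity"] <- s["homogeneity"] + p / (1 + d^2)
    }
  }
  s
}

# merge cost recomputed from raw pixel sets (not incremental statistics)
oracle_merge_cost <- function(labels, values, id_a, id_b, w, w_shape,
                              w_compact) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  nb <- dim(values)[3]
  seg_stats <- function(ids) {
    px <- which(matrix(labels %in% ids, nrow(labels)), arr.ind = TRUE)
    n <- nrow(px)
    sds <- vapply(seq_len(nb), function(b) {
      v <- values[cbind(px, b)]
      sqrt(mean((v - mean(v))^2))
    }, 0)
    # perimeter by edge counting (image border included)
    perim <- 0
    inset <- matrix(FALSE, nrow(labels), ncol(labels))
    inset[px] <- TRUE
    for (k in seq_len(n)) {
      r <- px[k, 1]; cc <- px[k, 2]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 < 1 || r2 > nrow(labels) || c2 < 1 || c2 > ncol(labels) ||
            !inset[r2, c2]) perim <- perim + 1
      }
    }
    bb <- c(range(px[, 1]), range(px[, 2]))
    bbp <- 2 * ((bb[2] - bb[1] + 1) + (bb[4] - bb[3] + 1))
    list(n = n, sds = sds, perim = perim, bbp = bbp)
  }
  A <- seg_stats(id_a); B <- seg_stats(id_b); M <- seg_stats(c(id_a, id_b))
  d_col <- sum(w * (M$n * M$sds - (A$n * A$sds + B$n * B$sds)))
  d_cmp <- M$perim * sqrt(M$n) -
    (A$perim * sqrt(A$n) + B$perim * sqrt(B$n))
  d_smo <- M$n * M$perim / M$bbp -
    (A$n * A$perim / A$bbp + B$n * B$perim / B$bbp)
  (1 - w_shape) * d_col + w_shape * (w_compact * d_cmp +
                                       (1 - w_compact) * d_smo)
}
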