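# Naive reference implementations used as independent oracles. These are
# deliberately slow and literal; they never share code with the package.

# half-sample symmetric reflection of an index vector onto 1..n
reflect_idx <- function(i, n) {
  vapply(i, function(k) {
    while (k < 1 || k > n) {
      if (k < 1) k <- 1 - k
      if (k > n) k <- 2 * n + 1 - k
    }
    k
  }, numeric(1))
}

# local median by explicit window sort, reflective padding
oracle_local_median <- function(m, window) {
  h <- window %/% 2
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- reflect_idx((i - h):(i + h), nr)
      rj <- reflect_idx((j - h):(j + h), nc)
      out[i, j] <- sort(as.vector(m[ri, rj]))[(window^2 + 1) / 2]
    }
  }
  out
}

# Phansalkar decision per pixel over a disc window, reflective padding
oracle_phansalkar <- function(m, radius, k = 0.25, r = 0.5, p = 2, q = 10) {
  norm <- m / 255
  nr <- nrow(m)
  nc <- ncol(m)
  off <- expand.grid(di = -radius:radius, dj = -radius:radius)
  off <- off[off$di^2 + off$dj^2 <= radius^2, ]
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- reflect_idx(i + off$di, nr)
      rj <- reflect_idx(j + off$dj, nc)
      vals <- norm[cbind(ri, rj)]
      mu <- mean(vals)
      s <- sqrt(mean((vals - mu)^2))
      thr <- mu * (1 + p * exp(-q * mu) + k * ((s / r) - 1))
      out[i, j] <- norm[i, j] > thr
    }
  }
  out
}

# connected-component labeling by explicit flood fill
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p0 <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        ii <- p0[1] + nb[k, 1]
        jj <- p0[2] + nb[k, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# particle filter via the flood-fill labeling above
oracle_filter_particles <- function(mask, min_area) {
  lab <- oracle_label(mask, 8)
  if (max(lab) == 0) return(mask)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area])
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Huang threshold by per-pixel evaluation of the fuzziness functional
oracle_huang <- function(m) {
  px <- as.vector(m)
  gmin <- min(px)
  gmax <- max(px)
  C <- gmax - gmin
  ent <- function(u) ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
  cand <- gmin:(gmax - 1)
  fuzz <- sapply(cand, function(t) {
    lo <- px[px <= t]
    hi <- px[px > t]
    mu <- ifelse(px <= t, mean(lo), mean(hi))
    sum(ent(1 / (1 + abs(px - mu) / C)))
  })
  cand[which.min(fuzz)]
}

# Mann-Whitney U by all-pairs counting
oracle_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact length of a polyline clipped to a disc
oracle_length_in_disc <- function(network, center, radius) {
  total <- 0
  for (s in network$segments) {
    for (k in seq_len(nrow(s) - 1)) {
      a <- s[k, ] - center
      b <- s[k + 1, ] - center
      d <- b - a
      A <- sum(d^2)
      if (A == 0) next
      B <- 2 * sum(a * d)
      C <- sum(a^2) - radius^2
      disc <- B^2 - 4 * A * C
      if (disc <= 0) {
        inside <- C <= 0
        if (inside) total <- total + sqrt(A)
        next
      }
      t1 <- max(0, min(1, (-B - sqrt(disc)) / (2 * A)))
      t2 <- max(0, min(1, (-B + sqrt(disc)) / (2 * A)))
      total <- total + (t2 - t1) * sqrt(A)
    }
  }
  total
}

# random 8-bit test image with a coarse two-population structure
random_fixture <- function(n, seed, lo = 40, hi = 190, sd = 25) {
  set.seed(seed)
  base <- matrix(sample(c(lo, hi), n * n, replace = TRUE), n, n)
  m <- round(base + matrix(rnorm(n * n, 0, sd), n, n))
  matrix(pmin(pmax(m, 0), 255), n, n)
}

as_img <- function(m, ppm = 10, plexus = "SCP") {
  en_face_image(m, px_per_mm = ppm, plexus = plexus)
}
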