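# Brute-force oracles, written independently of the package internals:
# plain-R exhaustive enumeration over voxels and neighbors.

ORACLE_OFFSETS <- rbind(
  c(0, 0, 1), c(0, 1, -1), c(0, 1, 0), c(0, 1, 1),
  c(1, -1, -1), c(1, -1, 0), c(1, -1, 1),
  c(1, 0, -1), c(1, 0, 0), c(1, 0, 1),
  c(1, 1, -1), c(1, 1, 0), c(1, 1, 1))

ALL26 <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
ALL26 <- ALL26[rowSums(abs(ALL26)) > 0, ]

inBounds <- function(p, d) all(p >= 1) && all(p <= d)

oracleGLCM <- function(lev, ng) {
  d <- dim(lev)
  out <- array(0, c(ng, ng, 13))
  for (o in 1:13) for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (a == 0) next
    p <- c(i, j, k) + ORACLE_OFFSETS[o, ]
    if (!inBounds(p, d)) next
    b <- lev[p[1], p[2], p[3]]
    if (b == 0) next
    out[a, b, o] <- out[a, b, o] + 1
    out[b, a, o] <- out[b, a, o] + 1
  }
  out
}

# maximal runs per direction, found by walking every full line of the grid
oracleGLRLM <- function(lev, ng) {
  d <- dim(lev)
  maxlen <- max(d)
  out <- array(0, c(ng, maxlen, 13))
  for (o in 1:13) {
    off <- ORACLE_OFFSETS[o, ]
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      start <- c(i, j, k)
      if (inBounds(start - off, d)) next  # not a line start
      line <- integer(0)
      p <- start
      while (inBounds(p, d)) {
        line <- c(line, lev[p[1], p[2], p[3]])
        p <- p + off
      }
      r <- rle(line)
      for (q in seq_along(r$values))
        if (r$values[q] > 0)
          out[r$values[q], r$lengths[q], o] <-
            out[r$values[q], r$lengths[q], o] + 1
    }
  }
  out
}

# zones by breadth-first search over equal-level 26-neighbors
oracleGLSZM <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  idx <- which(lev > 0, arr.ind = TRUE)
  for (q in seq_len(nrow(idx))) {
    s <- idx[q, ]
    if (seen[s[1], s[2], s[3]]) next
    target <- lev[s[1], s[2], s[3]]
    queue <- list(s)
    seen[s[1], s[2], s[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      for (m in seq_len(nrow(ALL26))) {
        p <- cur + ALL26[m, ]
        if (!inBounds(p, d)) next
        if (!seen[p[1], p[2], p[3]] && lev[p[1], p[2], p[3]] == target) {
          seen[p[1], p[2], p[3]] <- TRUE
          queue <- c(queue, list(p))
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(level = target, size = size)
  }
  do.call(rbind, zones)
}

oracleGLDM <- function(lev, ng, alpha = 0L) {
  d <- dim(lev)
  out <- matrix(0, ng, 27)
  idx <- which(lev > 0, arr.ind = TRUE)
  for (q in seq_len(nrow(idx))) {
    s <- idx[q, ]
    a <- lev[s[1], s[2], s[3]]
    dep <- 1L
    for (m in seq_len(nrow(ALL26))) {
      p <- s + ALL26[m, ]
      if (!inBounds(p, d)) next
      b <- lev[p[1], p[2], p[3]]
      if (b > 0 && abs(b - a) <= alpha) dep <- dep + 1L
    }
    out[a, dep] <- out[a, dep] + 1
  }
  out
}

oracleNGTDM <- function(lev, ng) {
  d <- dim(lev)
  s <- numeric(ng)
  n <- numeric(ng)
  idx <- which(lev > 0, arr.ind = TRUE)
  for (q in seq_len(nrow(idx))) {
    v <- idx[q, ]
    a <- lev[v[1], v[2], v[3]]
    nb <- numeric(0)
    for (m in seq_len(nrow(ALL26))) {
      p <- v + ALL26[m, ]
      if (!inBounds(p, d)) next
      b <- lev[p[1], p[2], p[3]]
      if (b > 0) nb <- c(nb, b)
    }
    if (!length(nb)) next
    n[a] <- n[a] + 1
    s[a] <- s[a] + abs(a - mean(nb))
  }
  list(s = s, n = n)
}

# exhaustive pairwise AUC with half-credit ties
oracleAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

randomLevelArray <- function(maxSide = 6L, maxLevel = 4L) {
  d <- sample(2:maxSide, 3, replace = TRUE)
  ng <- sample(2:maxLevel, 1)
  lev <- array(sample(0:ng, prod(d), replace = TRUE), d)
  if (!any(lev > 0)) lev[1, 1, 1] <- 1L
  list(lev = lev, ng = ng, dims = d)
}
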