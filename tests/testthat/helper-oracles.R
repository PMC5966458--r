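# Brute-force oracles used to cross-check the compiled raster operators.
# Deliberately naive (nested loops, explicit reflection) and independent of
# the implementation under test.

reflectIndex <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

diskOffsetsOracle <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

ballHeightsOracle <- function(radius) {
  g <- diskOffsetsOracle(radius)
  g$h <- sqrt(pmax(0, radius^2 - g$dr^2 - g$dc^2))
  g
}

morphOracle <- function(m, se, dilate = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      vals <- numeric(nrow(se))
      for (k in seq_len(nrow(se))) {
        if (dilate) {
          rr <- reflectIndex(r - se$dr[k], nr)
          cc <- reflectIndex(c - se$dc[k], nc)
          vals[k] <- m[rr, cc] + se$h[k]
        } else {
          rr <- reflectIndex(r + se$dr[k], nr)
          cc <- reflectIndex(c + se$dc[k], nc)
          vals[k] <- m[rr, cc] - se$h[k]
        }
      }
      out[r, c] <- if (dilate) max(vals) else min(vals)
    }
  }
  out
}

openingOracle <- function(m, se) morphOracle(morphOracle(m, se, FALSE), se, TRUE)

medianOracle <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  se <- diskOffsetsOracle(radius)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      vals <- numeric(nrow(se))
      for (k in seq_len(nrow(se)))
        vals[k] <- m[reflectIndex(r + se$dr[k], nr),
                     reflectIndex(c + se$dc[k], nc)]
      out[r, c] <- median(vals)
    }
  }
  out
}

# classical one-way ANOVA from explicit sums of squares
anovaOracle <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- length(all) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = pf(f, dfb, dfw, lower.tail = FALSE),
       ssb = ssb, ssw = ssw)
}

drawDiskMask <- function(n, radius, cx = 0, cy = 0) {
  half <- (n - 1) / 2
  outer(-half:half - cy, -half:half - cx, function(y, x)
    x^2 + y^2 <= radius^2)
}

hasEBImage <- function() requireNamespace("EBImage", quietly = TRUE)
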