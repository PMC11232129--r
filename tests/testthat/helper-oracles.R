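# Independent oracles used by the test suite. These deliberately use a
# different algorithm than the package implementation.

# Rasterization area oracle: count grid cells whose centers fall inside the
# polygon (even-odd rule), at resolution `h` mm. Returns cm^2.
oracleAreaRaster <- function(points, h = 0.05) {
  xr <- range(points[, 1]); yr <- range(points[, 2])
  xs <- seq(xr[1] - h, xr[2] + h, by = h)
  ys <- seq(yr[1] - h, yr[2] + h, by = h)
  g <- expand.grid(x = xs + h / 2, y = ys + h / 2)
  n <- nrow(points)
  xi <- points[, 1]; yi <- points[, 2]
  xj <- points[c(n, seq_len(n - 1)), 1]; yj <- points[c(n, seq_len(n - 1)), 2]
  inside <- rep(FALSE, nrow(g))
  for (k in seq_len(n)) {
    crosses <- ((yi[k] > g$y) != (yj[k] > g$y))
    if (any(crosses)) {
      xint <- xi[k] + (g$y[crosses] - yi[k]) * (xj[k] - xi[k]) / (yj[k] - yi[k])
      flip <- xint > g$x[crosses]
      inside[crosses][flip] <- !inside[crosses][flip]
    }
  }
  sum(inside) * h * h / 100
}

# Exact maximal-chord oracle for CONVEX polygons: the chord length
# perpendicular to `axis` as a function of station position is piecewise
# linear with breakpoints at vertex projections, so the maximum is attained
# at a vertex station. Evaluate the exact intersection chord at every vertex
# projection and take the max. Returns mm.
oracleMaxChordConvex <- function(points, axis) {
  axis <- axis / sqrt(sum(axis^2))
  perp <- c(-axis[2], axis[1])
  proj <- as.numeric(points %*% axis)
  n <- nrow(points)
  chordAt <- function(s) {
    a <- proj - s
    b <- c(a[-1], a[1])
    p2 <- rbind(points[-1, , drop = FALSE], points[1, , drop = FALSE])
    hit <- (a <= 0 & b > 0) | (a > 0 & b <= 0) | (a == 0 & b == 0)
    ts <- numeric(0)
    for (i in which(a != b)) {
      t <- a[i] / (a[i] - b[i])
      if (t >= 0 && t <= 1) {
        pt <- points[i, ] + t * (p2[i, ] - points[i, ])
        ts <- c(ts, sum(pt * perp))
      }
    }
    for (i in which(a == 0 & b == 0)) ts <- c(ts, sum(points[i, ] * perp),
                                              sum(p2[i, ] * perp))
    if (length(ts) < 2) 0 else max(ts) - min(ts)
  }
  max(vapply(proj, chordAt, numeric(1)))
}

# Convex polygon generator: random points on an ellipse with sorted angles.
randomConvexPolygon <- function(n = 12, a = 20, b = 12, center = c(0, 0),
                                rot = 0) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  p <- cbind(a * cos(th), b * sin(th))
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  sweep(p %*% R, 2, center, `+`)
}

# Brute-force ICC(2,1) oracle: mean squares from explicit double loops.
oracleIcc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rowM <- rowMeans(m); colM <- colMeans(m)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (m[i, j] - rowM[i] - colM[j] + grand)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Exhaustive exact Wilcoxon rank-sum p-value oracle (two-sided) for small
# samples without ties: enumerate all group assignments.
oracleWilcoxExact <- function(x, y) {
  v <- c(x, y); n <- length(v); nx <- length(x)
  r <- rank(v)
  uObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-12)
}

# Regular closed contour helpers.
circlePoints <- function(r = 10, n = 48, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
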