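# Small planar-geometry helpers shared by the scene generator and the
# contact-graph builder. Polygons are n x 2 matrices of (x, y) vertices in um,
# open form (first vertex not repeated).

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# TRUE if the polygon has no self-intersections (adjacent edges excluded)
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  inter <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through wrap
      if (inter(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

points_in_polygon <- function(x, y, poly) {
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

polygon_to_wkt <- function(poly) {
  closed <- rbind(poly, poly[1, , drop = FALSE])
  coords <- paste(sprintf("%.6f %.6f", closed[, 1], closed[, 2]),
                  collapse = ", ")
  paste0("POLYGON ((", coords, "))")
}

wkt_to_polygon <- function(wkt) {
  inner <- sub("^POLYGON \\(\\((.*)\\)\\)$", "\\1", wkt)
  pairs <- strsplit(strsplit(inner, ",\\s*")[[1]], "\\s+")
  m <- do.call(rbind, lapply(pairs, as.numeric))
  if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

# Truncated normal draws via inverse-CDF; lower truncation only.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (1 - p_lo), mean, sd)
}

# Latent location for a lower-truncated normal whose *truncated* mean equals
# `target_mean`. Keeps configured means honest under truncation.
truncnorm_latent_mean <- function(target_mean, sd, lower) {
  f <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a)) - target_mean
  }
  stats::uniroot(f, c(target_mean - 4 * sd, target_mean + sd))$root
}
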