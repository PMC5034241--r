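# Exact linking number of two closed polygons, computed segment-pair by
# segment-pair as the signed solid angle subtended by the quadrilateral of
# the two segments (Klenin & Langowski closed form). Independent of the
# package's midpoint-rule kernel: for closed curves it returns the integer
# linking number up to floating-point error, with no discretisation bias.

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_unit <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

polygonal_linking_exact <- function(c1, c2) {
  c1 <- as.matrix(c1); c2 <- as.matrix(c2)
  n1v <- nrow(c1); n2v <- nrow(c2)
  p3 <- c2
  p4 <- c2[c(2:n2v, 1), , drop = FALSE]
  total <- 0
  for (i in seq_len(n1v)) {
    p1 <- c1[i, ]
    p2 <- c1[if (i == n1v) 1L else i + 1L, ]
    r12 <- matrix(p2 - p1, n2v, 3, byrow = TRUE)
    r13 <- sweep(p3, 2, p1)
    r14 <- sweep(p4, 2, p1)
    r23 <- sweep(p3, 2, p2)
    r24 <- sweep(p4, 2, p2)
    r34 <- p4 - p3
    n1 <- row_unit(row_cross(r13, r14))
    n2 <- row_unit(row_cross(r14, r24))
    n3 <- row_unit(row_cross(r24, r23))
    n4 <- row_unit(row_cross(r23, r13))
    omega <- asin(clamp1(rowSums(n1 * n2))) +
      asin(clamp1(rowSums(n2 * n3))) +
      asin(clamp1(rowSums(n3 * n4))) +
      asin(clamp1(rowSums(n4 * n1)))
    sgn <- sign(rowSums(row_cross(r34, r12) * r13))
    total <- total + sum(omega * sgn)
  }
  total / (4 * pi)
}
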