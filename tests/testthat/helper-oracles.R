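# Independent oracles, coded by direct summation / explicit loops, kept
# deliberately separate from the package's vectorised implementations.

# quadratic cross-prediction MSE via explicit normal equations
oracle_mcpe_mse <- function(series, tau) {
  n <- length(series)
  z <- series[((seq_len(n) + tau - 1L) %% n) + 1L]
  X <- cbind(1, z, z^2)
  beta <- solve(crossprod(X), crossprod(X, series))
  mean((series - X %*% beta)^2)
}

# G-P scale statistic by O(n^2) double loop
oracle_gp_cm <- function(series, tau, dim) {
  s <- sqrt(mean((series - mean(series))^2))
  n <- length(series)
  count <- n - (dim - 1L) * tau
  pts <- sapply(0:(dim - 1L), function(j) series[(1L + j * tau):(count + j * tau)])
  ct <- 0L; cs <- 0L
  for (i in 1:(count - 1L)) for (j in (i + 1L):count) {
    ct <- ct + 1L
    if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < s) cs <- cs + 1L
  }
  cs / ct
}

# brute-force p nearest neighbours by full sort
oracle_knn <- function(points, p) {
  n <- nrow(points)
  t(sapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(points) - points[i, ])^2))
    d[i] <- Inf
    order(d)[seq_len(p)]
  }))
}

# every topological feature by direct per-formula summation
oracle_topo <- function(xy) {
  N <- nrow(xy)
  X <- xy[, 1]; Y <- xy[, 2]
  deg <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) return(0)
    acos(min(1, max(-1, sum(u * v) / (nu * nv)))) * 180 / pi
  }
  heron <- function(a, b, cc) {
    s <- (a + b + cc) / 2
    sqrt(max(s * (s - a) * (s - b) * (s - cc), 0))
  }
  sacc_o <- 0
  for (i in 1:(N - 1)) sacc_o <- sacc_o + pi / 4 * ((X[i + 1] - X[i])^2 + (Y[i + 1] - Y[i])^2)
  sact_o <- 0; sttc_o <- 0
  centers <- matrix(0, N - 2, 2)
  for (i in 1:(N - 2)) {
    sact_o <- sact_o + abs(det(rbind(c(X[i], Y[i], 1), c(X[i + 1], Y[i + 1], 1),
                                     c(X[i + 2], Y[i + 2], 1)))) / 2
    a <- sqrt((X[i + 1] - X[i])^2 + (Y[i + 1] - Y[i])^2)
    b <- sqrt((X[i + 2] - X[i + 1])^2 + (Y[i + 2] - Y[i + 1])^2)
    cc <- sqrt((X[i + 2] - X[i])^2 + (Y[i + 2] - Y[i])^2)
    S <- heron(a, b, cc)
    r <- if (a + b + cc > 0) 2 * S / (a + b + cc) else 0
    sttc_o <- sttc_o + pi * r^2
    centers[i, ] <- c(mean(X[i:(i + 2)]), mean(Y[i:(i + 2)]))
  }
  satcc_o <- 0
  for (i in 1:(N - 1)) {
    al <- sqrt(X[i]^2 + Y[i]^2); be <- sqrt(X[i + 1]^2 + Y[i + 1]^2)
    ga <- sqrt((X[i + 1] - X[i])^2 + (Y[i + 1] - Y[i])^2)
    satcc_o <- satcc_o + heron(al, be, ga)
  }
  sdttc_o <- 0
  for (k in 1:(N - 3)) sdttc_o <- sdttc_o + sqrt(sum((centers[k + 1, ] - centers[k, ])^2))
  sattc_o <- 0
  if (N >= 5) for (k in 1:(N - 4))
    sattc_o <- sattc_o + deg(centers[k + 1, ] - centers[k, ],
                             centers[k + 2, ] - centers[k + 1, ])
  sac_o <- 0
  for (i in 1:(N - 2)) sac_o <- sac_o + deg(c(X[i + 1] - X[i], Y[i + 1] - Y[i]),
                                            c(X[i + 2] - X[i + 1], Y[i + 2] - Y[i + 1]))
  h <- grDevices::chull(X, Y)
  hx <- X[h]; hy <- Y[h]; k <- length(h)
  per <- 0; area2 <- 0
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    per <- per + sqrt((hx[j] - hx[i])^2 + (hy[j] - hy[i])^2)
    area2 <- area2 + hx[i] * hy[j] - hx[j] * hy[i]
  }
  bc_o <- if (abs(area2) / 2 > 0) per / (abs(area2) / 2) else Inf
  cu <- numeric(N)
  for (i in 2:(N - 1)) {
    u <- c(X[i] - X[i - 1], Y[i] - Y[i - 1]); v <- c(X[i + 1] - X[i], Y[i + 1] - Y[i])
    cross <- abs(u[1] * v[2] - u[2] * v[1])
    den <- sqrt(sum(u^2)) * sqrt(sum(v^2)) * sqrt(sum((u + v)^2))
    cu[i] <- if (den > 0) 2 * cross / den else 0
  }
  cu[1] <- cu[2]; cu[N] <- cu[N - 1]
  acu_o <- mean(cu)
  sdcp_o <- 0
  for (i in 1:(N - 1)) sdcp_o <- sdcp_o + sqrt((X[i + 1] - X[i])^2 + (Y[i + 1] - Y[i])^2)
  d45 <- abs(Y - X) / sqrt(2); d135 <- abs(X + Y) / sqrt(2)
  popsd <- function(v) sqrt(mean((v - mean(v))^2))
  r <- sqrt(X^2 + Y^2)
  ni <- which.min(r); fi <- which.max(r)
  c(SACC = sacc_o, SACT = sact_o, STTC = sttc_o, SATCC = satcc_o,
    SDTTC = sdttc_o, SATTC = sattc_o, SAC = sac_o, BC = bc_o, ACU = acu_o,
    SDCP = sdcp_o, SD45 = sum(d45), SD135 = sum(d135),
    SP = popsd(d45) * popsd(d135), SDCO = sum(r),
    DBNF = sqrt((X[fi] - X[ni])^2 + (Y[fi] - Y[ni])^2),
    DGCO = sqrt(mean(X)^2 + mean(Y)^2))
}

# least-squares similarity alignment of emb onto ref; returns the residual
# sum of squares as a fraction of ref's total variance
procrustes_residual <- function(emb, ref) {
  A <- cbind(1, emb)
  # affine map is enough for "up to affine" recovery claims
  fit <- qr(A)
  pred <- A %*% qr.coef(fit, ref)
  sum((ref - pred)^2) / sum(scale(ref, scale = FALSE)^2)
}

random_trajectory <- function(n, scale = 1) {
  matrix(rnorm(2L * n, sd = scale), n, 2L)
}
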