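# Independent brute-force oracles. These deliberately share no code with the
# package: plain double loops and closed forms only.

# exhaustive pair enumeration for the co-occurrence counts
oracle_glcm_counts <- function(q, n, d, theta) {
  off <- switch(as.character(theta),
                "0" = c(0L, d), "45" = c(-d, d),
                "90" = c(-d, 0L), "135" = c(-d, -d))
  h <- nrow(q); w <- ncol(q)
  counts <- matrix(0L, n, n)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        counts[q[r, c], q[r2, c2]] <- counts[q[r, c], q[r2, c2]] + 1L
      }
    }
  }
  counts
}

# naive direct-summation Haralick features
oracle_haralick <- function(P, base = 2) {
  n <- nrow(P)
  px <- numeric(n); py <- numeric(n)
  for (i in 1:n) for (j in 1:n) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:n) mux <- mux + i * px[i]
  for (j in 1:n) muy <- muy + j * py[j]
  sx <- 0; sy <- 0
  for (i in 1:n) sx <- sx + (i - mux)^2 * px[i]
  for (j in 1:n) sy <- sy + (j - muy)^2 * py[j]
  sx <- sqrt(sx); sy <- sqrt(sy)
  pxy <- numeric(2 * n)
  for (i in 1:n) for (j in 1:n) pxy[i + j] <- pxy[i + j] + P[i, j]
  lg <- function(v) if (v > 0) log(v, base) else 0
  energy <- 0; contrast <- 0; corr <- 0; variance <- 0; entropy <- 0
  for (i in 1:n) for (j in 1:n) {
    energy <- energy + P[i, j]^2
    contrast <- contrast + (i - j)^2 * P[i, j]
    if (sx * sy > 0)
      corr <- corr + ((i - mux) / sx) * ((j - muy) / sy) * P[i, j]
    variance <- variance + (i - mux)^2 * P[i, j]
    entropy <- entropy - P[i, j] * lg(P[i, j])
  }
  sum_avg <- 0; sum_ent <- 0
  for (k in 2:(2 * n)) {
    sum_avg <- sum_avg + k * pxy[k]
    sum_ent <- sum_ent - pxy[k] * lg(pxy[k])
  }
  sum_var <- 0
  for (k in 2:(2 * n)) sum_var <- sum_var + (k - sum_avg)^2 * pxy[k]
  c(energy = energy, contrast = contrast, correlation = corr,
    variance = variance, sum_average = sum_avg, sum_variance = sum_var,
    sum_entropy = sum_ent, entropy = entropy)
}

# empirical-CDF KS distance by direct evaluation at every pooled point
oracle_ks_D <- function(xs, ys) {
  best <- 0
  for (t in c(xs, ys)) {
    fx <- sum(xs <= t) / length(xs)
    fy <- sum(ys <= t) / length(ys)
    best <- max(best, abs(fx - fy))
  }
  best
}

# exact two-sided rank-sum p-value by enumerating all group assignments of
# the pooled sample (tie-free samples only)
oracle_ranksum_exact <- function(xs, ys) {
  n1 <- length(xs); n2 <- length(ys)
  pooled <- c(xs, ys)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_stat(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_stat)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# explicit dense-inverse Mahalanobis distance (nonsingular settings only)
oracle_mahalanobis <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  s <- ((na - 1) * cov(xa) + (nb - 1) * cov(xb)) / (na + nb - 2)
  d <- colMeans(xa) - colMeans(xb)
  sqrt(drop(t(d) %*% solve(s) %*% d))
}

# quantized-image fixture with an explicit level count
make_q <- function(m, n_levels) {
  structure(matrix(as.integer(m), nrow(m), ncol(m)),
            n_levels = as.integer(n_levels),
            class = c("quantized_image", "matrix"))
}

# small random RGB fundus with full-frame FOV
random_fundus <- function(h, w, seed = 1, group = "g", full_fov = TRUE) {
  set.seed(seed)
  px <- array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
  fundus_image(px, id = sprintf("rand%d", seed), group = group,
               fov = if (full_fov) matrix(TRUE, h, w) else NULL)
}

# constant-color fundus
constant_fundus <- function(h, w, rgb, group = "g") {
  px <- array(rep(rgb, each = h * w), c(h, w, 3))
  fundus_image(px, id = "const", group = group, fov = matrix(TRUE, h, w))
}
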