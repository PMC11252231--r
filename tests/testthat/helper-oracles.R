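# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are written from the defining formulas, not by
# calling the package's own code paths.

# Spearman r: explicit ranks, then the product-moment formula by hand
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# overall KMO via an explicit double loop over pairs
oracle_kmo <- function(R) {
  inv <- solve(R)
  p <- ncol(R)
  r2 <- 0; q2 <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r2 <- r2 + R[i, j]^2
      q2 <- q2 + (-inv[i, j] / sqrt(inv[i, i] * inv[j, j]))^2
    }
  }
  r2 / (r2 + q2)
}

oracle_bartlett <- function(R, n) {
  m <- ncol(R)
  chisq <- -(n - 1 - (2 * m + 5) / 6) * log(det(R))
  df <- m * (m - 1) / 2
  list(chisq = chisq, df = df,
       p_value = pchisq(chisq, df, lower.tail = FALSE))
}

oracle_npi <- function(cf) sqrt((mean(cf)^2 + max(cf)^2) / 2)
oracle_nri <- function(er) sqrt((mean(er)^2 + max(er)^2) / 2)

# classical pairwise-Jacobi varimax with Kaiser row normalization
oracle_varimax <- function(A, eps = 1e-10, max_sweeps = 1000) {
  h <- sqrt(rowSums(A^2))
  B <- A / h
  m <- nrow(B); k <- ncol(B)
  for (sweep_i in seq_len(max_sweeps)) {
    moved <- 0
    for (p in seq_len(k - 1)) {
      for (q in (p + 1):k) {
        x <- B[, p]; y <- B[, q]
        u <- x^2 - y^2
        v <- 2 * x * y
        Au <- sum(u); Bv <- sum(v)
        C <- sum(u^2 - v^2); D <- sum(2 * u * v)
        num <- D - 2 * Au * Bv / m
        den <- C - (Au^2 - Bv^2) / m
        phi <- atan2(num, den) / 4
        if (abs(phi) > eps) {
          cs <- cos(phi); sn <- sin(phi)
          B[, p] <- x * cs + y * sn
          B[, q] <- -x * sn + y * cs
          moved <- moved + abs(phi)
        }
      }
    }
    if (moved < eps) break
  }
  B * h
}

# varimax criterion (raw, on Kaiser-normalized loadings)
varimax_criterion <- function(L) {
  B <- L / sqrt(rowSums(L^2))
  m <- nrow(B)
  sum(apply(B^2, 2, function(c2) mean(c2^2) - mean(c2)^2))
}

# align columns of B to A by absolute correlation, fixing signs
align_loadings <- function(B, A) {
  k <- ncol(A)
  used <- integer(0)
  out <- matrix(0, nrow(A), k)
  for (h in seq_len(k)) {
    cors <- vapply(seq_len(k), function(j) {
      if (j %in% used) return(-Inf)
      abs(sum(A[, h] * B[, j]))
    }, numeric(1))
    j <- which.max(cors)
    used <- c(used, j)
    s <- sign(sum(A[, h] * B[, j]))
    out[, h] <- s * B[, j]
  }
  out
}

perms <- function(k) {
  if (k == 1) return(matrix(1))
  do.call(rbind, lapply(seq_len(k), function(i) {
    sub <- perms(k - 1)
    cbind(i, matrix((seq_len(k)[-i])[sub], nrow(sub)))
  }))
}

# best-permutation match of recovered contributions against the truth
match_contributions <- function(recovered, truth) {
  k <- ncol(truth)
  pm <- perms(k)
  best <- Inf; bestp <- pm[1, ]
  for (r in seq_len(nrow(pm))) {
    mae <- mean(abs(recovered[, pm[r, ]] - truth))
    if (mae < best) { best <- mae; bestp <- pm[r, ] }
  }
  list(mae = best, perm = bestp)
}

# a tiny valid sample table
toy_table <- function(n = 8, elements = c("Cd", "Ni", "Pb"), seed = 7) {
  set.seed(seed)
  m <- matrix(rlnorm(n * length(elements), 1, 0.4), n, length(elements),
              dimnames = list(NULL, elements))
  as_sample_table(m)
}

# strictly positive two-level column with exact sample mean and sd
# (k low values, n - k high values; n-1 denominator)
exact_moments_positive <- function(mean, sd, n, k = floor(0.78 * n)) {
  a <- -sqrt((n - 1) * (n - k) / (k * n))
  b <- -k * a / (n - k)
  x <- mean + sd * c(rep(a, k), rep(b, n - k))
  stopifnot(all(x > 0))
  x
}

# a column with exact sample mean and sd at n points
exact_moments_column <- function(mean, sd, n, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

table2_means <- c(Al = 22521, Cd = 0.176, Co = 7.58, Cr = 44.9, Cu = 19.1,
                  Fe = 15821, Mn = 352, Ni = 37.9, Pb = 8.85, Zn = 34.9)
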