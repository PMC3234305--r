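# Independent oracles and small fixtures used across the suite. Oracles are
# deliberately written from the definitions, not by calling the package.

# Pearson correlation straight from the definition
pearson_oracle <- function(p, q) {
  mp <- mean(p); mq <- mean(q)
  sum((p - mp) * (q - mq)) /
    sqrt(sum((p - mp)^2) * sum((q - mq)^2))
}

# connected components of the graph with edges where r[i, j] >= rho (BFS)
components_oracle <- function(r, rho) {
  n <- nrow(r)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cur
      nb <- which(r[v, ] >= rho & comp == 0L)
      queue <- c(queue, setdiff(nb, v))
    }
  }
  comp
}

# same partition up to label renaming (canonical first-occurrence labels)
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# Benjamini-Hochberg step-up from the definition
bh_oracle <- function(p) {
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv)
  adj <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q[ok][o] <- pmin(adj, 1)
  q
}

# exhaustive FCR from the definition: average over all permutations of the
# pooled RTs dealt back into the size template (recursive permutation walk)
fcr_enum_oracle <- function(rt_list, delta) {
  rt_list <- rt_list[vapply(rt_list, length, integer(1)) >= 2L]
  sizes <- vapply(rt_list, length, integer(1))
  pool <- unlist(rt_list, use.names = FALSE)
  cv <- function(v) 100 * sd(v) / mean(v)
  denom <- sum(vapply(rt_list, cv, numeric(1)) <= delta)
  ends <- cumsum(sizes); starts <- ends - sizes + 1L
  total <- 0; count <- 0
  walk <- function(prefix, remaining) {
    if (length(remaining) == 0L) {
      hits <- sum(vapply(seq_along(sizes), function(i)
        cv(prefix[starts[i]:ends[i]]) <= delta, logical(1)))
      total <<- total + hits / denom
      count <<- count + 1
      return(invisible())
    }
    for (i in seq_along(remaining))
      walk(c(prefix, remaining[i]), remaining[-i])
  }
  walk(numeric(0), pool)
  total / count
}

# compact grid keeping module tests fast
small_grid <- function(kernel = "gaussian", window_k = 30) {
  grid_config(200, 320, 0.1, window_k, kernel)
}

# random admitted spectrum on the small grid
random_spectrum <- function(id, precursor_mz = runif(1, 300, 800),
                            n_peaks = 25, grid = small_grid(),
                            rt = runif(1, 1800, 7200),
                            sample = "A", replicate = "1") {
  mz <- sort(runif(n_peaks, grid$mz_min + 1, grid$mz_max - 5))
  new_spectrum(id, mz, runif(n_peaks, 0.05, 1), precursor_mz,
               retention_time = rt, sample = sample, replicate = replicate)
}

# n column vectors with exactly the target correlation matrix
profiles_with_correlation <- function(R, len = 60, seed = 1) {
  set.seed(seed)
  k <- nrow(R)
  Z <- matrix(rnorm(len * k), len, k)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))
  X <- Q %*% chol(R)
  # columns have exact sample correlation R (up to numerics)
  X
}
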