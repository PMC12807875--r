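# Independent reference implementations used to cross-check the package.
# Deliberately naive (loops, enumeration, dense grids); they must never
# call the functions they verify.

# Two-group binomial logistic MLE by Newton-Raphson on the log-likelihood.
oracle_binom_glm <- function(xi, total, treated) {
  X <- cbind(1, as.numeric(treated))
  beta <- c(0, 0)
  H <- NULL
  for (it in 1:100) {
    p <- 1 / (1 + exp(-(X %*% beta)))
    grad <- t(X) %*% (xi - total * p)
    H <- t(X) %*% (X * as.numeric(total * p * (1 - p)))
    step <- solve(H, grad)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < 1e-13) break
  }
  p <- 1 / (1 + exp(-(X %*% beta)))
  H <- t(X) %*% (X * as.numeric(total * p * (1 - p)))
  se <- sqrt(diag(solve(H)))
  z <- beta[2] / se[2]
  list(beta = beta[2], se = se[2], p_value = 2 * stats::pnorm(-abs(z)))
}

# Textbook step-down Holm adjustment.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Textbook step-up Benjamini-Hochberg adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  for (i in seq_len(m)) {
    rank_i <- m - i + 1
    running <- min(running, m / rank_i * p[o[i]])
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# O(n^2) partition by transitive closure of the "starts within window"
# relation (breadth-first search over the pairwise graph).
oracle_partition <- function(start, window) {
  n <- length(start)
  adj <- abs(outer(start, start, "-")) <= window
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in order(start)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Exact two-sided rank-sum p value by enumeration of all group assignments
# (tie-free data only), using the same two-sided rule as the standard test.
oracle_wilcox_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ids <- utils::combn(nx + ny, nx)
  us <- apply(ids, 2, function(id) sum(r[id]) - nx * (nx + 1) / 2)
  p1 <- if (u_obs > nx * ny / 2) mean(us >= u_obs) else mean(us <= u_obs)
  min(2 * p1, 1)
}

# Best RSS of r ~ a*exp(-k*t) + b over a dense (k, b) grid with the
# conditionally optimal (clamped) a at each grid point.
oracle_decay_best_rss <- function(t, ratio, offset = TRUE) {
  ks <- exp(seq(log(5e-3), log(5), length.out = 120))
  bs <- if (offset) seq(0, 0.6, by = 0.02) else 0
  best <- Inf
  for (k in ks) {
    e <- exp(-k * t)
    for (b in bs) {
      a <- sum(e * (ratio - b)) / sum(e * e)
      a <- min(max(a, -1), 1)
      rss <- sum((ratio - a * e - b)^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# Closed-form Pearson sample correlation.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
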