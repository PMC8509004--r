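# Independent oracles used across the suite. These deliberately take
# different computational routes from the package code they check.

# OLS by explicit normal equations on the design matrix, p from the t CDF.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  covb <- s2 * solve(crossprod(X))
  se <- sqrt(covb[2, 2])
  tval <- beta[2] / se
  list(intercept = beta[1], slope = beta[2], se = se, t = tval,
       p = 2 * pt(-abs(tval), n - 2),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Textbook BH step-up: for each i find the largest j with p(j) <= j*q/m.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[o][i:m] * m / (i:m))
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Brute-force agglomerative average linkage; returns the cophenetic
# distance matrix, which characterises the tree.
avg_linkage_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  d <- D
  active <- seq_len(n)
  while (length(active) > 1) {
    sub <- d[active, active, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- active[ij[1]]; b <- active[ij[2]]
    h <- d[a, b]
    for (u in clusters[[a]]) for (v in clusters[[b]]) {
      coph[u, v] <- coph[v, u] <- h
    }
    # average linkage update: weighted by cluster sizes
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    for (k in setdiff(active, c(a, b))) {
      d[a, k] <- d[k, a] <- (na * d[a, k] + nb * d[b, k]) / (na + nb)
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    active <- setdiff(active, b)
  }
  coph
}

# All permutations of a vector (recursive; fine for n <= 6).
combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Small simulated dataset shared by several tests.
toy_sim <- function(...) {
  args <- list(n_genes = 25, n_donors = 20,
               regions = c("PVC", "OFC", "Hipp"), seed = 42)
  args[names(list(...))] <- list(...)
  do.call(simulate_brainspan, args)
}
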