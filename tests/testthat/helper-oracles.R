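# Independent oracles and small fixture builders used across test files.
# Each oracle re-derives the quantity by brute force, without touching the
# package's own code paths.

# David's score by explicit loops over the P-matrix definition.
brute_davids_score <- function(W) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      tot <- W[i, j] + W[j, i]
      if (tot > 0) P[i, j] <- W[i, j] / tot
    }
  }
  w <- numeric(n); l <- numeric(n)
  for (i in seq_len(n)) {
    w[i] <- sum(P[i, ])
    l[i] <- sum(P[, i])
  }
  w2 <- numeric(n); l2 <- numeric(n)
  for (i in seq_len(n)) {
    w2[i] <- sum(P[i, ] * w)
    l2[i] <- sum(P[, i] * l)
  }
  w + w2 - l - l2
}

# All permutations of 1..n (n <= 7).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

# Exhaustive maximum of the rank objective over all orderings.
brute_rank_optimum <- function(P) {
  best <- -Inf
  for (ord in all_perms(nrow(P))) {
    Q <- P[ord, ord]
    v <- sum(Q[upper.tri(Q)])
    if (v > best) best <- v
  }
  best
}

# All compositions of r into m nonnegative parts.
all_compositions <- function(r, m) {
  if (m == 1) return(list(r))
  out <- list()
  for (k in 0:r) {
    for (rest in all_compositions(r - k, m - 1)) {
      out[[length(out) + 1L]] <- c(k, rest)
    }
  }
  out
}

# Exhaustive maximum Kullback-Leibler divergence over integer reallocations
# of the row total r against availability q.
brute_d_max <- function(r, q) {
  best <- -Inf
  for (k in all_compositions(r, length(q))) {
    if (any(k > 0 & q == 0)) next
    p <- k / r
    nz <- p > 0
    d <- sum(p[nz] * log(p[nz] / q[nz]))
    if (d > best) best <- d
  }
  best
}

# Degree-corrected 2x2-block log-likelihood of a core/periphery split
# (same objective the search maximizes, re-derived independently).
brute_cp_loglik <- function(A, rc, cc) {
  k <- rowSums(A); d <- colSums(A)
  ll <- 0
  for (rb in c(TRUE, FALSE)) for (cb in c(TRUE, FALSE)) {
    E <- sum(A[rc == rb, cc == cb, drop = FALSE])
    if (E > 0)
      ll <- ll + E * log(E / (sum(k[rc == rb]) * sum(d[cc == cb])))
  }
  ll
}

# Exhaustive best core/periphery log-likelihood over all 2^(r+c) splits.
brute_cp_optimum <- function(A) {
  n <- nrow(A); m <- ncol(A)
  best <- -Inf
  for (ri in 0:(2^n - 1)) for (ci in 0:(2^m - 1)) {
    rc <- as.logical(bitwAnd(ri, 2^(seq_len(n) - 1)) > 0)
    cc <- as.logical(bitwAnd(ci, 2^(seq_len(m) - 1)) > 0)
    ll <- brute_cp_loglik(A, rc, cc)
    if (ll > best) best <- ll
  }
  best
}

# Normalized mutual information between two labelings.
nmi <- function(a, b) {
  tab <- table(a, b)
  pij <- tab / sum(tab)
  pi <- rowSums(pij); pj <- colSums(pij)
  mi <- sum(ifelse(pij > 0, pij * log(pij / outer(pi, pj)), 0))
  h <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  if (h(pi) == 0 || h(pj) == 0) return(as.numeric(mi == 0))
  mi / sqrt(h(pi) * h(pj))
}

# Random sparse tournament matrix with a fixed seed.
random_tournament <- function(n, seed, max_contests = 8, p_observed = 0.6) {
  set.seed(seed)
  W <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_observed) {
      tot <- sample.int(max_contests, 1)
      wins <- rbinom(1, tot, runif(1))
      W[i, j] <- wins
      W[j, i] <- tot - wins
    }
  }
  if (sum(W) == 0) W[1, 2] <- 1L
  W
}

# Neutral (abundance-product) pairwise table with an extra pure-noise trait,
# for GAM power/size experiments: 13 x 10 species, NB response with theta 2.
neutral_pair_table <- function(seed, total_visits = 2272, theta = 2) {
  set.seed(seed)
  nh <- 13; np <- 10
  A <- qlnorm(ppoints(nh), 3, 0.9)
  B <- qlnorm(ppoints(np), 6, 1)
  hp <- A / sum(A); fp <- B / sum(B)
  idx <- expand.grid(i = seq_len(nh), j = seq_len(np))
  mu <- total_visits * hp[idx$i] * fp[idx$j]
  noise <- rnorm(nh)[idx$i]
  data.frame(visits = rnbinom(nrow(idx), size = theta, mu = mu),
             hummingbird_abundance_prop = hp[idx$i],
             flower_abundance_prop = fp[idx$j],
             noise_trait = noise)
}
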