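#' Validate a quantitative visitation matrix
#'
#' Rows are hummingbird species, columns plant species, cells the number of
#' legitimate flower visits (interaction strength).
#'
#' @param A numeric matrix of nonnegative visit counts.
#' @param require_positive error when the matrix is all-zero (most metrics
#'   are undefined on an empty network).
#' @return the validated matrix with dimnames filled in.
#' @export
as_visitation_matrix <- function(A, require_positive = TRUE) {
  A <- as.matrix(A)
  if (!is.numeric(A) || any(!is.finite(A)) || any(A < 0))
    stop_dominet("visitation matrix must be nonnegative and finite")
  if (require_positive && sum(A) == 0)
    stop_dominet("visitation matrix has no interactions")
  rownames(A) <- rownames(A) %||% paste0("H", seq_len(nrow(A)))
  colnames(A) <- colnames(A) %||% paste0("P", seq_len(ncol(A)))
  if (anyDuplicated(rownames(A)) || anyDuplicated(colnames(A)))
    stop_dominet("duplicate species labels in visitation matrix")
  A
}

# Kullback-Leibler divergence of an integer allocation k (summing to r) from
# the availability distribution q, in nats: sum (k/r) log((k/r)/q).
kl_alloc <- function(k, r, q) {
  p <- k / r
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

# Most-proportional integer allocation of r units to availabilities q
# (largest-remainder rounding of the targets r*q).
dmin_alloc <- function(r, q) {
  target <- r * q
  k <- floor(target)
  rem <- r - sum(k)
  if (rem > 0) {
    frac <- target - k
    # largest remainders first; ties to the more available partner, then index
    ord <- order(-frac, -q, seq_along(q))
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  k
}

# Greedy maximal allocation: place r units one at a time, each on the
# partner whose summand increases d the most; ties go to the rarer partner.
dmax_alloc <- function(r, q) {
  m <- length(q)
  k <- integer(m)
  usable <- which(q > 0)
  term <- function(kj, qj) if (kj == 0) 0 else (kj / r) * log((kj / r) / qj)
  cur <- numeric(m)
  for (u in seq_len(r)) {
    gain <- vapply(usable, function(j) term(k[j] + 1, q[j]) - cur[j],
                   numeric(1))
    ord <- order(-gain, q[usable], usable)
    j <- usable[ord[1]]
    k[j] <- k[j] + 1
    cur[j] <- term(k[j], q[j])
  }
  k
}

#' Species-level specialization d'
#'
#' Kullback-Leibler specialization of each consumer row: the divergence `d`
#' of its realized partner-use distribution from partner availability
#' (column totals), normalized by the minimum and maximum divergence
#' achievable when reallocating the same integer row total over partners:
#' `d' = (d - d_min) / (d_max - d_min)`. 0 marks a perfect generalist (use
#' proportional to availability), 1 the strongest specialist the row total
#' permits. `d_min` uses largest-remainder proportional rounding; `d_max`
#' greedily loads units where the divergence gain is largest (rarest
#' partners first on ties).
#'
#' @param A visitation matrix (counts).
#' @param guild `"rows"` (default), `"cols"`, or `"both"`: which side(s) to
#'   score; columns are scored on `t(A)`.
#' @return data.frame with `species`, `guild`, `degree`, `d`, `d_min`,
#'   `d_max`, `d_prime`. Rows with zero totals get `NA` metrics (flagged,
#'   not an error).
#' @export
specialization_d <- function(A, guild = c("rows", "cols", "both")) {
  guild <- match.arg(guild)
  A <- as_visitation_matrix(A)
  if (guild == "both") {
    return(rbind(specialization_d(A, "rows"),
                 specialization_d(t(A), "rows") |>
                   transform(guild = "cols")))
  }
  if (guild == "cols") A <- t(A)
  if (!is_count_matrix(A))
    stop_dominet("d' requires integer visit counts")
  A <- round(A)
  Ftot <- sum(A)
  q <- colSums(A) / Ftot
  out <- lapply(seq_len(nrow(A)), function(i) {
    r <- sum(A[i, ])
    if (r == 0)
      return(data.frame(degree = 0L, d = NA_real_, d_min = NA_real_,
                        d_max = NA_real_, d_prime = NA_real_))
    d <- kl_alloc(A[i, ], r, q)
    dmin <- kl_alloc(dmin_alloc(r, q), r, q)
    dmax <- kl_alloc(dmax_alloc(r, q), r, q)
    dp <- if (dmax - dmin < 1e-12) 0 else (d - dmin) / (dmax - dmin)
    data.frame(degree = sum(A[i, ] > 0), d = d, d_min = dmin, d_max = dmax,
               d_prime = min(max(dp, 0), 1))
  })
  cbind(data.frame(species = rownames(A), guild = "rows"),
        do.call(rbind, out))
}

#' Barber modularity of a bipartite partition
#'
#' Weighted bipartite modularity
#' \deqn{Q = \frac{1}{F}\sum_{ij}\left(a_{ij} -
#'   \frac{r_i c_j}{F}\right)\,\delta(g_i, h_j)}
#' the excess of within-module interaction weight over the margins-product
#' expectation, for given row and column module labels.
#'
#' @param A visitation matrix.
#' @param row_modules,col_modules integer/character module labels drawn from
#'   a common label set.
#' @return the modularity Q.
#' @export
barber_modularity <- function(A, row_modules, col_modules) {
  A <- as_visitation_matrix(A)
  if (length(row_modules) != nrow(A) || length(col_modules) != ncol(A))
    stop_dominet("module label length does not match matrix dimensions")
  Ftot <- sum(A)
  M <- A - outer(rowSums(A), colSums(A)) / Ftot
  match_mat <- outer(row_modules, col_modules, "==")
  sum(M[match_mat]) / Ftot
}

# One LPAwb+ run from a given initial column labelling. M is the precomputed
# modularity-excess matrix A - outer(k, d)/F. Returns row/col labels and the
# matched-excess total (Q * F).
lpawb_run <- function(M, col_labels, max_sweeps = 200) {
  n <- nrow(M); m <- ncol(M)
  row_labels <- rep(NA_integer_, n)
  next_label <- max(col_labels) + 1L

  propagate <- function(row_labels, col_labels) {
    for (sweep in seq_len(max_sweeps)) {
      changed <- FALSE
      labs <- sort(unique(c(row_labels[!is.na(row_labels)], col_labels)))
      C <- outer(col_labels, labs, "==") * 1      # m x L
      score <- M %*% C                            # n x L
      for (i in seq_len(n)) {
        b <- which.max(score[i, ])
        if (score[i, b] < 0) {                    # better off alone
          if (is.na(row_labels[i]) || row_labels[i] %in% col_labels ||
              sum(row_labels == row_labels[i], na.rm = TRUE) > 1) {
            row_labels[i] <- next_label; next_label <<- next_label + 1L
            changed <- TRUE
          }
        } else if (is.na(row_labels[i]) || labs[b] != row_labels[i]) {
          row_labels[i] <- labs[b]; changed <- TRUE
        }
      }
      labs2 <- sort(unique(row_labels))
      R <- outer(row_labels, labs2, "==") * 1     # n x L2
      score2 <- crossprod(M, R)                   # m x L2
      for (j in seq_len(m)) {
        b <- which.max(score2[j, ])
        if (score2[j, b] < 0) {
          if (col_labels[j] %in% row_labels ||
              sum(col_labels == col_labels[j]) > 1) {
            col_labels[j] <- next_label; next_label <<- next_label + 1L
            changed <- TRUE
          }
        } else if (labs2[b] != col_labels[j]) {
          col_labels[j] <- labs2[b]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    list(row = row_labels, col = col_labels)
  }

  matched_excess <- function(row_labels, col_labels)
    sum(M[outer(row_labels, col_labels, "==")])

  st <- propagate(row_labels, col_labels)
  q <- matched_excess(st$row, st$col)

  # merge stage: greedily join module pairs while Q improves, re-propagating
  # after every successful merge
  repeat {
    labs <- sort(unique(c(st$row, st$col)))
    if (length(labs) < 2) break
    R <- outer(st$row, labs, "==") * 1
    C <- outer(st$col, labs, "==") * 1
    X <- crossprod(R, M %*% C)  # X[a,b] = excess between rows of a and cols of b
    best <- c(0, 0); best_gain <- 1e-12
    for (a in seq_along(labs)) for (b in seq_along(labs)) {
      if (a >= b) next
      gain <- X[a, b] + X[b, a]
      if (gain > best_gain) { best_gain <- gain; best <- c(a, b) }
    }
    if (best[1] == 0) break
    from <- labs[best[2]]; to <- labs[best[1]]
    st$row[st$row == from] <- to
    st$col[st$col == from] <- to
    st <- propagate(st$row, st$col)
    q2 <- matched_excess(st$row, st$col)
    if (q2 <= q + 1e-12) { q <- max(q, q2); break }
    q <- q2
  }
  list(row = st$row, col = st$col, excess = q)
}

# Relabel modules 1..k by order of first appearance (rows first, then cols).
relabel_modules <- function(row_labels, col_labels) {
  seen <- unique(c(row_labels, col_labels))
  list(row = match(row_labels, seen), col = match(col_labels, seen))
}

#' Maximize Barber modularity with DIRTLPAwb+
#'
#' Restart-wrapped weighted label propagation: each run initializes column
#' modules at a different granularity (from one module up to one per
#' column), alternates best-label updates between the two guilds, then
#' greedily merges modules while Q improves. The best partition over all
#' runs is returned. Deterministic for a fixed seed.
#'
#' @param A visitation matrix with positive total.
#' @param n_runs independent restarts (the field default is 50).
#' @param seed integer seed.
#' @param max_sweeps propagation sweep budget per run.
#' @return object of class `module_partition`: `row_modules`, `col_modules`
#'   (integers 1..k), `Q`, `n_modules`, `n_runs`, `seed`.
#' @export
dirt_lpawb_plus <- function(A, n_runs = 50, seed = 1, max_sweeps = 200) {
  A <- as_visitation_matrix(A)
  if (n_runs < 1) stop_dominet("n_runs must be >= 1")
  Ftot <- sum(A)
  M <- A - outer(rowSums(A), colSums(A)) / Ftot
  m <- ncol(A)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_runs)) {
      # vary the initial number of column modules across runs
      k0 <- if (r == 1) m else sample.int(m, 1)
      init <- if (k0 >= m) seq_len(m) else sample.int(k0, m, replace = TRUE)
      run <- lpawb_run(M, as.integer(init), max_sweeps = max_sweeps)
      if (is.null(best) || run$excess > best$excess + 1e-12) best <- run
    }
  })
  lab <- relabel_modules(best$row, best$col)
  structure(
    list(row_modules = stats::setNames(lab$row, rownames(A)),
         col_modules = stats::setNames(lab$col, colnames(A)),
         Q = best$excess / Ftot,
         n_modules = length(unique(c(lab$row, lab$col))),
         n_runs = n_runs, seed = seed,
         null_mean = NA_real_, null_sd = NA_real_, z = NA_real_,
         n_null = 0L),
    class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Bipartite module partition: Q =", round(x$Q, 4),
      "with", x$n_modules, "modules\n")
  if (!is.na(x$z))
    cat("Patefield null (n =", x$n_null, "): mean Q =",
        round(x$null_mean, 4), "sd =", signif(x$null_sd, 3),
        "-> z =", round(x$z, 2), "\n")
  invisible(x)
}

#' Patefield fixed-margins null draw
#'
#' Uniform sample of nonnegative integer matrices with exactly the given row
#' and column totals (Patefield's algorithm, sequential
#' multivariate-hypergeometric cell filling, as implemented in
#' `stats::r2dtable`).
#'
#' @param row_margins,col_margins nonnegative integer totals with equal sums.
#' @param n number of tables to draw.
#' @param seed optional integer seed.
#' @return a single matrix when `n = 1`, else a list of matrices.
#' @export
patefield_sample <- function(row_margins, col_margins, n = 1, seed = NULL) {
  if (any(row_margins < 0) || any(col_margins < 0) ||
      any(row_margins != round(row_margins)) ||
      any(col_margins != round(col_margins)))
    stop_dominet("margins must be nonnegative integers")
  if (sum(row_margins) != sum(col_margins))
    stop_dominet("row and column margins must have equal totals")
  # a single row or column fixes the table completely (r2dtable needs >= 2)
  if (length(row_margins) == 1 || length(col_margins) == 1) {
    tab <- matrix(0, length(row_margins), length(col_margins))
    if (length(row_margins) == 1) tab[1, ] <- col_margins
    else tab[, 1] <- row_margins
    tabs <- replicate(n, tab, simplify = FALSE)
  } else {
    tabs <- with_seed(seed, stats::r2dtable(n, round(row_margins),
                                            round(col_margins)))
  }
  if (n == 1) tabs[[1]] else tabs
}

#' Modularity z-score against the Patefield null ensemble
#'
#' Runs [dirt_lpawb_plus()] on the observed network and on `n_null`
#' fixed-margins Patefield replicates, each null given the same search
#' budget as the observed network, and reports
#' `z = (Q_obs - mean(Q_null)) / sd(Q_null)`.
#'
#' @param A visitation matrix of integer counts.
#' @param n_null number of null replicates (field default 100).
#' @param n_runs restarts per modularity search.
#' @param seed integer seed governing both the search and the null draws.
#' @param max_sweeps propagation budget per run.
#' @return a `module_partition` with `null_mean`, `null_sd`, `z`, `n_null`
#'   filled in; `z` is `Inf` (with a warning) when the null sd is zero.
#' @export
modularity_zscore <- function(A, n_null = 100, n_runs = 50, seed = 1,
                              max_sweeps = 200) {
  A <- as_visitation_matrix(A)
  if (!is_count_matrix(A))
    stop_dominet("Patefield nulls require integer counts")
  if (n_null < 1) stop_dominet("n_null must be >= 1")
  obs <- dirt_lpawb_plus(A, n_runs = n_runs, seed = derive_seed(seed, 1),
                         max_sweeps = max_sweeps)
  nulls <- patefield_sample(rowSums(A), colSums(A), n = n_null,
                            seed = derive_seed(seed, 2))
  if (n_null == 1) nulls <- list(nulls)
  q_null <- vapply(seq_along(nulls), function(i) {
    dirt_lpawb_plus(nulls[[i]], n_runs = n_runs,
                    seed = derive_seed(seed, 2 + i),
                    max_sweeps = max_sweeps)$Q
  }, numeric(1))
  obs$null_mean <- mean(q_null)
  obs$null_sd <- stats::sd(q_null)
  obs$n_null <- as.integer(n_null)
  if (obs$null_sd == 0 || is.na(obs$null_sd)) {
    warning("null ensemble has zero spread; z reported as Inf")
    obs$z <- Inf
  } else {
    obs$z <- (obs$Q - obs$null_mean) / obs$null_sd
  }
  obs
}

# Degree-corrected 2x2-block log-likelihood of a core/periphery assignment.
# rc, cc: logical core flags for rows and columns.
cp_loglik <- function(A, k, d, rc, cc) {
  ll <- 0
  for (rb in c(TRUE, FALSE)) for (cb in c(TRUE, FALSE)) {
    E <- sum(A[rc == rb, cc == cb, drop = FALSE])
    if (E > 0) {
      K <- sum(k[rc == rb]); D <- sum(d[cc == cb])
      ll <- ll + E * log(E / (K * D))
    }
  }
  ll
}

cp_blocks <- function(A, rc, cc) {
  c(E11 = sum(A[rc, cc, drop = FALSE]),
    E12 = sum(A[rc, !cc, drop = FALSE]),
    E21 = sum(A[!rc, cc, drop = FALSE]),
    E22 = sum(A[!rc, !cc, drop = FALSE]))
}

#' Core-periphery decomposition and CPness
#'
#' Splits each guild into a core and a periphery so that interactions fall
#' into an L-shape of four blocks. The split maximizes a degree-corrected
#' two-block log-likelihood by greedy single-species flips from several
#' deterministic initializations (weighted-degree median split and its
#' complement, all-core, top-degree singletons); the denser block pair is
#' labelled the core. `CPness = (E11 + E12 + E21) / E` is the fraction of
#' interaction weight outside the periphery-periphery block.
#'
#' @param A visitation matrix with positive total.
#' @return object of class `core_periphery`: logical `row_core`,
#'   `col_core`, block sums `E` (E11, E12, E21, E22), and `cpness`.
#' @export
core_periphery <- function(A) {
  A <- as_visitation_matrix(A)
  n <- nrow(A); m <- ncol(A)
  k <- rowSums(A); d <- colSums(A)
  Ftot <- sum(A)

  search_from <- function(rc, cc) {
    ll <- cp_loglik(A, k, d, rc, cc)
    repeat {
      best_gain <- 1e-12; best <- NULL
      for (i in seq_len(n)) {
        rc2 <- rc; rc2[i] <- !rc2[i]
        g <- cp_loglik(A, k, d, rc2, cc) - ll
        if (g > best_gain) { best_gain <- g; best <- list(rc = rc2, cc = cc) }
      }
      for (j in seq_len(m)) {
        cc2 <- cc; cc2[j] <- !cc2[j]
        g <- cp_loglik(A, k, d, rc, cc2) - ll
        if (g > best_gain) { best_gain <- g; best <- list(rc = rc, cc = cc2) }
      }
      if (is.null(best)) break
      rc <- best$rc; cc <- best$cc; ll <- ll + best_gain
    }
    list(rc = rc, cc = cc, ll = ll)
  }

  inits <- list(
    list(rc = k >= stats::median(k), cc = d >= stats::median(d)),
    list(rc = k > stats::median(k), cc = d > stats::median(d)),
    list(rc = rep(TRUE, n), cc = rep(TRUE, m)),
    list(rc = k == max(k), cc = d == max(d))
  )
  best <- NULL
  for (ini in inits) {
    rc <- ini$rc; cc <- ini$cc
    if (!any(rc)) rc[which.max(k)] <- TRUE
    if (!any(cc)) cc[which.max(d)] <- TRUE
    res <- search_from(rc, cc)
    if (is.null(best) || res$ll > best$ll + 1e-12) best <- res
  }
  rc <- best$rc; cc <- best$cc
  # single-species guilds are all-core by convention
  if (n == 1) rc <- TRUE
  if (m == 1) cc <- TRUE

  # orient labels: the core blocks are those of higher within-block
  # (weighted) connectance
  dens <- function(rb, cb) {
    nr <- sum(rc == rb); nc <- sum(cc == cb)
    if (nr == 0 || nc == 0) return(-Inf)
    sum(A[rc == rb, cc == cb, drop = FALSE]) / (nr * nc)
  }
  if (dens(FALSE, FALSE) > dens(TRUE, TRUE)) {
    rc <- !rc; cc <- !cc
  }
  E <- cp_blocks(A, rc, cc)
  structure(
    list(row_core = stats::setNames(rc, rownames(A)),
         col_core = stats::setNames(cc, colnames(A)),
         E = E,
         cpness = unname((E["E11"] + E["E12"] + E["E21"]) / Ftot)),
    class = "core_periphery")
}

#' @export
print.core_periphery <- function(x, ...) {
  cat("Core-periphery: CPness =", round(x$cpness, 3), "\n")
  cat("  core rows:", paste(names(x$row_core)[x$row_core], collapse = ", "),
      "\n  core cols:", paste(names(x$col_core)[x$col_core], collapse = ", "),
      "\n")
  invisible(x)
}
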