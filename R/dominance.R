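#' Validate an agonistic win/loss matrix
#'
#' An agonistic matrix is a square nonnegative integer matrix `W` in which
#' `W[i, j]` counts the contests (chases, displacements at a floral patch)
#' that species `i` won against species `j`. The diagonal is zero and species
#' labels are unique. Tournaments are typically sparse: many dyads are never
#' observed contesting.
#'
#' @param W square numeric matrix of win counts.
#' @param labels optional character vector of species labels; defaults to the
#'   rownames of `W` or `S1..Sn`.
#' @return the validated matrix with labels as dimnames.
#' @export
as_agonistic_matrix <- function(W, labels = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W))
    stop_dominet("agonistic matrix must be square, got ",
                 nrow(W), "x", ncol(W))
  if (!is_count_matrix(W))
    stop_dominet("agonistic matrix must contain nonnegative integer counts")
  if (any(diag(W) != 0))
    stop_dominet("agonistic matrix must have a zero diagonal")
  labels <- labels %||% rownames(W) %||% paste0("S", seq_len(nrow(W)))
  if (anyDuplicated(labels))
    stop_dominet("duplicate species labels: ",
                 paste(unique(labels[duplicated(labels)]), collapse = ", "))
  dimnames(W) <- list(labels, labels)
  W
}

#' David's score from a sparse tournament
#'
#' Ranks species by David's score \eqn{Ds = w + w_2 - l - l_2}, where for
#' species i, `w` sums its win proportions against each opponent, `w2` weights
#' those proportions by the opponents' own `w`, and `l`, `l2` are the mirror
#' quantities for losses. Win proportions are computed only over observed
#' dyads (`W[i,j] + W[j,i] > 0`); unobserved dyads contribute nothing, which
#' is what makes the index usable on incomplete tournaments. Scores sum to
#' zero over the group.
#'
#' @param W agonistic matrix (see [as_agonistic_matrix()]).
#' @return named numeric vector of David's scores, one per species.
#' @examples
#' W <- matrix(c(0, 4, 0, 0), 2, 2, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("A", "B")))
#' davids_score(W)  # A = 1, B = -1
#' @export
davids_score <- function(W) {
  W <- as_agonistic_matrix(W)
  n <- nrow(W)
  if (n < 2) stop_dominet("need at least 2 species")
  tot <- W + t(W)
  if (all(tot == 0)) stop_dominet("no contests recorded in agonistic matrix")
  P <- matrix(0, n, n, dimnames = dimnames(W))
  obs <- tot > 0
  P[obs] <- W[obs] / tot[obs]
  w <- rowSums(P)
  l <- colSums(P)
  w2 <- as.vector(P %*% w)
  l2 <- as.vector(t(P) %*% l)
  ds <- w + w2 - l - l2
  names(ds) <- rownames(W)
  ds
}

#' Dyadic dominance probabilities from direct and indirect pathways
#'
#' Converts a win/loss matrix into a matrix of dyadic dominance
#' probabilities. Direct wins are augmented with indirect win-pathways
#' through common third parties: a path i -> k -> j in the binarized
#' win-majority graph adds `decay^(len-1)` units of flow from i to j. The
#' pathway-augmented flow `F` is smoothed with half-unit pseudo-counts,
#' `P[i,j] = (F[i,j] + 0.5) / (F[i,j] + F[j,i] + 1)`, so dyads with no
#' information (direct or indirect) sit at 0.5 - an equal probability of
#' ranking higher or lower.
#'
#' @param W agonistic matrix.
#' @param max_path_len maximum pathway length counted (1 = direct only).
#' @param decay multiplicative weight per extra step, in (0, 1].
#' @return matrix `P` with `P + t(P) == 1` elementwise.
#' @export
dominance_probabilities <- function(W, max_path_len = 2, decay = 0.5) {
  W <- as_agonistic_matrix(W)
  if (!is.numeric(max_path_len) || max_path_len < 1 ||
      max_path_len != round(max_path_len))
    stop_dominet("max_path_len must be a positive integer")
  if (!is.numeric(decay) || decay <= 0 || decay > 1)
    stop_dominet("decay must lie in (0, 1]")
  Fm <- W
  if (max_path_len >= 2) {
    B <- (W > t(W)) * 1          # win-majority adjacency
    Bk <- B
    for (k in 2:max_path_len) {
      Bk <- Bk %*% B             # directed win-paths of length k
      Fm <- Fm + decay^(k - 1) * Bk
    }
  }
  P <- (Fm + 0.5) / (Fm + t(Fm) + 1)
  diag(P) <- 0.5
  dimnames(P) <- dimnames(W)
  P
}

# Objective of an ordering: total probability mass consistent with putting
# earlier species above later ones.
rank_objective <- function(P, ord) {
  Q <- P[ord, ord, drop = FALSE]
  sum(Q[upper.tri(Q)])
}

#' Optimal rank order, rank index, and dominance certainty
#'
#' Finds the species ordering that maximizes the summed dominance
#' probabilities of all higher-over-lower pairs, by simulated annealing with
#' restarts (deterministic for a fixed seed; ties keep the input order).
#' Dominance certainty for species i is the mean over opponents of
#' `max(P[i,j], P[j,i])` - 0.5 means its position is a coin flip, 1 means
#' fully certain. The rank index rescales ordinal ranks to \[0, 1\], 0 for
#' the top-ranking and 1 for the bottom-ranking species.
#'
#' @param P dyadic dominance-probability matrix
#'   (see [dominance_probabilities()]).
#' @param n_restarts annealing restarts.
#' @param n_iter iterations per restart.
#' @param seed integer seed for the annealing schedule.
#' @return list with `rank_order` (species indices, best first), `ranks`
#'   (ordinal rank per species), `rank_index`, `dc_mean`, `dc_sd`, and the
#'   achieved `objective`.
#' @export
rank_and_certainty <- function(P, n_restarts = 10, n_iter = 2000, seed = 1) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (n < 2) stop_dominet("need at least 2 species to rank")
  if (ncol(P) != n) stop_dominet("P must be square")
  if (max(abs(P + t(P) - 1)) > 1e-8)
    stop_dominet("P must satisfy P[i,j] + P[j,i] = 1")

  opp <- pmax(P, t(P))
  diag(opp) <- NA
  dc_mean <- rowMeans(opp, na.rm = TRUE)
  dc_sd <- apply(opp, 1, stats::sd, na.rm = TRUE)

  best_ord <- seq_len(n)
  best_obj <- rank_objective(P, best_ord)
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      ord <- if (r == 1) seq_len(n) else sample.int(n)
      obj <- rank_objective(P, ord)
      temp <- 1
      cool <- 0.995
      for (it in seq_len(n_iter)) {
        ij <- sample.int(n, 2)
        cand <- ord
        cand[ij] <- cand[rev(ij)]
        cobj <- rank_objective(P, cand)
        if (cobj > obj || stats::runif(1) < exp((cobj - obj) / temp)) {
          ord <- cand
          obj <- cobj
        }
        temp <- temp * cool
      }
      # polish with best-improvement pairwise swaps
      repeat {
        improved <- FALSE
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
          cand <- ord
          cand[c(i, j)] <- cand[c(j, i)]
          cobj <- rank_objective(P, cand)
          if (cobj > obj + 1e-12) {
            ord <- cand; obj <- cobj; improved <- TRUE
          }
        }
        if (!improved) break
      }
      if (obj > best_obj + 1e-12) {
        best_obj <- obj
        best_ord <- ord
      }
    }
  })

  ranks <- integer(n)
  ranks[best_ord] <- seq_len(n)
  rank_index <- (ranks - 1) / (n - 1)
  labels <- rownames(P) %||% paste0("S", seq_len(n))
  structure(
    list(rank_order = best_ord, ranks = stats::setNames(ranks, labels),
         rank_index = stats::setNames(rank_index, labels),
         dc_mean = stats::setNames(dc_mean, labels),
         dc_sd = stats::setNames(dc_sd, labels),
         objective = best_obj),
    class = "dominance_ranking")
}

#' Full dominance analysis of an agonistic matrix
#'
#' Convenience wrapper: David's scores, pathway-based dominance
#' probabilities, annealed rank order, rank index and dominance certainty in
#' one object.
#'
#' @inheritParams dominance_probabilities
#' @inheritParams rank_and_certainty
#' @return object of class `dominance_result`.
#' @export
dominance_analysis <- function(W, max_path_len = 2, decay = 0.5,
                               n_restarts = 10, n_iter = 2000, seed = 1) {
  W <- as_agonistic_matrix(W)
  ds <- davids_score(W)
  P <- dominance_probabilities(W, max_path_len = max_path_len, decay = decay)
  rk <- rank_and_certainty(P, n_restarts = n_restarts, n_iter = n_iter,
                           seed = seed)
  structure(
    list(labels = rownames(W), ds = ds, P = P,
         rank_order = rk$rank_order, ranks = rk$ranks,
         rank_index = rk$rank_index,
         dc_mean = rk$dc_mean, dc_sd = rk$dc_sd),
    class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat("Dominance analysis:", length(x$labels), "species\n")
  df <- data.frame(species = x$labels, Ds = round(x$ds, 3),
                   rank = x$ranks, rank_index = round(x$rank_index, 3),
                   DC_mean = round(x$dc_mean, 3), DC_sd = round(x$dc_sd, 3),
                   row.names = NULL)
  print(df[order(df$rank), ], row.names = FALSE)
  invisible(x)
}

#' Drop species whose rank position is uncertain
#'
#' Species whose dominance certainty does not exceed `threshold` (e.g. rarely
#' observed species stuck at DC = 0.5) are removed and the reduced tournament
#' returned, ready for re-ranking.
#'
#' @param W agonistic matrix.
#' @param result a `dominance_result` or `dominance_ranking` for `W`.
#' @param threshold DC cutoff in \[0.5, 1\]; species with `dc_mean` strictly
#'   above it are kept.
#' @return the reduced agonistic matrix.
#' @export
filter_uncertain_species <- function(W, result, threshold = 0.5) {
  W <- as_agonistic_matrix(W)
  if (threshold < 0.5 || threshold > 1)
    stop_dominet("threshold must lie in [0.5, 1]")
  dc <- result$dc_mean
  if (is.null(dc) || length(dc) != nrow(W))
    stop_dominet("result does not match the agonistic matrix")
  keep <- dc > threshold
  if (sum(keep) < 2)
    stop_dominet("fewer than 2 species exceed the DC threshold")
  W[keep, keep, drop = FALSE]
}

#' Tournament sampling-effort summary
#'
#' Reports the interaction totals the field literature prints for agonistic
#' networks: interactions per individual species, interactions per dyad, and
#' the proportion of dyads never observed contesting.
#'
#' @param W agonistic matrix.
#' @return list with `total_interactions`, `n_species`, `per_individual`,
#'   `per_dyad`, `prop_unknown`.
#' @export
tournament_summary <- function(W) {
  W <- as_agonistic_matrix(W)
  n <- nrow(W)
  if (n < 2) stop_dominet("need at least 2 species")
  total <- sum(W)
  n_dyads <- n * (n - 1) / 2
  tot <- W + t(W)
  unknown <- sum(tot[upper.tri(tot)] == 0)
  list(total_interactions = total,
       n_species = n,
       per_individual = total / n,
       per_dyad = total / n_dyads,
       prop_unknown = unknown / n_dyads)
}
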