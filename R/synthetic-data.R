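#' Define a synthetic community scenario
#'
#' Bundles the parameters of the synthetic-data generators: community sizes,
#' a latent dominance score per hummingbird, guild abundances, the logistic
#' steepness of contest outcomes, how observable dyads are, total sampling
#' effort, and the mixture weights of the three drivers of visitation
#' (neutral abundance products, morphological matching, dominance-driven
#' preference for high-calorie plants). Defaults emulate the study
#' community: 13 hummingbird and 10 plant species, 2,272 visits, 477
#' agonistic contests, and dyad observability low enough that roughly half
#' of all dyads are never seen contesting.
#'
#' @param n_hummingbirds,n_plants community sizes.
#' @param latent_dominance real vector (length `n_hummingbirds`) of latent
#'   dominance scores on an arbitrary scale.
#' @param hummingbird_abundance,plant_flower_abundance positive abundance
#'   vectors; defaults are fixed lognormal-profile abundances (a few common
#'   species dominating).
#' @param steepness positive logistic slope of win probability on the
#'   latent-score difference (`Inf` = deterministic outcomes).
#' @param dyad_observability probability that a dyad is observable at all.
#' @param total_contests,total_visits sampling effort.
#' @param weight_neutral,weight_match,weight_dominance nonnegative mixture
#'   weights of the visitation drivers; must sum to 1.
#' @param seed master integer seed; every generator derives its stream
#'   from it.
#' @return object of class `synthetic_scenario`.
#' @export
make_scenario <- function(n_hummingbirds = 13, n_plants = 10,
                          latent_dominance =
                            seq(2, -2, length.out = n_hummingbirds),
                          hummingbird_abundance =
                            stats::qlnorm(stats::ppoints(n_hummingbirds),
                                          meanlog = 3, sdlog = 0.9),
                          plant_flower_abundance =
                            stats::qlnorm(stats::ppoints(n_plants),
                                          meanlog = 6, sdlog = 1),
                          steepness = 2.5, dyad_observability = 0.45,
                          total_contests = 477, total_visits = 2272,
                          weight_neutral = 0.6, weight_match = 0.15,
                          weight_dominance = 0.25, seed = 1) {
  stopifnot(n_hummingbirds >= 2, n_plants >= 1)
  if (length(latent_dominance) != n_hummingbirds)
    stop_dominet("latent_dominance must have length n_hummingbirds")
  if (any(hummingbird_abundance <= 0) || any(plant_flower_abundance <= 0))
    stop_dominet("abundances must be positive")
  if (length(hummingbird_abundance) != n_hummingbirds ||
      length(plant_flower_abundance) != n_plants)
    stop_dominet("abundance vectors must match community sizes")
  if (is.na(steepness) || steepness < 0)
    stop_dominet("steepness must be nonnegative")
  if (dyad_observability < 0 || dyad_observability > 1)
    stop_dominet("dyad_observability must lie in [0, 1]")
  if (total_contests < 0 || total_visits < 0)
    stop_dominet("sampling totals must be nonnegative")
  w <- c(weight_neutral, weight_match, weight_dominance)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-12)
    stop_dominet("mixture weights must be nonnegative and sum to 1")
  structure(
    list(n_hummingbirds = n_hummingbirds, n_plants = n_plants,
         latent_dominance = latent_dominance,
         hummingbird_abundance = hummingbird_abundance,
         plant_flower_abundance = plant_flower_abundance,
         steepness = steepness, dyad_observability = dyad_observability,
         total_contests = total_contests, total_visits = total_visits,
         weight_neutral = weight_neutral, weight_match = weight_match,
         weight_dominance = weight_dominance, seed = seed),
    class = "synthetic_scenario")
}

#' Simulate a sparse agonistic tournament
#'
#' Each dyad is flagged observable once with probability
#' `dyad_observability`; every contest then picks a dyad uniformly among
#' observable ones and a winner with probability
#' `plogis(steepness * (s_i - s_j))` (Bradley-Terry form in the latent
#' scores). With `steepness = Inf` the higher-scored species always wins.
#'
#' @param scenario a [make_scenario()] object.
#' @return agonistic win-count matrix with attribute `"observable"` (the
#'   dyad flags).
#' @export
simulate_tournament <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_hummingbirds
  s <- scenario$latent_dominance
  labels <- paste0("H", seq_len(n))
  W <- matrix(0L, n, n, dimnames = list(labels, labels))
  pairs <- which(upper.tri(W), arr.ind = TRUE)
  with_seed(derive_seed(scenario$seed, 11), {
    obs <- stats::runif(nrow(pairs)) < scenario$dyad_observability
    if (scenario$total_contests > 0) {
      if (!any(obs))
        stop_dominet("no observable dyads but total_contests > 0")
      pick <- sample(which(obs), scenario$total_contests, replace = TRUE)
      di <- pairs[pick, 1]; dj <- pairs[pick, 2]
      diff <- s[di] - s[dj]
      p_win <- if (is.infinite(scenario$steepness)) {
        ifelse(diff > 0, 1, ifelse(diff < 0, 0, 0.5))
      } else {
        stats::plogis(scenario$steepness * diff)
      }
      i_wins <- stats::runif(length(pick)) < p_win
      wi <- ifelse(i_wins, di, dj)
      lo <- ifelse(i_wins, dj, di)
      for (c_ in seq_along(wi)) W[wi[c_], lo[c_]] <- W[wi[c_], lo[c_]] + 1L
    }
    attr(W, "observable") <- obs
  })
  W
}

#' Simulate trait tables for both guilds
#'
#' Draws hummingbird morphology (bill length in mm, curvature in degrees,
#' weight in g, with weight mildly correlated with latent dominance, as in
#' communities where the large species are behaviorally dominant) and plant
#' floral traits (corolla length/diameter/curvature, nectar volume in uL
#' and concentration in degrees Brix). One plant is given an agave-like
#' high-volume nectar profile so the community has a clear high-energy
#' resource. Abundances are copied from the scenario.
#'
#' @param scenario a [make_scenario()] object.
#' @return list with data.frames `hummingbirds` and `plants`; the
#'   hummingbird `ds` column carries the latent dominance score (replace it
#'   with the estimated David's score when analysing simulated data
#'   end-to-end).
#' @export
simulate_traits <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_hummingbirds
  m <- scenario$n_plants
  with_seed(derive_seed(scenario$seed, 13), {
    s <- scale(scenario$latent_dominance)[, 1]
    hb <- data.frame(
      species = paste0("H", seq_len(n)),
      bill_length = round(stats::rlnorm(n, log(18), 0.25), 1),
      bill_curvature = round(stats::runif(n, 2, 30), 1),
      weight = round(pmax(2, 4.5 + 1.2 * s + stats::rnorm(n, 0, 0.6)), 1),
      abundance = round(scenario$hummingbird_abundance),
      ds = scenario$latent_dominance)
    pl <- data.frame(
      species = paste0("P", seq_len(m)),
      corolla_length = round(stats::rlnorm(m, log(22), 0.35), 1),
      corolla_diameter = round(stats::rlnorm(m, log(6), 0.3), 1),
      corolla_curvature = round(stats::runif(m, 0, 25), 1),
      nectar_volume = round(stats::rlnorm(m, log(4), 0.5), 2),
      nectar_concentration = round(stats::runif(m, 15, 25), 1),
      flower_abundance = round(scenario$plant_flower_abundance))
    # one agave-like high-reward plant: copious, slightly dilute nectar
    big <- which.max(pl$flower_abundance)
    pl$nectar_volume[big] <- round(stats::rlnorm(1, log(40), 0.2), 2)
    pl$corolla_length[big] <- round(stats::rlnorm(1, log(14), 0.1), 1)
    list(hummingbirds = hb, plants = pl)
  })
}

#' Simulate a quantitative visitation matrix
#'
#' Distributes `total_visits` over hummingbird x plant cells by a single
#' multinomial draw whose cell probabilities mix three normalized drivers:
#' neutral abundance products `A_i * B_j`, morphological matching
#' `exp(-match_ij)`, and a dominance driver in which each hummingbird
#' prefers high-calorie plants with a softmax sharpness that decays with
#' its rank (the top-ranked species concentrates on the richest plants;
#' bottom-ranked species visit indiscriminately).
#'
#' @param scenario a [make_scenario()] object.
#' @param traits list from [simulate_traits()] (or equivalently structured
#'   tables).
#' @param beta_max softmax sharpness of the top-ranked species' calorie
#'   preference.
#' @return visitation count matrix.
#' @export
simulate_visitation <- function(scenario, traits, beta_max = 4) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  hb <- traits$hummingbirds
  pl <- traits$plants
  n <- scenario$n_hummingbirds
  m <- scenario$n_plants
  A <- scenario$hummingbird_abundance
  B <- scenario$plant_flower_abundance

  neutral <- outer(A, B)
  neutral <- neutral / sum(neutral)

  mm <- morphological_match(hb, pl)
  match_p <- exp(-mm)
  match_p <- match_p / sum(match_p)

  cal <- calories_per_flower(pl$nectar_volume,
                             concentration_brix = pl$nectar_concentration)
  zcal <- if (stats::sd(cal) > 0) (cal - mean(cal)) / stats::sd(cal)
          else rep(0, m)
  # rank index 0 for the top latent score; sharpness decays linearly with it
  ridx <- (rank(-scenario$latent_dominance, ties.method = "first") - 1) /
    (n - 1)
  dom <- t(vapply(seq_len(n), function(i) {
    pref <- exp(beta_max * (1 - ridx[i]) * zcal)
    (A[i] / sum(A)) * pref / sum(pref)
  }, numeric(m)))

  p <- scenario$weight_neutral * neutral +
    scenario$weight_match * match_p +
    scenario$weight_dominance * dom
  if (sum(p) <= 0) stop_dominet("all cell weights are zero")
  p <- p / sum(p)

  counts <- with_seed(derive_seed(scenario$seed, 17),
                      stats::rmultinom(1, scenario$total_visits,
                                       as.vector(p)))
  V <- matrix(as.integer(counts), n, m,
              dimnames = list(hb$species, pl$species))
  V
}

#' Planted-partition bipartite test fixture
#'
#' Poisson count matrix with a known block structure: `n_groups` row groups
#' and column groups, within-block mean `within_mean` and between-block
#' mean `between_mean`. Ground-truth labels are attached as attributes, for
#' module-recovery experiments.
#'
#' @param n_row_groups number of planted modules.
#' @param rows_per_group,cols_per_group species per module on each side.
#' @param within_mean,between_mean Poisson cell means
#'   (`within_mean > between_mean >= 0`).
#' @param seed integer seed.
#' @return count matrix with attributes `row_groups` and `col_groups`.
#' @export
planted_partition_matrix <- function(n_row_groups, rows_per_group,
                                     cols_per_group, within_mean,
                                     between_mean, seed = 1) {
  if (n_row_groups < 1 || rows_per_group < 1 || cols_per_group < 1)
    stop_dominet("group counts and sizes must be positive")
  if (!(within_mean > between_mean) || between_mean < 0)
    stop_dominet("need within_mean > between_mean >= 0")
  n <- n_row_groups * rows_per_group
  m <- n_row_groups * cols_per_group
  rg <- rep(seq_len(n_row_groups), each = rows_per_group)
  cg <- rep(seq_len(n_row_groups), each = cols_per_group)
  mu <- ifelse(outer(rg, cg, "=="), within_mean, between_mean)
  A <- with_seed(seed,
                 matrix(stats::rpois(n * m, as.vector(mu)), n, m))
  dimnames(A) <- list(paste0("H", seq_len(n)), paste0("P", seq_len(m)))
  attr(A, "row_groups") <- rg
  attr(A, "col_groups") <- cg
  A
}
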