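#' Caloric reward per flower from nectar measurements
#'
#' Converts nectar volume and sugar concentration to calories per flower:
#' `calories = volume_ul * molarity * 1.34`. Refractometer readings in
#' degrees Brix (g sucrose per 100 g solution) are converted to sucrose
#' molarity as `brix * 10 / 342.3` (grams per litre divided by the molar
#' mass of sucrose); the conversion lives in [brix_to_molarity()] so an
#' alternative (e.g. density-corrected) conversion is a one-line change.
#'
#' @param volume_ul nectar volume in microlitres.
#' @param concentration_brix sugar concentration in degrees Brix; values
#'   outside the 0-32 range of a field refractometer trigger a warning.
#' @param molarity sucrose molarity given directly (overrides
#'   `concentration_brix`).
#' @return calories per flower.
#' @examples
#' calories_per_flower(10, molarity = 0.5)  # 6.7 cal
#' @export
calories_per_flower <- function(volume_ul, concentration_brix = NULL,
                                molarity = NULL) {
  if (any(volume_ul < 0)) stop_dominet("nectar volume must be nonnegative")
  if (is.null(molarity)) {
    if (is.null(concentration_brix))
      stop_dominet("supply concentration_brix or molarity")
    molarity <- brix_to_molarity(concentration_brix)
  } else if (any(molarity < 0)) {
    stop_dominet("molarity must be nonnegative")
  }
  volume_ul * molarity * 1.34
}

#' @rdname calories_per_flower
#' @export
brix_to_molarity <- function(brix) {
  if (any(brix < 0)) stop_dominet("Brix must be nonnegative")
  if (any(brix > 32))
    warning("Brix above the 0-32 refractometer range")
  brix * 10 / 342.3
}

#' Total caloric offer of a plant species
#'
#' @param cal_per_flower calories per flower.
#' @param total_flowers flower abundance (count).
#' @return calories per species (`cal_per_flower * total_flowers`).
#' @export
calories_per_species <- function(cal_per_flower, total_flowers) {
  if (any(cal_per_flower < 0) || any(total_flowers < 0))
    stop_dominet("inputs must be nonnegative")
  cal_per_flower * total_flowers
}

#' Bill-corolla morphological match
#'
#' Standardizes bill length/curvature over the hummingbird species and
#' corolla length/curvature over the plant species (z-scores within each
#' guild's own species set), then returns the Euclidean distance between
#' each hummingbird-plant pair in that standardized (length, curvature)
#' space. Larger values mean a worse match. A trait with zero variance
#' contributes z-scores of 0 (with a warning).
#'
#' @param hb_traits data.frame with `species`, `bill_length`,
#'   `bill_curvature`.
#' @param pl_traits data.frame with `species`, `corolla_length`,
#'   `corolla_curvature`.
#' @return hummingbird x plant matrix of mismatch distances.
#' @export
morphological_match <- function(hb_traits, pl_traits) {
  need_h <- c("species", "bill_length", "bill_curvature")
  need_p <- c("species", "corolla_length", "corolla_curvature")
  if (!all(need_h %in% names(hb_traits)))
    stop_dominet("hb_traits needs columns: ", paste(need_h, collapse = ", "))
  if (!all(need_p %in% names(pl_traits)))
    stop_dominet("pl_traits needs columns: ", paste(need_p, collapse = ", "))
  zscore <- function(x, what) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      warning("zero variance in ", what, "; z-scores set to 0")
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  zbl <- zscore(hb_traits$bill_length, "bill_length")
  zbc <- zscore(hb_traits$bill_curvature, "bill_curvature")
  zcl <- zscore(pl_traits$corolla_length, "corolla_length")
  zcc <- zscore(pl_traits$corolla_curvature, "corolla_curvature")
  D <- sqrt(outer(zbl, zcl, "-")^2 + outer(zbc, zcc, "-")^2)
  dimnames(D) <- list(hb_traits$species, pl_traits$species)
  D
}

#' Relative abundance proportions
#'
#' Pools counts across surveys (columns, if a matrix) and divides each
#' species total by the grand total.
#'
#' @param counts numeric vector of per-species counts, or a species x survey
#'   matrix.
#' @return proportions summing to 1.
#' @export
abundance_proportions <- function(counts) {
  if (is.matrix(counts) || is.data.frame(counts))
    counts <- rowSums(as.matrix(counts))
  if (any(counts < 0)) stop_dominet("counts must be nonnegative")
  total <- sum(counts)
  if (total <= 0) stop_dominet("at least one count must be positive")
  counts / total
}

#' Pairwise predictor table for the interaction-frequency model
#'
#' Builds the full factorial hummingbird x plant table (structural zeros
#' included) with the response `visits` and every model predictor: guild
#' abundance proportions, calories per flower and per species, bill-corolla
#' mismatch, corolla length, bill length, hummingbird weight and David's
#' score.
#'
#' @param visits visitation matrix whose row labels match
#'   `hb_traits$species` and column labels `pl_traits$species`.
#' @param hb_traits data.frame: `species`, `bill_length`, `bill_curvature`,
#'   `weight`, `abundance`, `ds`.
#' @param pl_traits data.frame: `species`, `corolla_length`,
#'   `corolla_diameter`, `corolla_curvature`, `nectar_volume`,
#'   `nectar_concentration` (Brix), `flower_abundance`.
#' @return data.frame with one row per species pair.
#' @export
build_pair_table <- function(visits, hb_traits, pl_traits) {
  visits <- as_visitation_matrix(visits, require_positive = FALSE)
  need_h <- c("species", "bill_length", "bill_curvature", "weight",
              "abundance", "ds")
  need_p <- c("species", "corolla_length", "corolla_diameter",
              "corolla_curvature", "nectar_volume", "nectar_concentration",
              "flower_abundance")
  if (!all(need_h %in% names(hb_traits)))
    stop_dominet("hb_traits needs columns: ",
                 paste(setdiff(need_h, names(hb_traits)), collapse = ", "))
  if (!all(need_p %in% names(pl_traits)))
    stop_dominet("pl_traits needs columns: ",
                 paste(setdiff(need_p, names(pl_traits)), collapse = ", "))
  miss_h <- setdiff(rownames(visits), hb_traits$species)
  miss_p <- setdiff(colnames(visits), pl_traits$species)
  if (length(miss_h) || length(miss_p))
    stop_dominet("species missing from trait tables: ",
                 paste(c(miss_h, miss_p), collapse = ", "))
  hb <- hb_traits[match(rownames(visits), hb_traits$species), ]
  pl <- pl_traits[match(colnames(visits), pl_traits$species), ]

  cal_fl <- calories_per_flower(pl$nectar_volume,
                                concentration_brix = pl$nectar_concentration)
  cal_sp <- calories_per_species(cal_fl, pl$flower_abundance)
  mm <- morphological_match(hb, pl)
  hprop <- abundance_proportions(hb$abundance)
  fprop <- abundance_proportions(pl$flower_abundance)

  idx <- expand.grid(i = seq_len(nrow(visits)), j = seq_len(ncol(visits)))
  data.frame(
    hummingbird = rownames(visits)[idx$i],
    plant = colnames(visits)[idx$j],
    visits = visits[cbind(idx$i, idx$j)],
    morph_match = mm[cbind(idx$i, idx$j)],
    flower_abundance_prop = fprop[idx$j],
    hummingbird_abundance_prop = hprop[idx$i],
    calories_per_flower = cal_fl[idx$j],
    calories_per_species = cal_sp[idx$j],
    corolla_length = pl$corolla_length[idx$j],
    bill_length = hb$bill_length[idx$i],
    weight = hb$weight[idx$i],
    ds = hb$ds[idx$i],
    stringsAsFactors = FALSE)
}

# Profile negative-binomial log-likelihood of theta: refit the GCV GAM at a
# fixed theta and score the NB likelihood at its fitted means. Predictors
# here have one distinct value per species (10-13 levels), so some P-spline
# basis ranges are empty; the difference penalty keeps those coefficients
# identified, and mgcv's warning about them is muffled as expected noise.
nb_profile_fit <- function(formula, data, theta, gamma) {
  withCallingHandlers(
    mgcv::gam(formula, data = data, family = mgcv::negbin(theta),
              method = "GCV.Cp", gamma = gamma),
    warning = function(w) {
      if (grepl("no.*information about some basis coefficients",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Negative-binomial GAM of pairwise interaction frequency
#'
#' Fits `visits ~ s(x1) + s(x2) + ...` with a negative-binomial family (log
#' link) and one univariate penalized cubic P-spline per predictor
#' (second-order difference penalty). Smoothing parameters are chosen by
#' generalized cross-validation with each effective degree of freedom
#' costed at `gamma` (the anti-overfitting inflation; default 1.4). The NB
#' dispersion theta is estimated by outer profile-likelihood maximization
#' over a log-scale grid bracketing `theta_range`.
#'
#' @param pair_table data.frame from [build_pair_table()] (or any table
#'   with an integer `visits` column and the named predictors).
#' @param predictors character vector of predictor columns to smooth.
#' @param gamma GCV degrees-of-freedom inflation.
#' @param basis_size spline basis dimension per smooth (reduced
#'   automatically when a predictor has few distinct values).
#' @param theta_range search interval for the NB dispersion.
#' @return object of class `nb_gam_fit`: the mgcv model, a `smooth_table`
#'   (term, edf, chi_square, p_value), `theta`, `deviance_explained` (in
#'   percent), `r2_adj`, and `fitted` means.
#' @export
fit_nb_gam <- function(pair_table,
                       predictors = c("hummingbird_abundance_prop",
                                      "flower_abundance_prop",
                                      "calories_per_flower",
                                      "calories_per_species",
                                      "morph_match", "corolla_length",
                                      "bill_length", "weight", "ds"),
                       gamma = 1.4, basis_size = 10,
                       theta_range = c(0.05, 100)) {
  if (!"visits" %in% names(pair_table))
    stop_dominet("pair_table needs a 'visits' column")
  y <- pair_table$visits
  if (length(y) < 30) stop_dominet("need at least 30 records to fit the GAM")
  if (any(y < 0) || any(y != round(y)))
    stop_dominet("response must be nonnegative integer counts")
  missing_pred <- setdiff(predictors, names(pair_table))
  if (length(missing_pred))
    stop_dominet("predictors not in table: ",
                 paste(missing_pred, collapse = ", "))

  terms <- vapply(predictors, function(p) {
    k <- min(basis_size, length(unique(pair_table[[p]])))
    if (k < 3) sprintf("%s", p)               # too few levels to smooth
    else sprintf("s(%s, bs = \"ps\", k = %d, m = c(2, 2))", p, k)
  }, character(1))
  form <- stats::as.formula(paste("visits ~", paste(terms, collapse = " + ")))

  prof <- function(log_theta) {
    f <- nb_profile_fit(form, pair_table, exp(log_theta), gamma)
    -sum(stats::dnbinom(y, size = exp(log_theta), mu = stats::fitted(f),
                        log = TRUE))
  }
  opt <- stats::optimize(prof, log(theta_range))
  theta <- exp(opt$minimum)
  fit <- nb_profile_fit(form, pair_table, theta, gamma)

  sm <- summary(fit)
  smooth_table <- if (nrow(sm$s.table) > 0) {
    data.frame(term = sub("^s\\((.*)\\)$", "\\1", rownames(sm$s.table)),
               edf = sm$s.table[, "edf"],
               chi_square = sm$s.table[, "Chi.sq"],
               p_value = sm$s.table[, "p-value"],
               row.names = NULL)
  } else {
    data.frame(term = character(), edf = numeric(),
               chi_square = numeric(), p_value = numeric())
  }
  structure(
    list(model = fit, smooth_table = smooth_table, theta = theta,
         deviance_explained = 100 * sm$dev.expl,
         r2_adj = sm$r.sq, fitted = stats::fitted(fit),
         gamma = gamma, formula = form),
    class = "nb_gam_fit")
}

#' @export
print.nb_gam_fit <- function(x, ...) {
  cat("Negative-binomial GAM (GCV, gamma =", x$gamma,
      ", theta =", signif(x$theta, 4), ")\n")
  tab <- x$smooth_table
  tab$edf <- round(tab$edf, 3)
  tab$chi_square <- round(tab$chi_square, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  cat("Deviance explained:", round(x$deviance_explained, 1),
      "%  adj. R2:", round(x$r2_adj, 3), "\n")
  invisible(x)
}
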