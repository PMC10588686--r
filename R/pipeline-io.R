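#' Read a labelled matrix from CSV
#'
#' Expects species labels in the first row and first column and a numeric
#' body; validates shape and content and returns the labelled matrix.
#'
#' @param path CSV file path.
#' @param square_required error unless the matrix is square (agonistic
#'   matrices).
#' @return numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path, square_required = FALSE) {
  if (!file.exists(path)) stop_dominet("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  row_labels <- as.character(df[[1]])
  col_labels <- names(df)[-1]
  if (anyDuplicated(row_labels))
    stop_dominet("duplicate row label: ",
                 row_labels[duplicated(row_labels)][1])
  if (anyDuplicated(col_labels))
    stop_dominet("duplicate column label: ",
                 col_labels[duplicated(col_labels)][1])
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M) || any(is.na(M)))
    stop_dominet("matrix body must be numeric with no missing cells: ", path)
  if (any(M < 0)) stop_dominet("negative cells in ", path)
  dimnames(M) <- list(row_labels, col_labels)
  if (square_required && nrow(M) != ncol(M))
    stop_dominet("square matrix required, got ", nrow(M), "x", ncol(M))
  M
}

#' Write a labelled matrix to CSV
#'
#' Inverse of [read_matrix_csv()]: labels in the first row and column.
#'
#' @param M labelled numeric matrix.
#' @param path output path.
#' @export
write_matrix_csv <- function(M, path) {
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' Holds the input paths, seeds, and stage settings of the full analysis,
#' with defaults at the field-standard values: 50 modularity runs, 100
#' Patefield null replicates, a dominance-certainty threshold of 0.5, and
#' the GAM's GCV inflation gamma = 1.4.
#'
#' @param agonistic,visitation,hb_traits,pl_traits optional input CSV
#'   paths; when `NULL` the pipeline simulates a synthetic community.
#' @param seed master seed.
#' @param n_runs,n_null modularity search restarts and null replicates.
#' @param dc_threshold dominance-certainty filter threshold.
#' @param gamma,basis_size GAM settings.
#' @param out_dir optional output directory for the JSON report.
#' @return object of class `run_config` (a plain list; round-trips through
#'   [write_config()] / [read_config()] losslessly).
#' @export
run_config <- function(agonistic = NULL, visitation = NULL,
                       hb_traits = NULL, pl_traits = NULL, seed = 1,
                       n_runs = 50, n_null = 100, dc_threshold = 0.5,
                       gamma = 1.4, basis_size = 10, out_dir = NULL) {
  cfg <- list(agonistic = agonistic, visitation = visitation,
              hb_traits = hb_traits, pl_traits = pl_traits, seed = seed,
              n_runs = n_runs, n_null = n_null,
              dc_threshold = dc_threshold, gamma = gamma,
              basis_size = basis_size, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full dominance-to-network pipeline
#'
#' Executes the analysis stages in their natural order: dominance ranking
#' (David's score, dominance probabilities, certainty), DC filtering,
#' tournament summary, network metrics (d', modularity + Patefield
#' z-score, core-periphery), the pairwise trait table and NB-GAM, the three
#' PCAs, and the specialization regressions. With no input paths in the
#' config, a synthetic community is simulated from the config seed, so the
#' pipeline is runnable end-to-end without field data.
#'
#' @param config a [run_config()].
#' @return a nested report list (also written as JSON to
#'   `config$out_dir/report.json` when `out_dir` is set).
#' @export
run_reproduce <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_dominet("stage '", name, "' failed: ", conditionMessage(e)))
  }

  synth <- is.null(config$visitation)
  if (synth) {
    scen <- make_scenario(seed = seed)
    W <- simulate_tournament(scen)
    traits <- simulate_traits(scen)
    V <- simulate_visitation(scen, traits)
    hb <- traits$hummingbirds
    pl <- traits$plants
  } else {
    stage("inputs", {
      V <- as_visitation_matrix(read_matrix_csv(config$visitation))
      W <- if (!is.null(config$agonistic))
        as_agonistic_matrix(read_matrix_csv(config$agonistic, TRUE))
      hb <- if (!is.null(config$hb_traits))
        utils::read.csv(config$hb_traits, check.names = FALSE)
      pl <- if (!is.null(config$pl_traits))
        utils::read.csv(config$pl_traits, check.names = FALSE)
    })
  }

  report <- list(config = unclass(config))

  # --- dominance ----------------------------------------------------------
  if (!is.null(W)) stage("dominance", {
    dom <- dominance_analysis(W, seed = derive_seed(seed, 31))
    summ <- tournament_summary(W)
    report$tournament <- c(summ,
                           list(per_individual_1dp =
                                  round(summ$per_individual, 1),
                                per_dyad_1dp = round(summ$per_dyad, 1)))
    report$dominance <- list(
      species = dom$labels, ds = unname(dom$ds),
      rank = unname(dom$ranks), rank_index = unname(dom$rank_index),
      dc_mean = unname(dom$dc_mean), dc_sd = unname(dom$dc_sd))
    filt <- tryCatch(
      filter_uncertain_species(W, dom, config$dc_threshold),
      error = function(e) NULL)
    if (!is.null(filt) && nrow(filt) < nrow(W)) {
      dom_f <- dominance_analysis(filt, seed = derive_seed(seed, 32))
      report$dominance_filtered <- list(
        species = dom_f$labels, ds = unname(dom_f$ds),
        rank = unname(dom_f$ranks), dc_mean = unname(dom_f$dc_mean))
    }
  }) else dom <- NULL

  # --- network metrics ----------------------------------------------------
  stage("network metrics", {
    part <- modularity_zscore(V, n_null = config$n_null,
                              n_runs = config$n_runs,
                              seed = derive_seed(seed, 41))
    cp <- core_periphery(V)
    dspec <- specialization_d(V)
  })
  report$network <- list(
    grand_total = sum(V), n_hummingbirds = nrow(V), n_plants = ncol(V),
    Q = part$Q, Q_3dp = round(part$Q, 3), n_modules = part$n_modules,
    null_mean = part$null_mean, null_sd = part$null_sd, z = part$z,
    row_modules = unname(part$row_modules),
    col_modules = unname(part$col_modules),
    cpness = cp$cpness, E = as.list(cp$E),
    core_hummingbirds = names(cp$row_core)[cp$row_core],
    core_plants = names(cp$col_core)[cp$col_core])
  report$specialization <- dspec

  # --- interaction model --------------------------------------------------
  if (!is.null(hb) && !is.null(pl)) stage("interaction model", {
    if (!is.null(dom)) hb$ds <- unname(dom$ds[match(hb$species,
                                                    dom$labels)])
    pair <- build_pair_table(V, hb, pl)
    gam_fit <- fit_nb_gam(pair, gamma = config$gamma,
                          basis_size = config$basis_size)
    report$gam <- list(smooth_table = gam_fit$smooth_table,
                       theta = gam_fit$theta,
                       deviance_explained = gam_fit$deviance_explained,
                       r2_adj = gam_fit$r2_adj)

    # --- PCAs -------------------------------------------------------------
    hb_pca <- pca(data.frame(ds = hb$ds, weight = hb$weight,
                             bill_length = hb$bill_length,
                             bill_curvature = hb$bill_curvature,
                             row.names = hb$species))
    cal <- calories_per_flower(pl$nectar_volume,
                               concentration_brix = pl$nectar_concentration)
    pl_pca <- pca(data.frame(nectar_volume = pl$nectar_volume,
                             nectar_concentration = pl$nectar_concentration,
                             calories = cal,
                             corolla_length = pl$corolla_length,
                             corolla_diameter = pl$corolla_diameter,
                             corolla_curvature = pl$corolla_curvature,
                             row.names = pl$species))
    report$pca <- list(
      hummingbird = list(percent_variance =
                           unname(hb_pca$percent_variance),
                         contributions = hb_pca$contributions),
      floral = list(percent_variance = unname(pl_pca$percent_variance),
                    contributions = pl_pca$contributions))

    # --- regressions ------------------------------------------------------
    dsp <- dspec[match(hb$species, dspec$species), ]
    regs <- list(
      d_prime_vs_ds = linreg(hb$ds, dsp$d_prime),
      d_prime_vs_bill_length = linreg(hb$bill_length, dsp$d_prime),
      d_prime_vs_bill_curvature = linreg(hb$bill_curvature, dsp$d_prime))
    if (!is.null(dom)) {
      ri <- dom$rank_index[match(hb$species, dom$labels)]
      regs$d_prime_vs_rank_index <- linreg(unname(ri), dsp$d_prime)
    }
    report$regressions <- lapply(regs, function(r)
      list(slope = r$slope, r_squared = r$r_squared,
           r_squared_2dp = round(r$r_squared, 2), F = r$F,
           df1 = r$df1, df2 = r$df2, p_value = r$p_value))
  }) else {
    warning("trait tables absent; GAM, PCA and regression stages skipped")
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
  }
  invisible(report)
}
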