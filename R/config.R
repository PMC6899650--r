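#' Analysis configuration
#'
#' Bundles the tunable parameters of the spatial analysis. Defaults follow
#' the census conventions for metre-scale bedding planes: 0.1 m bandwidth
#' with 3-step smoothing up to 2.5 m, 999 Monte-Carlo simulations with the
#' 5% highest and lowest (rank 50) defining the envelope, a 0.02 m
#' small-scale exclusion when fitting cluster models, and a 0.5 m moving
#' window for heterogeneous Poisson backgrounds.
#'
#' @param bandwidth PCF bandwidth h, metres.
#' @param r_max largest analysed distance, metres.
#' @param smoothing_span moving-average span in bandwidths.
#' @param n_sims Monte-Carlo simulations per envelope.
#' @param envelope_rank envelope rank (`NULL`: 5% of `n_sims`).
#' @param n_sims_select cheaper simulation count used only to rank candidate
#'   moving-window radii.
#' @param hp_R moving-window radius for heterogeneous Poisson models,
#'   metres; `NULL` grid-searches `R_grid` by goodness of fit.
#' @param R_grid candidate moving-window radii, metres.
#' @param r_exclusion small-scale exclusion radius for model fitting,
#'   metres (finite specimen size).
#' @param pd_threshold minimum Diggle p_d (on both the PCF and
#'   nearest-neighbour bases) for an acceptable fit.
#' @param refit_pd below this p_d the cluster-model fit basis is switched
#'   (PCF+L to PCF only to L only).
#' @param dtc_residual_pd below this TC p_d a second cluster scale triggers
#'   a double Thomas fit.
#' @param max_excursion_steps longest tolerated envelope excursion, in grid
#'   steps, for an acceptable fit. The default (`NULL`) uses
#'   `smoothing_span`: the moving average correlates runs of up to span
#'   adjacent bins, so only longer excursions carry evidence beyond a single
#'   independent fluctuation.
#' @param min_n smallest pattern size the fitting protocol accepts.
#' @param abundance_threshold minimum per-taxon abundance analysed.
#' @param seed master RNG seed for a pipeline run.
#' @return A list of class `sppa_config`.
#' @export
sppa_config <- function(bandwidth = 0.1, r_max = 2.5, smoothing_span = 3,
                        n_sims = 999, envelope_rank = NULL,
                        n_sims_select = 99, hp_R = 0.5,
                        R_grid = seq(0.1, 1, by = 0.1),
                        r_exclusion = 0.02, pd_threshold = 0.05,
                        refit_pd = 0.1, dtc_residual_pd = 0.2,
                        max_excursion_steps = NULL, min_n = 10,
                        abundance_threshold = 30, seed = NULL) {
  if (is.null(envelope_rank)) envelope_rank <- max(1, ceiling(0.05 * n_sims))
  if (is.null(max_excursion_steps)) max_excursion_steps <- smoothing_span
  stopifnot(n_sims >= 2 * envelope_rank)
  structure(list(bandwidth = bandwidth, r_max = r_max,
                 smoothing_span = smoothing_span, n_sims = n_sims,
                 envelope_rank = envelope_rank,
                 n_sims_select = n_sims_select, hp_R = hp_R, R_grid = R_grid,
                 r_exclusion = r_exclusion, pd_threshold = pd_threshold,
                 refit_pd = refit_pd, dtc_residual_pd = dtc_residual_pd,
                 max_excursion_steps = max_excursion_steps, min_n = min_n,
                 abundance_threshold = abundance_threshold, seed = seed),
            class = "sppa_config")
}

config_grid <- function(config) {
  distance_grid(config$bandwidth, config$r_max, config$smoothing_span)
}

# Analysis grid for a given window: the configured r_max, capped at a
# quarter of the window diameter (larger distances are not estimable from a
# census surface).
grid_for_window <- function(config, window) {
  diam <- sqrt(diff(window$xrange)^2 + diff(window$yrange)^2)
  r_max <- min(config$r_max, diam / 4)
  r_max <- max(r_max, 5 * config$bandwidth)  # keep a usable grid
  distance_grid(config$bandwidth, r_max, config$smoothing_span)
}
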