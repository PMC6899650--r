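# End-to-end orchestration: bias screening, per-taxon univariate model
# ladder, pairwise bivariate independence tests, niche/neutral summary, and
# report files per surface.

pd_row <- function(fit) {
  out <- list()
  for (m in c("CSR", "HP", "TC", "DTC", "ITC")) {
    row <- fit$candidates[fit$candidates$model == m, , drop = FALSE]
    out[[paste0("p_d_pcf_", m)]] <- if (nrow(row)) row$p_d_pcf else NA
    out[[paste0("p_d_nn_", m)]] <- if (nrow(row)) row$p_d_nn else NA
  }
  out
}

fit_table_row <- function(surface, taxon, fit) {
  p <- fit$params
  tc <- if (inherits(p, "thomas_params")) p
        else if (is.list(p) && inherits(p$thomas, "thomas_params")) p$thomas
        else if (inherits(p, "double_thomas_params")) p$large
  as.data.frame(c(list(surface = surface, taxon = taxon, n = fit$n,
                       model_fit = fit$kind,
                       sigma = if (!is.null(tc)) tc$sigma else NA,
                       rho = if (!is.null(tc)) tc$rho else NA,
                       mean_cluster = if (!is.null(tc))
                         mean_cluster_size(tc) else NA,
                       fit_basis = fit$fit_basis),
                  pd_row(fit)), stringsAsFactors = FALSE)
}

#' Run the full spatial analysis on one or more surfaces
#'
#' Per surface: differential-erosion screening (AIC model comparison, the
#' adopted surface becoming the null background), the univariate model
#' ladder for every analysis taxon, toroidal-shift bivariate tests for every
#' taxon pair on the largest inscribed rectangle, a niche/neutral summary,
#' and report files (`bias_report.csv`, `fit_table.csv`,
#' `bivariate_table.csv`, `surface_summary.csv`, diagnostic plots). A
#' failing stage is reported for its surface without aborting the others.
#'
#' @param maps list of `bed_map` objects and/or CSV paths readable by
#'   [read_surface_map()].
#' @param config an [sppa_config()].
#' @param out_dir output directory (created); `NULL` writes no files.
#' @param seed master seed (overrides `config$seed`).
#' @param erosion_anchor optional `c(x, y)` anchor for the radial erosion
#'   model, recycled across surfaces.
#' @param make_plots write diagnostic PDF plots (default `TRUE`).
#' @return Invisibly, a list per surface with `fits`, `classifications`,
#'   `bivariate`, `bias`, `summary`, `fit_table`, plus any `error`.
#' @export
run_pipeline <- function(maps, config = sppa_config(), out_dir = NULL,
                         seed = NULL, erosion_anchor = NULL,
                         make_plots = TRUE) {
  if (inherits(maps, "bed_map") || is.character(maps) && length(maps) == 1)
    maps <- list(maps)
  seed <- seed %||% config$seed
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  surface_seeds <- child_seeds(seed, length(maps))
  results <- list()
  for (si in seq_along(maps)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      analyse_surface(maps[[si]], config, surface_seeds[[si]],
                      erosion_anchor),
      error = function(e) list(error = conditionMessage(e)))
    name <- res$surface %||% paste0("surface_", si)
    results[[name]] <- res
    message(sprintf("[sppa] surface %s: %.1f s%s", name,
                    proc.time()[["elapsed"]] - t0,
                    if (!is.null(res$error)) paste0(" FAILED: ", res$error)
                    else ""))
    if (!is.null(out_dir) && is.null(res$error))
      write_surface_reports(res, out_dir, make_plots)
  }
  invisible(results)
}

analyse_surface <- function(map, config, seed, erosion_anchor = NULL) {
  if (is.character(map)) map <- read_surface_map(map)
  stopifnot(inherits(map, "bed_map"))
  surface <- map$surface_name
  filtered <- filter_analysis_taxa(map, config$abundance_threshold)
  taxa <- names(taxon_counts(filtered))
  if (length(taxa) == 0) stop("no analysis taxa after filtering")

  # Bias screening on the pooled census.
  bias <- NULL; background <- NULL
  if (nrow(map$records) >= 10) {
    fits <- suppressMessages(
      fit_erosion_models(taxon_points(map), map$window,
                         anchor = erosion_anchor))
    bias <- erosion_report(fits)
    adopted <- bias$model_kind[bias$adopted]
    if (length(adopted) && adopted != "homogeneous") {
      k <- which(vapply(fits, function(f) f$model_kind, character(1)) ==
                 adopted)[1]
      background <- apply_bias_surface(fits[[k]], map$window)
    }
  }

  taxa_seeds <- child_seeds(seed, length(taxa) + 1)
  fits <- list(); classifications <- list(); fit_rows <- list()
  for (ti in seq_along(taxa)) {
    tx <- taxa[ti]
    fit <- fit_protocol(taxon_points(filtered, tx), map$window, config,
                        background = background, seed = taxa_seeds[[ti]])
    attr(fit, "taxon") <- tx
    fits[[tx]] <- fit
    classifications[[tx]] <- classify_univariate(fit)
    fit_rows[[tx]] <- fit_table_row(surface, tx, fit)
  }

  # Bivariate tests on the largest inscribed rectangle.
  bivariate <- list()
  if (length(taxa) >= 2) {
    rect <- largest_inscribed_rect(map$window)
    clipped <- extract_rect_subwindow(filtered, rect)
    pair_seeds <- child_seeds(taxa_seeds[[length(taxa) + 1]],
                              length(taxa) * (length(taxa) - 1) / 2)
    k <- 0
    for (i in seq_len(length(taxa) - 1)) for (j in (i + 1):length(taxa)) {
      k <- k + 1
      pa <- taxon_points(clipped, taxa[i]); pb <- taxon_points(clipped, taxa[j])
      if (nrow(pa) < config$min_n || nrow(pb) < config$min_n) next
      bt <- toroidal_shift_test(pa, pb, rect, grid_for_window(config, rect),
                                n_sims = config$n_sims,
                                rank = config$envelope_rank,
                                seed = pair_seeds[[k]],
                                taxon_a = taxa[i], taxon_b = taxa[j])
      key <- paste(taxa[i], taxa[j], sep = "-")
      bivariate[[key]] <- bt
      classifications[[key]] <- classify_bivariate(bt)
    }
  }

  list(surface = surface,
       fits = fits,
       classifications = classifications,
       bivariate = bivariate,
       bias = bias,
       fit_table = do.call(rbind, unname(fit_rows)),
       bivariate_table = bivariate_table(bivariate),
       summary = summarize_surface(unname(classifications), surface))
}

bivariate_table <- function(bivariate) {
  if (length(bivariate) == 0) return(NULL)
  do.call(rbind, lapply(unname(bivariate), function(b) {
    exc <- b$envelope$excursions
    data.frame(taxon_a = b$taxon_a, taxon_b = b$taxon_b,
               n_a = b$n_a, n_b = b$n_b, independent = b$independent,
               direction = b$direction,
               density_change_pct = b$density_change_pct,
               excursion_r = if (is.null(exc) || nrow(exc) == 0) "" else
                 paste(sprintf("%s[%.2f,%.2f]", exc$direction, exc$r_lo,
                               exc$r_hi), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

write_surface_reports <- function(res, out_dir, make_plots = TRUE) {
  pre <- file.path(out_dir, res$surface)
  if (!is.null(res$bias))
    write.csv(res$bias, paste0(pre, "_bias_report.csv"), row.names = FALSE)
  write.csv(res$fit_table, paste0(pre, "_fit_table.csv"), row.names = FALSE)
  if (!is.null(res$bivariate_table))
    write.csv(res$bivariate_table, paste0(pre, "_bivariate_table.csv"),
              row.names = FALSE)
  s <- res$summary
  write.csv(data.frame(surface = s$surface,
                       model_kind = names(s$model_counts),
                       count = as.integer(s$model_counts),
                       proportion = as.numeric(s$model_proportions),
                       univariate_neutral = s$univariate_neutral,
                       univariate_niche = s$univariate_niche,
                       bivariate_neutral = s$bivariate_neutral,
                       bivariate_niche = s$bivariate_niche),
            paste0(pre, "_surface_summary.csv"), row.names = FALSE)
  if (make_plots) {
    tryCatch({
      grDevices::pdf(paste0(pre, "_plots.pdf"), width = 7, height = 5)
      on.exit(grDevices::dev.off(), add = TRUE)
      for (tx in names(res$fits)) {
        env <- res$fits[[tx]]$envelopes[["CSR"]]
        if (!is.null(env))
          plot(env$observed,
               main = sprintf("%s: %s (best: %s)", res$surface, tx,
                              res$fits[[tx]]$kind))
      }
      props <- res$summary$model_proportions
      if (length(props))
        graphics::barplot(as.numeric(props) * 100, names.arg = names(props),
                          ylab = "% of taxa", main = res$surface,
                          col = ifelse(names(props) %in%
                                         c("CSR", "TC", "DTC"),
                                       "steelblue", "firebrick"))
      for (key in names(res$bivariate))
        plot(res$bivariate[[key]]$envelope$observed,
             main = sprintf("%s: %s", res$surface, key))
    }, error = function(e)
      warning("plotting failed: ", conditionMessage(e)))
  }
  invisible(NULL)
}
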