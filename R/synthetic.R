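# Ground-truthed synthetic fossil beds. Each taxon is generated from a
# named point process (CSR, heterogeneous Poisson, Thomas cluster, nested
# double cluster, or thinned inhomogeneous cluster), sizes are attached from
# lognormal distributions, and the assembled community can then be distorted
# by tectonic strain and differential-erosion thinning — the forward models
# of the biases the analysis corrects. The generation record (ground truth)
# retains every parameter and per-specimen survival, so recovery and
# classification tests can be scored against the truth.

#' Taxon specification for synthetic communities
#'
#' @param taxon label.
#' @param process `"CSR"`, `"HP"`, `"TC"`, `"DTC"` or `"ITC"`.
#' @param target_n expected specimen count in the window (counts are
#'   Poisson-distributed around it except for CSR and HP, which condition on
#'   it exactly).
#' @param params process parameters: nothing for CSR; for HP a list
#'   `(covariate, b)` or `(covariate, b, anchor)` on log intensity; for TC a
#'   list `(sigma, rho)` (`lambda` is set from `target_n`); for DTC
#'   `(sigma, rho, small_sigma, small_mu)`; for ITC the TC parameters plus
#'   the HP-style surface spec under `$surface`.
#' @param size_distribution list `(meanlog, sdlog)` of the lognormal disc
#'   diameter / frond length in metres, or `NULL` for no sizes.
#' @param group_class census class (default `"described_taxon"`).
#' @export
taxon_spec <- function(taxon, process = c("CSR", "HP", "TC", "DTC", "ITC"),
                       target_n, params = list(),
                       size_distribution = list(meanlog = log(0.05),
                                                sdlog = 0.4),
                       group_class = "described_taxon") {
  process <- match.arg(process)
  stopifnot(target_n >= 0)
  structure(list(taxon = taxon, process = process, target_n = target_n,
                 params = params, size_distribution = size_distribution,
                 group_class = group_class),
            class = "taxon_spec")
}

#' Community specification for synthetic fossil beds
#'
#' @param window an [sppa_window][owin_rect].
#' @param taxa list of [taxon_spec()]s.
#' @param strain optional [strain_estimate()] applied as a forward
#'   distortion.
#' @param erosion optional erosion spec: list with `kind`
#'   (`"gradient_x"`, `"gradient_y"`, `"radial_from_point"`), slope `b` on
#'   log retention, optional `anchor`.
#' @param surface_name label.
#' @param seed default RNG seed for [generate_community()].
#' @export
community_spec <- function(window, taxa, strain = NULL, erosion = NULL,
                           surface_name = "synthetic", seed = NULL) {
  dens <- sum(vapply(taxa, function(t) t$target_n, numeric(1))) /
    window_area(window)
  if (dens < 0.5 || dens > 150)
    warning(sprintf("total expected density %.2f ind/m2 outside the 0.5-150 plausibility band",
                    dens))
  structure(list(window = window, taxa = taxa, strain = strain,
                 erosion = erosion, surface_name = surface_name, seed = seed),
            class = "community_spec")
}

taxon_surface <- function(sp, window, target_lambda = NULL) {
  b <- sp$b %||% 1.5
  kind <- sp$covariate %||% sp$kind %||% "gradient_x"
  # intercept chosen so the surface integrates to target_lambda * |W|
  a0 <- 0
  I <- window_covariate_integral(window, kind, b, sp$anchor)
  if (!is.null(target_lambda))
    a0 <- log(target_lambda * window_area(window) / I)
  gradient_intensity(kind, a0, b, anchor = sp$anchor, window = window)
}

generate_taxon_points <- function(tx, window) {
  A <- window_area(window)
  lambda <- tx$target_n / A
  switch(tx$process,
    CSR = runif_window(tx$target_n, window),
    HP = {
      surf <- taxon_surface(tx$params, window, lambda)
      simulate_heterogeneous_poisson(surf, window, n = tx$target_n)
    },
    TC = {
      p <- thomas_params(tx$params$sigma, tx$params$rho, lambda)
      simulate_thomas(p, window)
    },
    DTC = {
      small_mu <- tx$params$small_mu
      large <- thomas_params(tx$params$sigma, tx$params$rho,
                             lambda / small_mu)
      simulate_double_thomas(
        double_thomas_params(large, tx$params$small_sigma, small_mu), window)
    },
    ITC = {
      surf <- taxon_surface(tx$params$surface, window, lambda)
      p <- thomas_params(tx$params$sigma, tx$params$rho, lambda)
      simulate_inhom_thomas(p, surf, window, rescale = TRUE)
    })
}

#' Generate a ground-truthed synthetic community
#'
#' Per-taxon patterns are drawn from the named simulators, merged into a
#' [bed_map()] with lognormal sizes attached, then the forward tectonic
#' strain and erosion thinning are applied, in that order. The returned
#' ground truth records every generator parameter, per-taxon realized
#' counts, and per-specimen erosion survival.
#'
#' @param spec a [community_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return list with elements `map` (a `bed_map`) and `truth`.
#' @export
generate_community <- function(spec, seed = NULL) {
  seed <- seed %||% spec$seed
  with_seed(seed, {
    recs <- list()
    truth_taxa <- list()
    next_id <- 1L
    for (tx in spec$taxa) {
      pts <- generate_taxon_points(tx, spec$window)
      n <- nrow(pts)
      df <- if (n == 0) NULL else {
        d <- data.frame(specimen_id = seq.int(next_id, length.out = n),
                        taxon = tx$taxon, group_class = tx$group_class,
                        x = pts[, 1], y = pts[, 2])
        if (!is.null(tx$size_distribution)) {
          diam <- rlnorm(n, tx$size_distribution$meanlog,
                         tx$size_distribution$sdlog)
          d$disc_width <- diam
          d$disc_length <- diam
          d$disc_orientation <- 0
          d$frond_length <- rlnorm(n, tx$size_distribution$meanlog + log(3),
                                   tx$size_distribution$sdlog)
        }
        d
      }
      if (!is.null(df)) recs[[length(recs) + 1]] <- df
      truth_taxa[[tx$taxon]] <- list(process = tx$process,
                                     params = tx$params,
                                     target_n = tx$target_n, realized_n = n)
      next_id <- next_id + n
    }
    records <- if (length(recs)) {
      all_names <- unique(unlist(lapply(recs, names)))
      do.call(rbind, lapply(recs, function(d) {
        for (nm in setdiff(all_names, names(d))) d[[nm]] <- NA
        d[, all_names]
      }))
    } else data.frame(taxon = character(0), x = numeric(0), y = numeric(0))
    map <- bed_map(records, window = spec$window,
                   surface_name = spec$surface_name)
    truth <- list(taxa = truth_taxa, strain = spec$strain,
                  erosion = spec$erosion, seed = seed)
    if (!is.null(spec$strain)) map <- apply_tectonic_strain(map, spec$strain)
    if (!is.null(spec$erosion)) {
      thinned <- apply_erosion_thinning(map, spec$erosion)
      truth$survived <- attr(thinned, "survived")
      map <- thinned
    }
    list(map = map, truth = truth)
  })
}

#' Thin a map by a differential-erosion retention field (forward model)
#'
#' Independent thinning with retention proportional to
#' `exp(b * covariate)`, normalized to a maximum of 1 over the window. The
#' per-specimen survival indicator (indexed like the input records) is
#' attached as attribute `"survived"`.
#'
#' @param map a `bed_map`.
#' @param erosion list with `kind`, `b`, optional `anchor`
#'   (see [community_spec()]).
#' @param seed optional RNG seed.
#' @export
apply_erosion_thinning <- function(map, erosion, seed = NULL) {
  with_seed(seed, {
    rec <- map$records
    if (nrow(rec) == 0) return(map)
    kind <- erosion$kind %||% "gradient_x"
    zf <- covariate_fun(kind, erosion$anchor)
    logret <- erosion$b * zf(rec$x, rec$y)
    v <- map$window$vertices
    gx <- seq(map$window$xrange[1], map$window$xrange[2], length.out = 21)
    gy <- seq(map$window$yrange[1], map$window$yrange[2], length.out = 21)
    gg <- expand.grid(x = c(gx, v[, 1]), y = c(gy, v[, 2]))
    logmax <- max(erosion$b * zf(gg$x, gg$y))
    keep <- runif(nrow(rec)) <= exp(logret - logmax)
    out <- bed_map(rec[keep, , drop = FALSE], window = map$window,
                   surface_name = map$surface_name)
    attr(out, "survived") <- keep
    out
  })
}

#' Bank of named synthetic scenarios
#'
#' Five community specifications spanning the realistic range of census
#' surfaces: window areas from under a square metre to over a hundred square
#' metres, specimen densities from a few to about a hundred per square
#' metre, per-taxon abundances from tens to over a thousand, and the full
#' set of generating processes, strain and erosion distortions. See the
#' package vignette for the rationale behind each scenario's parameters.
#'
#' @return Named list of [community_spec()]s.
#' @export
scenario_bank <- function() {
  sz <- function(m, s = 0.4) list(meanlog = log(m), sdlog = s)
  list(
    bed_b_like = community_spec(
      owin_rect(c(0, 14.4), c(0, 8)),
      list(taxon_spec("charniodiscus_like", "TC", 48,
                      list(sigma = 0.25, rho = 48 / 115.2 / 2.9), sz(0.04)),
           taxon_spec("primocandelabrum_like", "TC", 106,
                      list(sigma = 0.3, rho = 106 / 115.2 / 21.5), sz(0.05)),
           taxon_spec("charnia_like", "TC", 69,
                      list(sigma = 0.3, rho = 69 / 115.2 / 12), sz(0.06)),
           taxon_spec("holdfast_discs", "CSR", 250, size_distribution = sz(0.03),
                      group_class = "bin_group"),
           taxon_spec("ivesheadiomorphs", "CSR", 200,
                      size_distribution = sz(0.08),
                      group_class = "taphomorph"),
           taxon_spec("hiemalora_like", "CSR", 80,
                      size_distribution = sz(0.03),
                      group_class = "organ_taxon")),
      erosion = list(kind = "gradient_x", b = -0.15),
      surface_name = "bed_b_like"),
    e_surface_like = community_spec(
      owin_rect(c(0, 10.7), c(0, 8)),
      list(taxon_spec("fractofusus_like", "TC", 1137,
                      list(sigma = 0.12, rho = 1137 / 85.6 / 11.8), sz(0.06)),
           taxon_spec("feather_duster_like", "TC", 272,
                      list(sigma = 0.15, rho = 272 / 85.6 / 5.6), sz(0.05)),
           taxon_spec("charniodiscus_like", "DTC", 326,
                      list(sigma = 0.5, rho = 0.35, small_sigma = 0.08,
                           small_mu = 2.1), sz(0.05)),
           taxon_spec("beothukis_like", "HP", 76,
                      list(covariate = "gradient_x", b = 0.35), sz(0.05)),
           taxon_spec("thectardis_like", "CSR", 39, size_distribution = sz(0.05)),
           taxon_spec("bradgatia_like", "CSR", 34, size_distribution = sz(0.06)),
           taxon_spec("ivesheadiomorphs", "CSR", 700,
                      size_distribution = sz(0.08),
                      group_class = "taphomorph")),
      surface_name = "e_surface_like"),
    bristy_cove_like = community_spec(
      owin_rect(c(0, 0.9), c(0, 0.9)),
      list(taxon_spec("fractofusus_like", "CSR", 76,
                      size_distribution = sz(0.01, 0.3)),
           taxon_spec("holdfast_discs", "CSR", 30,
                      size_distribution = sz(0.008, 0.3),
                      group_class = "bin_group")),
      surface_name = "bristy_cove_like"),
    st_shotts_like = community_spec(
      owin_rect(c(0, 10.2), c(0, 5)),
      list(taxon_spec("aspidella_like", "TC", 170,
                      list(sigma = 0.3, rho = 170 / 51 / 9.2), sz(0.03)),
           taxon_spec("charnia_like", "TC", 54,
                      list(sigma = 0.35, rho = 54 / 51 / 11), sz(0.06)),
           taxon_spec("holdfast_discs", "CSR", 150,
                      size_distribution = sz(0.03),
                      group_class = "bin_group"),
           taxon_spec("ivesheadiomorphs", "CSR", 100,
                      size_distribution = sz(0.08),
                      group_class = "taphomorph")),
      erosion = list(kind = "gradient_y", b = -0.3),
      surface_name = "st_shotts_like"),
    spaniards_bay_like = community_spec(
      owin_rect(c(0, 5.86), c(0, 2.8)),
      list(taxon_spec("beothukis_like", "HP", 18,
                      list(covariate = "gradient_x", b = 0.5), sz(0.08)),
           taxon_spec("trepassia_like", "ITC", 33,
                      list(sigma = 0.1, rho = 0.6,
                           surface = list(covariate = "gradient_x", b = 0.5)),
                      sz(0.08)),
           taxon_spec("avalofractus_like", "CSR", 18,
                      size_distribution = sz(0.04))),
      strain = strain_estimate(1.35, pi / 6),
      surface_name = "spaniards_bay_like")
  )
}

#' Read a community specification from YAML
#'
#' The schema mirrors [community_spec()]: `window: {xrange, yrange}` (or
#' `vertices`), `taxa:` a list of `{taxon, process, target_n, params,
#' size_distribution, group_class}`, optional `strain: {ratio, orientation}`
#' and `erosion: {kind, b, anchor}`.
#'
#' @param path YAML file.
#' @export
read_community_spec <- function(path) {
  y <- yaml::read_yaml(path)
  window <- if (!is.null(y$window$vertices)) {
    v <- do.call(rbind, y$window$vertices)
    owin_poly(v[, 1], v[, 2])
  } else owin_rect(unlist(y$window$xrange), unlist(y$window$yrange))
  taxa <- lapply(y$taxa, function(t)
    taxon_spec(t$taxon, t$process, t$target_n, t$params %||% list(),
               t$size_distribution %||% list(meanlog = log(0.05), sdlog = 0.4),
               t$group_class %||% "described_taxon"))
  strain <- if (!is.null(y$strain))
    strain_estimate(y$strain$ratio, y$strain$orientation %||% 0)
  community_spec(window, taxa, strain = strain, erosion = y$erosion,
                 surface_name = y$surface_name %||% "scenario",
                 seed = y$seed)
}
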