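# Niche vs neutral assignment. Univariate: complete spatial randomness and
# dispersal-limitation clustering (TC, DTC) are neutral; habitat association
# (HP), clustering with habitat filtering (ITC) and spatial segregation are
# niche. Bivariate: independence is neutral; any non-independence
# (aggregation = facilitation/shared habitat, segregation = competition) is
# niche.

PROCESS_MAP <- c(CSR = "neutral", TC = "neutral", DTC = "neutral",
                 HP = "niche", ITC = "niche", SEGREGATED = "niche")

#' Classify a univariate model fit as niche or neutral
#'
#' @param fit an `sppa_fit` from [fit_protocol()].
#' @return A `classification_result` with `subject`, `process`
#'   (`"neutral"` or `"niche"`), `best_model` and a machine-readable
#'   `rationale` rule id.
#' @export
classify_univariate <- function(fit) {
  stopifnot(inherits(fit, "sppa_fit"))
  process <- unname(PROCESS_MAP[fit$kind])
  if (is.na(process)) stop("unknown model kind: ", fit$kind)
  structure(list(subject = attr(fit, "taxon") %||% "taxon",
                 best_model = fit, model_kind = fit$kind, process = process,
                 rationale = paste0("univariate:", fit$kind, "->", process)),
            class = "classification_result")
}

#' Classify a bivariate independence test as niche or neutral
#'
#' @param result a `bivariate_result` from [toroidal_shift_test()].
#' @export
classify_bivariate <- function(result) {
  stopifnot(inherits(result, "bivariate_result"))
  process <- if (result$independent) "neutral" else "niche"
  structure(list(subject = paste(result$taxon_a, result$taxon_b, sep = "-"),
                 best_model = result,
                 model_kind = if (result$independent) "independent"
                              else result$direction,
                 process = process,
                 rationale = paste0("bivariate:",
                                    if (result$independent) "independent"
                                    else result$direction, "->", process)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<%s: %s (%s)>\n", x$subject, x$process, x$model_kind))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize the classifications of one surface
#'
#' @param results list of `classification_result`s.
#' @param surface surface name.
#' @return A `surface_summary` with per-model-kind counts and proportions
#'   and niche/neutral tallies, split by univariate and bivariate subjects.
#' @export
summarize_surface <- function(results, surface = "surface") {
  stopifnot(length(results) > 0)
  kinds <- vapply(results, function(r) r$model_kind, character(1))
  procs <- vapply(results, function(r) r$process, character(1))
  uni <- vapply(results, function(r) inherits(r$best_model, "sppa_fit"),
                logical(1))
  kt <- table(kinds[uni])
  structure(list(surface = surface,
                 model_counts = kt,
                 model_proportions = if (sum(kt)) kt / sum(kt) else kt,
                 univariate_neutral = sum(procs[uni] == "neutral"),
                 univariate_niche = sum(procs[uni] == "niche"),
                 bivariate_neutral = sum(procs[!uni] == "neutral"),
                 bivariate_niche = sum(procs[!uni] == "niche"),
                 n_subjects = length(results)),
            class = "surface_summary")
}

#' @export
print.surface_summary <- function(x, ...) {
  cat(sprintf("<surface '%s': univariate %d neutral / %d niche; bivariate %d neutral / %d niche>\n",
              x$surface, x$univariate_neutral, x$univariate_niche,
              x$bivariate_neutral, x$bivariate_niche))
  if (length(x$model_counts)) print(x$model_counts)
  invisible(x)
}
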