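#' @keywords internal
"_PACKAGE"

#' @useDynLib sppa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimize runif rnorm rpois median approx rlnorm
#' @importFrom stats setNames quantile sd ks.test
#' @importFrom utils read.csv write.csv head
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
# A NULL seed leaves the ambient stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
child_seeds <- function(seed, n, salt = 0L) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed + salt, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

stop_sppa <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "sppa_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Accept a point pattern as matrix / data.frame / list with x, y.
as_coords <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) >= 2)
    out <- cbind(x = as.numeric(p[, 1]), y = as.numeric(p[, 2]))
  } else if (is.data.frame(p) || is.list(p)) {
    stopifnot(!is.null(p$x), !is.null(p$y))
    out <- cbind(x = as.numeric(p$x), y = as.numeric(p$y))
  } else {
    stop("cannot interpret 'p' as planar coordinates")
  }
  if (any(!is.finite(out))) stop("non-finite coordinates")
  out
}
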