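# Internal helpers shared across modules.

# Classed error/warning so callers can distinguish failure modes.
nlh_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "nlhebb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

nlh_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "nlhebb_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

l2_norm <- function(x) sqrt(sum(x * x))

unit_vec <- function(x) {
  n <- l2_norm(x)
  if (!is.finite(n) || n == 0) {
    nlh_stop("cannot normalize a zero-norm or non-finite vector", "nlhebb_normalization_error")
  }
  x / n
}

#' Deterministically derive a stage seed from a global seed
#'
#' A splitmix-style integer mixer: the global seed and a stage label are
#' hashed together so that independent pipeline stages get decoupled,
#' reproducible seeds, all below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage label (or integer counter).
#' @return a single integer in `[0, 2^31)`.
#' @export
spawn_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.finite(seed))
  chars <- utf8ToInt(paste0("s", as.character(stage)))
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (ch in chars) {
    # 69069 is a classic Marsaglia multiplier; arithmetic kept in doubles,
    # reduced mod 2^31-1 so it stays exactly representable.
    h <- (h * 69069 + ch * 2654435.0 + 1) %% 2147483647
  }
  as.integer(floor(h))
}

# Run an expression with a locally seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Numerically stable log(1 + exp(z)) and log(cosh(z)).
softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
logcosh <- function(z) abs(z) + log1p(exp(-2 * abs(z))) - log(2)

# Piecewise adaptive quadrature: integrate() loses accuracy silently when the
# integrand has interior kinks, so we split at the supplied knot points.
piecewise_integrate <- function(f, lower, upper, knots = numeric(0), abs_tol = 1e-10) {
  pts <- sort(unique(c(lower, upper, knots[knots > lower & knots < upper])))
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    res <- tryCatch(
      stats::integrate(f, pts[i], pts[i + 1L],
                       abs.tol = abs_tol / max(1L, length(pts) - 1L),
                       rel.tol = .Machine$double.eps^0.5, subdivisions = 500L),
      error = function(e) nlh_stop(
        paste0("quadrature failed on [", pts[i], ", ", pts[i + 1L], "]: ",
               conditionMessage(e)),
        "nlhebb_numerical_error")
    )
    total <- total + res$value
  }
  total
}
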