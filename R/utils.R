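#' @keywords internal
"_PACKAGE"

#' @importFrom stats AIC anova approx as.formula chisq.test coef complete.cases
#'   kruskal.test median pnorm predict quantile rbinom rexp rgamma rnorm runif
#'   sd setNames shapiro.test var vcov
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a component seed from a master seed; keeps results < 2^31 so they
# remain valid R integer seeds.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 9973) %% 2147483629L)
}

# Run `expr` under its own RNG stream without disturbing the caller's RNG.
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, offset))
  expr
}

stop_thermoglyc <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "thermoglyc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Evaluate a polynomial given coefficients c0, c1, c2, ... (ascending powers).
polyval <- function(coefs, t) {
  out <- rep(0, length(t))
  for (i in seq_along(coefs)) out <- out + coefs[[i]] * t^(i - 1)
  out
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
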