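#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state existed before, so that library calls never leak
#' randomness into (or out of) the caller's session.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# full round-trip precision for text serialization
fmt_full <- function(x) sprintf("%.17g", x)

# piecewise-linear profile lookup; nodes is a 2-column matrix (t, value),
# constant extrapolation beyond the end nodes
interp_profile <- function(t, nodes) {
  stats::approx(nodes[, 1], nodes[, 2], xout = t, rule = 2)$y
}

assert_side <- function(side) {
  if (!is.character(side) || length(side) != 1L || !side %in% c("left", "right"))
    stop("`side` must be \"left\" or \"right\"", call. = FALSE)
  side
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  as.numeric(x)
}
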