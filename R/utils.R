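# Internal numerical helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published summary tables round
#' half up, so percentages are formatted with this rule instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# log(sum(exp(x))) without overflow; -Inf for empty input
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when a == b
logdiffexp <- function(a, b) {
  if (b > a + 1e-12) stop("logdiffexp requires a >= b")
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  has <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-component substream of a global seed, kept inside the
# 32-bit integer range R's RNG accepts.
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483647)
}

# Two-sided normal p-value, clamped away from exact zero so downstream
# log-scale work stays finite.
p_two_sided <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), 1e-300)
}

# Two-sided t p-value with df degrees of freedom.
p_two_sided_t <- function(t, df) {
  pmax(2 * stats::pt(-abs(t), df = df), 1e-300)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
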