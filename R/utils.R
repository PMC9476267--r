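#' @importFrom rlang .data %||%
#' @importFrom stats quantile rnorm runif rgamma median sd setNames
#' @importFrom utils head tail
NULL

# wrap an angle (radians) into (-pi, pi]
wrap_angle <- function(a) {
  w <- ((a + pi) %% (2 * pi)) - pi
  w[!is.na(w) & w == -pi] <- pi
  w
}

clip01 <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)

# deterministic 32-bit sub-seed for a (seed, key) pair; a stable polynomial
# string hash so that adding a cow never perturbs the streams of others
sub_seed <- function(seed, key) {
  codes <- utf8ToInt(as.character(key))
  h <- 0
  m <- 2147480009 # prime < 2^31
  for (cc in codes) h <- (h * 31 + cc) %% m
  as.integer((h + (seed %% m) * 2654435761) %% m)
}

# integer allocation of n among categories by largest remainder (Hamilton)
largest_remainder <- function(n, freqs) {
  stopifnot(abs(sum(freqs) - 1) < 1e-9)
  raw <- n * freqs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(freqs))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
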