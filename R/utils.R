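# internal helpers shared across modules

M2YD <- 1.0936133  # metres -> yards

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so stochastic operations never leak global state.
#' @noRd
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a well-separated child seed, kept inside 32-bit integer range
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1299721) %% 2147483399) + 1L
}

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds away from zero), used when
#' reporting integer animal counts.
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

# clip values into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# convert factors used by the density model to canonical factor coding
canonicalFactors <- function(df) {
  if ("Season" %in% names(df))
    df$Season <- factor(as.character(df$Season),
                        levels = c("Fall/Winter", "Spring/Summer"))
  if ("River" %in% names(df))
    df$River <- factor(as.character(df$River), levels = c("A", "B", "C"))
  if ("DevelopedSL" %in% names(df))
    df$DevelopedSL <- factor(as.character(as.integer(as.character(
      df$DevelopedSL))), levels = c("0", "1"))
  df
}
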