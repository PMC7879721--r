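#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for all printed percentages in this package (base R's
#' [round()] rounds half to even, which disagrees on e.g. 0.5).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_out(0.5)   # 1, not 0
#' round_half_out(18.456, 1)
round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count ratio at a fixed printed precision
#'
#' @param n Numerator count(s).
#' @param total Denominator count(s); must be positive.
#' @param digits Decimal places kept, rounding half away from zero.
#' @return `100 * n / total`, rounded.
#' @export
#' @examples
#' percent(1, 3, 4)  # 33.3333
percent <- function(n, total, digits = 0) {
  if (any(total <= 0)) stop("percentage denominator must be positive")
  round_half_out(100 * n / total, digits)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-component sub-seed derived from a master seed, so that
# e.g. enlarging the corpus never perturbs the assessment draws. Kept below
# 2^31 - 1 (R seeds are 32-bit integers).
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 2654435)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

# Parse a date window given as Date[2], character[2], or "A:B" / "A/B".
as_window <- function(w) {
  if (is.character(w) && length(w) == 1) w <- strsplit(w, "[:/]")[[1]]
  if (length(w) != 2) stop("a date window needs exactly two dates")
  w <- as_date(w)
  if (any(is.na(w)) || w[1] > w[2]) stop("invalid date window: ", paste(w, collapse = " .. "))
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
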