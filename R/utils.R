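#' @keywords internal
"_PACKAGE"

# Perch types that feed the interaction (clumping) networks.
PERCH_TYPES <- c("social_perch", "copulation_perch")
LOCATION_TYPES <- c(PERCH_TYPES, "feeder")
NET_TYPES <- c("interaction", "association")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' All stochastic stages (covariates, membership, latent effects, detection
#' emission, masking, metric correction, bootstrap) draw their seed from one
#' master integer through this function, so a single `seed` governs the whole
#' study while stages stay decoupled.
#'
#' @param seed master integer seed.
#' @param label character tag naming the sub-stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  # rolling multiplicative hash; every step stays far below 2^53 so the
  # double-precision modular arithmetic is exact
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(label)) h <- (h * 69069 + code) %% 2147483647
  h <- (h * 69069 + 1) %% 2147483647
  as.integer(h %% 2147483629 + 1)
}

# Run `expr` under a local RNG seed without disturbing the caller's stream.
# A NULL seed uses (and advances) the global stream.
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

stop_cn <- function(...) stop(sprintf(...), call. = FALSE)

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_cn("%s is missing required column(s): %s", what,
            paste(miss, collapse = ", "))
}

is_iso_date <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}$", x) & !is.na(as.Date(x, optional = TRUE))
}
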