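#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n row_number desc across all_of
#' @importFrom stats fft mvfft rbinom runif rnorm rgeom median pf
#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Derive a stage seed from a run seed; keeps every derived seed < 2^31.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

db_to_amp <- function(db) 10^(db / 20)
amp_to_db <- function(a) 20 * log10(pmax(a, .Machine$double.xmin))
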