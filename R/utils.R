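## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## DNA complement used for strand translation during harmonization.
.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.complement <- function(x) unname(.COMPLEMENT[x])

.is_palindromic <- function(ea, oa) .complement(ea) == oa

## Two-sided normal p-value, clamped away from exact zero so the
## p-in-(0,1] invariant survives extreme z scores.
.pval_z <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)

.pval_t <- function(t, df) pmax(2 * stats::pt(-abs(t), df = df),
                                .Machine$double.xmin)

## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards. All stochastic routines in
## the package take an explicit seed and route through here.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

## Deterministic sub-seed derivation (Lehmer step) so one user seed can
## drive several independent stochastic stages; stays below 2^31 - 1.
derive_seed <- function(seed, offset = 1L) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483647)
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
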