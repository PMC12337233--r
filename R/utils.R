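# Internal helpers shared across the package.

#' Sentinel label for an abstaining base predictor
#'
#' A base model that fails to produce a usable option label (for example an
#' unparseable free-text answer) is recorded with this sentinel. An abstain
#' counts as an incorrect answer when model error rates are computed and
#' contributes no score to any option during voting.
#'
#' @return The abstain sentinel string, `"__ABSTAIN__"`.
#' @export
#' @examples
#' abstain_label()
abstain_label <- function() "__ABSTAIN__"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic entry points route through this
# so that a given seed yields byte-identical results without clobbering the
# user's random stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

# Derive a secondary 31-bit seed from a base seed and a stream index, so that
# independent stochastic sub-steps get distinct but reproducible streams.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream)) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
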