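## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

warn_ <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x == floor(x))

## Deterministic substream seeding: every file type of the simulator draws
## from its own named substream so adding one output never perturbs another.
.substreams <- c(
  genome = 11L, hits = 23L, methylome = 37L, sequences = 41L,
  expression = 53L, population = 67L, orthogroups = 71L, tes = 83L,
  classes = 89L
)

set_substream <- function(seed, stream) {
  off <- .substreams[[stream]]
  if (is.null(off)) stop_("unknown random substream '%s'", stream)
  set.seed(((as.integer(seed) %% 1000003L) * 97L + off) %% 2147483647L)
  invisible(NULL)
}

## 0-based half-open interval overlap test, vectorized on the first interval.
overlaps0 <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
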