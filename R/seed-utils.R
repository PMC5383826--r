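# Deterministic seed derivation: one root seed fanned out to child streams by
# a stable string hash, so adding a participant or stage never reshuffles the
# randomness of the others.

#' Derive a child seed from a root seed and a purpose label
#'
#' Uses a 32-bit FNV-1a hash of `"<root>|<label>"`, folded into the valid
#' range for [set.seed()]. Stable across platforms and R sessions.
#'
#' @param root Integer root seed.
#' @param label Character purpose label (e.g. `"participant-7"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "bank")
derive_seed <- function(root, label) {
  stopifnot(length(root) == 1L, is.finite(root), length(label) == 1L)
  bytes <- utf8ToInt(sprintf("%d|%s", as.integer(root), as.character(label)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 32-bit FNV prime multiply, kept in double precision below 2^53
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

# Run expr with a locally-set RNG state; global stream untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
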