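# Internal helpers shared across modules.

kc_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "kc_error", "error", "condition")))
}

# Deterministic per-run seed derivation from a master seed. Seeds stay below
# 2^31 - 1 so they are valid R integer seeds.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 0L)
  if (n == 0L) return(integer(0))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# n x k community indicator matrix from an integer membership vector.
membership_matrix <- function(comm, k = max(comm)) {
  M <- matrix(0, length(comm), k)
  M[cbind(seq_along(comm), comm)] <- 1
  M
}

# Relabel a membership vector to consecutive integers in order of first
# occurrence (canonical form; partition equality is up to relabeling).
canonical_labels <- function(comm) {
  match(comm, unique(comm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
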