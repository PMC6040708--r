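# Internal helpers shared across modules.

# Deterministic child seed derivation. A single run seed fans out into
# per-area / per-stage streams; values stay below 2^31 - 1 so they are valid
# R integer seeds.
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + 7919 * index) %% 2147483629)
}

# canonical unordered LLE-type combination label
lle_combo_label <- function(type_a, type_b) {
  a <- pmin(type_a, type_b)
  b <- pmax(type_a, type_b)
  # alphabetical order puts ditch first; report margin-first as in the field
  ifelse(a == "margin" & b == "margin", "margin-margin",
    ifelse(a == "ditch" & b == "ditch", "ditch-ditch", "margin-ditch")
  )
}

lle_combo_levels <- c("margin-margin", "margin-ditch", "ditch-ditch")

`%0%` <- function(x, default) if (length(x) == 0L || all(is.na(x))) default else x
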