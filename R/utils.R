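# Seed derivation: a Lehmer-style mix of the master seed with a string label
# and an optional index, so each pipeline stage / repeat gets an independent,
# reproducible sub-seed and adding stages never perturbs the others.
# Result always lies in [1, 2^31 - 2], safe for set.seed().
derive_seed <- function(master, label, index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% m
  s <- (((abs(master) %% m) * 48271) %% m + h + abs(index)) %% m
  as.integer(s %% (m - 1) + 1)
}

# Tiny FNV-1a string hash (hex), used to fingerprint configurations in the
# pipeline manifest without a digest dependency.
fnv1a <- function(x) {
  h <- 2166136261
  for (ch in utf8ToInt(paste(x, collapse = ""))) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_scalar_prob <- function(x, field, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) stop_cfg(field, if (open) "must be in (0, 1)" else "must be in [0, 1]")
  x
}
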