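# Internal helpers shared across modules.

# Classed errors so callers can distinguish failure modes programmatically.
abort_ms <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("moundscan_", class), "moundscan_error")))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

# FNV-1a hash of a character scalar; used to fingerprint configurations.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0x811c9dc5
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # split so intermediates stay inside the 2^53 exact-integer range
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_fingerprint <- function(config) {
  fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE))
}
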