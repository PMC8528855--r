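# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All user-facing stochastic operations funnel
# through this so a single integer seed pins the whole pipeline.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive `n` independent sub-stream seeds (< 2^31) from one root seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stopf("'%s' must be a single integer >= %d (got %s)", name, min,
          paste(x, collapse = ","))
  }
  as.integer(x)
}

# FNV-1a 32-bit hash of a character scalar; used for provenance records
# (no external digest dependency needed for a fingerprint).
fnv1a32 <- function(s) {
  fnv1a32_impl(utf8ToInt(enc2utf8(s)))
}

fnv1a32_impl <- function(bytes) {
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  # h may exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor on doubles holding 32-bit unsigned values
bitwXor_dbl <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

# Deterministic numeric formatting for TSV output. %.12g is idempotent
# under write -> parse -> write, which gives exact round-trip bytes.
fmt_num <- function(x) sprintf("%.12g", x)
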