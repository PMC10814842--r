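# Internal validation helpers. Every user-facing constructor funnels through
# these so error messages always name the offending field.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, positive = FALSE, nonneg = FALSE,
                             min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (positive && x <= 0) stop_field(field, "must be > 0")
  if (nonneg && x < 0) stop_field(field, "must be >= 0")
  if (!is.null(min) && x < min) stop_field(field, sprintf("must be >= %g", min))
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop_field(field, "must be a single whole number")
  if (x < min) stop_field(field, sprintf("must be >= %d", min))
  invisible(as.integer(x))
}

# Restore the caller's RNG state on exit so generator calls do not perturb
# the global random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# sigma of a lognormal with a given coefficient of variation
lognormal_sigma_from_cv <- function(cv) sqrt(log(1 + cv^2))

# FNV-1a 32-bit hash of a character string, returned as 8 hex digits.
# Used only to stamp a config fingerprint into output provenance headers.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256                       # xor touches only the low byte
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536                      # 32-bit modular multiply without
    hi <- (h - lo) / 65536                # leaving double precision
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  hi16 <- (h - h %% 65536) / 65536
  sprintf("%04x%04x", as.integer(hi16), as.integer(h %% 65536))
}
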