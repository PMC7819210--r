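# small shared helpers (validation, hashing, seeds)

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_probability <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config("'%s' must be a probability in [0, 1] (got %s)",
                name, paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_range <- function(r, name) {
  if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
    stop_config("'%s' must be an ordered pair (low <= high), got (%s)",
                name, paste(format(r), collapse = ", "))
  }
  invisible(r)
}

# FNV-1a 32-bit hash of a character string; used to derive per-patient RNG
# substreams from patient ids so cohort order cannot change results, and to
# fingerprint configurations in run manifests. Pure integer arithmetic kept
# inside 2^31 via modular reduction.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    # 32-bit multiply by the FNV prime 16777619, done in doubles mod 2^32
    h <- (h * 16777619) %% 2^32
  }
  as.integer(h %% 2^31)
}

# deterministic per-patient seed below 2^31
patient_seed <- function(master_seed, patient_id) {
  (as.integer(master_seed) %% 2^31 + fnv1a32(as.character(patient_id))) %% 2147483629L
}

# stable column name for a willingness-to-pay threshold (no scientific
# notation, survives CSV/JSON round trips)
thr_col <- function(threshold) {
  paste0("prop_ce_", format(threshold, scientific = FALSE, trim = TRUE))
}

config_hash <- function(object) {
  payload <- jsonlite::toJSON(object, auto_unbox = TRUE, digits = NA,
                              force = TRUE)
  sprintf("%08x", fnv1a32(as.character(payload)))
}
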