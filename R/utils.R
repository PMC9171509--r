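# Internal helpers: validation, exact integer arithmetic, provenance.

abort_la <- function(msg, class) {
  stop(structure(class = c(class, "lungalloc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, min = -Inf, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x)) || x < min)
    abort_la(sprintf("'%s' must be a single number >= %s", name, min),
             "validation_error")
  invisible(x)
}

# ---- exact big-integer arithmetic (decimal, base 1e4 limbs) ----------------
# Needed for exact search-space counts like (9+1)^183; no gmp on the stack.

big_from_int <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0L)
  limbs <- integer(0)
  while (x > 0) { limbs <- c(limbs, as.integer(x %% 10000L)); x <- x %/% 10000L }
  limbs
}

big_mul <- function(a, b) {
  # a, b: little-endian integer vectors of base-1e4 limbs
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    res[i:(i + length(b) - 1L)] <- res[i:(i + length(b) - 1L)] + a[i] * b
  }
  carry <- 0
  for (i in seq_along(res)) {
    v <- res[i] + carry
    res[i] <- v %% 10000
    carry <- v %/% 10000
  }
  while (carry > 0) { res <- c(res, carry %% 10000); carry <- carry %/% 10000 }
  while (length(res) > 1L && res[length(res)] == 0) res <- res[-length(res)]
  as.integer(res)
}

big_pow <- function(base, exp) {
  out <- big_from_int(1)
  b <- big_from_int(base)
  while (exp > 0) {
    if (exp %% 2L == 1L) out <- big_mul(out, b)
    b <- big_mul(b, b)
    exp <- exp %/% 2L
  }
  out
}

big_to_string <- function(limbs) {
  n <- length(limbs)
  head <- as.character(limbs[n])
  rest <- if (n > 1L) sprintf("%04d", rev(limbs[-n])) else character(0)
  paste0(head, paste0(rest, collapse = ""))
}

# ---- provenance ------------------------------------------------------------

# FNV-1a 32-bit over a string; cheap config fingerprint (no digest pkg).
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261 # tracked as a double; kept < 2^32
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

provenance <- function(seed = NA, config = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE)
  list(tool = "lungalloc",
       version = as.character(utils::packageVersion("lungalloc")),
       seed = seed,
       config_hash = fnv1a32(as.character(cfg_json)))
}

provenance_comment <- function(seed = NA, config = list()) {
  p <- provenance(seed, config)
  sprintf("# lungalloc %s seed=%s config=%s", p$version, p$seed, p$config_hash)
}

write_csv_prov <- function(df, path, seed = NA, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_comment(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_prov <- function(path, ...) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}
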