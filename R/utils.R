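# internal helpers

# Deterministic per-task substream seed derived from a master seed; kept
# below 2^31 so it is always a valid integer seed.
.substreamSeed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 16807) %% 2147483629L + 1)
}

# integer FNV-1a hash of a string, for identity-keyed RNG substreams
.strHash <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  as.integer(h %% 2147483629)
}

# FNV-1a hash of a character scalar, for tagging outputs with their config.
.fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

.assertCountVector <- function(y) {
  if (!is.numeric(y) || length(y) < 1)
    stop("'y' must be a non-empty numeric vector of counts")
  if (anyNA(y) || any(!is.finite(y)))
    stop("counts must be finite and non-missing")
  if (any(y < 0) || any(y != floor(y)))
    stop("counts must be non-negative integers")
  invisible(TRUE)
}

.assertTwoGroups <- function(x) {
  if (!all(x %in% c(0, 1)))
    stop("'x' must be a 0/1 group indicator")
  if (sum(x == 0) < 2 || sum(x == 1) < 2)
    stop("need at least 2 samples in each group")
  invisible(TRUE)
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
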