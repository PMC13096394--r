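# internal helpers shared across modules

# collapse surrounding and internal whitespace runs; the gradation-matching
# normalization used everywhere a raw cell value meets a scale
.normalizeToken <- function(x) {
  x <- trimws(x)
  gsub("[[:space:]]+", " ", x)
}

# TRUE when every non-missing token parses as a number
.isNumericColumn <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(FALSE)
  !anyNA(suppressWarnings(as.numeric(x)))
}

# FNV-1a over a character rendering of the counts; cheap deterministic
# fingerprint tying a model to the frequency matrix it came from
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # multiply by the FNV prime 16777619 = 2^24 + 403, mod 2^32, staying
    # within double precision
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# population (divide-by-n) standard deviation over matrix rows
.rowPopSd <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowMeans((m - mu)^2))
}
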