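# internal helpers shared across modules

# half-open [lo, hi) bin index, 0-based; values exactly at the upper limit of
# the last bin are rejected upstream by coverage checks
bin_index <- function(x, lo, width) as.integer(floor((x - lo) / width))

# unnormalized DFT frequencies (cycles per um) for n samples at spacing dx
fft_freq <- function(n, dx) {
  (((seq_len(n) - 1L) + n %/% 2L) %% n - n %/% 2L) / (n * dx)
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("`%s` must be a finite number", name))
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_domain(sprintf("`%s` = %g is outside its valid range", name, x))
  invisible(x)
}

# group-sum `x` by integer key, returning (key, sum) in key order
rowsum_by_key <- function(x, key) {
  s <- rowsum(x, key, reorder = TRUE)
  list(key = as.numeric(rownames(s)), sum = s[, 1L])
}

# md5 digest of an arbitrary R object; uncompressed serialization so the
# digest is stable across sessions
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
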