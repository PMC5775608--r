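# Low-level DNA string helpers. Sequences are plain uppercase character
# scalars over {A,C,G,T,N}; coordinates are 0-based half-open throughout the
# package and converted to 1-based only at report boundaries.

DNA_BASES <- c("A", "C", "G", "T")

# byte -> 0:3 lookup (N and anything else -> NA)
.dna_code <- local({
  m <- rep(NA_integer_, 256L)
  m[utf8ToInt("A")] <- 0L
  m[utf8ToInt("C")] <- 1L
  m[utf8ToInt("G")] <- 2L
  m[utf8ToInt("T")] <- 3L
  m
})

encode_dna <- function(seq) {
  .dna_code[utf8ToInt(seq)]
}

decode_dna <- function(x) {
  chars <- rep("N", length(x))
  ok <- !is.na(x)
  chars[ok] <- DNA_BASES[x[ok] + 1L]
  paste(chars, collapse = "")
}

revcomp <- function(seq) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", seq))))
}

# substring in 0-based half-open coordinates (vectorised over positions)
slice0 <- function(seq, start0, end0) {
  substring(seq, start0 + 1L, end0)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fraction of identical characters between equal-length strings
string_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(NA_real_)
  mean(utf8ToInt(a) == utf8ToInt(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
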