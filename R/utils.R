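#' @importFrom stats runif rbinom uniroot setNames
#' @importFrom utils head tail write.table read.table
NULL

# Internal 2-bit-ish integer encoding; anything that is not A/C/G/T (notably N)
# encodes to 0 and never matches, so ambiguous bases count as mismatches.
.DNA_CODE <- local({
  x <- integer(256)
  x[utf8ToInt("A") + 1L] <- 1L; x[utf8ToInt("a") + 1L] <- 1L
  x[utf8ToInt("C") + 1L] <- 2L; x[utf8ToInt("c") + 1L] <- 2L
  x[utf8ToInt("G") + 1L] <- 3L; x[utf8ToInt("g") + 1L] <- 3L
  x[utf8ToInt("T") + 1L] <- 4L; x[utf8ToInt("t") + 1L] <- 4L
  x
})

encode_dna <- function(x) {
  if (length(x) != 1L) stop("encode_dna() expects a single sequence string")
  .DNA_CODE[utf8ToInt(x) + 1L]
}

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper (N and lower case preserved in kind).
#'
#' @param x a single DNA sequence string.
#' @return the reverse complement string.
#' @export
revcomp <- function(x) {
  chartr("ACGTacgtNn", "TGCAtgcaNn",
         vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
                USE.NAMES = FALSE))
}

#' Generate random DNA with a given GC content
#'
#' Bases are i.i.d.; the simplest null background under which long
#' high-identity similarity blocks cannot arise by chance.
#'
#' @param n length in bases.
#' @param gc GC fraction in \[0, 1\].
#' @return a DNA string of length \code{n}.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Mutate a sequence by i.i.d. substitutions at the given per-base rate.
# Returns list(seq, n_sub). Substituted bases always change identity.
mutate_seq <- function(x, rate) {
  if (rate <= 0) return(list(seq = x, n_sub = 0L))
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate & v %in% c("A", "C", "G", "T"))
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  list(seq = paste(v, collapse = ""), n_sub = length(hit))
}

substr_ <- function(x, start, end) {
  if (end < start) return("")
  substr(x, start, end)
}

# Longest exact common prefix length of two strings.
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  va <- utf8ToInt(substr(a, 1L, n)); vb <- utf8ToInt(substr(b, 1L, n))
  d <- which(va != vb)
  if (length(d) == 0L) n else d[1L] - 1L
}

# Longest exact common suffix length of two strings.
common_suffix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  va <- rev(utf8ToInt(a)); vb <- rev(utf8ToInt(b))
  d <- which(va[seq_len(n)] != vb[seq_len(n)])
  if (length(d) == 0L) n else d[1L] - 1L
}

# Rolling k-mer hashes (exact, base-4 polynomial in double precision; 4^k must
# stay below 2^53, i.e. k <= 26). Windows containing non-ACGT bases are NA.
kmer_hashes <- function(code, k) {
  n <- length(code)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  h <- numeric(m)
  bad <- cumsum(code == 0L)
  for (j in seq_len(k)) {
    h <- h + (code[j:(j + m - 1L)]) * 4^(k - j)
  }
  nbad <- bad[k:n] - c(0, bad)[1:m]
  h[nbad > 0] <- NA_real_
  h
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
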