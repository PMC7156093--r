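#' Find gapless high-identity similarity blocks between two sequences
#'
#' The dot-plot primitive used throughout the pipeline. A similarity block is
#' a gapless pairing of equal-length intervals on the two sequences such that
#' (i) every window of \code{min_length} bases inside the block meets
#' \code{min_identity} (the "95\% identity for a word size of 100" criterion
#' used to define breakpoints), (ii) the block as a whole meets
#' \code{min_identity}, and (iii) block ends are anchored: every terminal
#' sub-segment also meets \code{min_identity}, which pins borders to the last
#' exactly matching stretch instead of letting long blocks absorb random
#' trailing sequence. Indels between the sequences split blocks; breakpoints
#' downstream are called at block borders.
#'
#' Blocks are seeded by exact k-mer matches and extended along the diagonal.
#' For \code{min_identity} = 0.95 and \code{min_length} = 100 any qualifying
#' window must contain an exact 15-mer, so the default seed (k = 12) loses
#' nothing; for laxer settings the seed is shrunk automatically.
#'
#' @param seq_a,seq_b DNA sequence strings (or length-1 \code{DNAStringSet}).
#' @param min_length minimum reported block length in bases.
#' @param min_identity minimum identity fraction within a block; ambiguous
#'   bases (N) count as mismatches.
#' @param both_strands also search \code{seq_a} against the reverse
#'   complement of \code{seq_b}; such blocks carry orientation
#'   \code{"reverse"} with \code{b_start}/\code{b_end} on the original strand.
#' @param k seed k-mer size; \code{NULL} chooses a lossless size.
#' @return a data.frame with columns \code{a_start}, \code{a_end},
#'   \code{b_start}, \code{b_end} (1-based closed), \code{orientation}
#'   (\code{"forward"}/\code{"reverse"}), \code{length}, \code{identity},
#'   sorted by \code{a_start}. Zero rows is a valid result.
#' @export
find_similarity_blocks <- function(seq_a, seq_b, min_length = 100,
                                   min_identity = 0.95, both_strands = FALSE,
                                   k = NULL) {
  seq_a <- as_dna_string(seq_a)
  seq_b <- as_dna_string(seq_b)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    stopf("find_similarity_blocks(): sequences must be non-empty")
  if (is.null(k)) k <- choose_seed_k(min_length, min_identity)
  if (min_length < k)
    stopf("min_length (%d) must be >= seed size (%d)", min_length, k)
  code_a <- encode_dna(seq_a)
  fwd <- scan_strand(code_a, encode_dna(seq_b), min_length, min_identity, k)
  fwd$orientation <- rep("forward", nrow(fwd))
  out <- fwd
  if (both_strands) {
    nb <- nchar(seq_b)
    rev <- scan_strand(code_a, encode_dna(revcomp(seq_b)),
                       min_length, min_identity, k)
    if (nrow(rev)) {
      tmp <- nb - rev$b_end + 1L
      rev$b_end <- nb - rev$b_start + 1L
      rev$b_start <- tmp
      rev$orientation <- "reverse"
      out <- rbind(fwd, rev)
    }
  }
  out <- out[order(out$a_start, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("a_start", "a_end", "b_start", "b_end", "orientation",
          "length", "identity")]
}

#' Find repeats within a single sequence (self dot plot)
#'
#' Off-diagonal blocks of a sequence against itself reveal direct and
#' inverted repeats; the trivial self-match diagonal is excluded and each
#' repeat pair is reported once (with \code{a_start <= b_start}).
#'
#' @inheritParams find_similarity_blocks
#' @param seq DNA sequence string.
#' @return as \code{\link{find_similarity_blocks}}, with
#'   \code{a_interval != b_interval} for every row.
#' @export
self_repeat_blocks <- function(seq, min_length = 100, min_identity = 0.95,
                               k = NULL) {
  b <- find_similarity_blocks(seq, seq, min_length, min_identity,
                              both_strands = TRUE, k = k)
  keep <- !(b$a_start == b$b_start & b$a_end == b$b_end &
              b$orientation == "forward")
  b <- b[keep, , drop = FALSE]
  # one representative per mirror pair
  b <- b[b$a_start <= b$b_start, , drop = FALSE]
  if (nrow(b)) {
    dup <- duplicated(b[, c("a_start", "a_end", "b_start", "b_end",
                            "orientation")])
    b <- b[!dup, , drop = FALSE]
  }
  rownames(b) <- NULL
  b
}

as_dna_string <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stopf("expected a single sequence")
    return(toupper(x))
  }
  as.character(x)[1]
}

# Smallest number of mismatches that keeps a window of length L above t, and
# from it a seed size guaranteed to occur exactly in any qualifying window.
choose_seed_k <- function(min_length, min_identity, k_max = 12L) {
  mism <- floor(min_length * (1 - min_identity))
  guaranteed <- floor((min_length - mism) / (mism + 1))
  # below k = 8 the seed index degenerates (too many spurious diagonals);
  # detection then relies on copies carrying at least one exact 8-mer, which
  # any biologically plausible high-identity region does
  max(8L, min(k_max, guaranteed))
}

empty_blocks <- function() {
  data.frame(a_start = integer(0), a_end = integer(0),
             b_start = integer(0), b_end = integer(0),
             length = integer(0), identity = numeric(0))
}

# Seed, group by diagonal, extend. Returns forward-orientation blocks.
scan_strand <- function(code_a, code_b, min_length, min_identity, k,
                        max_occ = 256L) {
  na <- length(code_a); nb <- length(code_b)
  if (na < k || nb < k) return(empty_blocks())
  ha <- kmer_hashes(code_a, k)
  hb <- kmer_hashes(code_b, k)
  pa <- which(!is.na(ha)); pb <- which(!is.na(hb))
  if (!length(pa) || !length(pb)) return(empty_blocks())
  ta <- tabulate_hash(ha[pa]); tb <- tabulate_hash(hb[pb])
  # drop hyper-abundant seeds (low-complexity guard)
  keep_a <- ta$count[match(ha[pa], ta$hash)] <= max_occ
  keep_b <- tb$count[match(hb[pb], tb$hash)] <= max_occ
  pa <- pa[keep_a]; pb <- pb[keep_b]
  if (!length(pa) || !length(pb)) return(empty_blocks())
  shared <- intersect(ha[pa], hb[pb])
  if (!length(shared)) return(empty_blocks())
  pa <- pa[ha[pa] %in% shared]
  pb <- pb[hb[pb] %in% shared]
  ib <- split(pb, hb[pb])
  hits_a <- ha[pa]
  idx <- match(as.character(hits_a), names(ib))
  sel <- !is.na(idx)
  if (!any(sel)) return(empty_blocks())
  pa <- pa[sel]; idx <- idx[sel]
  bl <- ib[idx]
  a_pos <- rep.int(pa, lengths(bl))
  b_pos <- unlist(bl, use.names = FALSE)
  diag <- a_pos - b_pos
  by_diag <- split(a_pos, diag)
  res <- vector("list", 64L); nres <- 0L
  for (dn in names(by_diag)) {
    d <- as.integer(dn)
    seeds <- sort(unique(by_diag[[dn]]))
    blocks <- scan_diagonal(code_a, code_b, d, seeds, k,
                            min_length, min_identity)
    if (!is.null(blocks) && nrow(blocks)) {
      nres <- nres + 1L
      if (nres > length(res)) res <- c(res, vector("list", length(res)))
      res[[nres]] <- blocks
    }
  }
  if (nres == 0L) return(empty_blocks())
  do.call(rbind, res[seq_len(nres)])
}

tabulate_hash <- function(h) {
  tt <- table(h)
  list(hash = as.numeric(names(tt)), count = as.integer(tt))
}

# Merge sorted intervals given as parallel start/end vectors (base R; the
# hot path avoids S4 construction).
merge_sorted_intervals <- function(s, e) {
  if (length(s) <= 1L) return(cbind(s, e))
  new_run <- c(TRUE, s[-1] > cummax(e)[-length(e)] + 1L)
  grp <- cumsum(new_run)
  cbind(s[!duplicated(grp)],
        as.integer(tapply(e, grp, max)))
}

# All blocks on diagonal d (a = b + d), restricted to neighbourhoods of the
# seed positions (in a-coordinates). Windowed qualification + end trimming.
scan_diagonal <- function(code_a, code_b, d, seeds, k, L, t) {
  na <- length(code_a); nb <- length(code_b)
  lo_all <- max(1L, 1L + d); hi_all <- min(na, nb + d)
  if (hi_all - lo_all + 1L < L) return(NULL)
  margin <- L + k
  rng <- merge_sorted_intervals(pmax(lo_all, seeds - margin),
                                pmin(hi_all, seeds + k + margin))
  out <- NULL
  for (i in seq_len(nrow(rng))) {
    lo <- rng[i, 1]; hi <- rng[i, 2]
    repeat {
      if (hi - lo + 1L < L) break
      m <- (code_a[lo:hi] == code_b[(lo - d):(hi - d)]) & code_a[lo:hi] > 0L
      iv <- qualifying_intervals(m, L, t)
      if (is.null(iv)) break
      grow_lo <- iv[1, 1] <= 1L && lo > lo_all
      grow_hi <- iv[nrow(iv), 2] >= (hi - lo + 1L) && hi < hi_all
      if (!grow_lo && !grow_hi) {
        bl <- finalize_blocks(m, iv, lo, d, L, t)
        out <- rbind(out, bl)
        break
      }
      if (grow_lo) lo <- max(lo_all, lo - 4L * L)
      if (grow_hi) hi <- min(hi_all, hi + 4L * L)
    }
  }
  if (is.null(out) || !nrow(out)) return(NULL)
  out[!duplicated(out[, c("a_start", "a_end")]), , drop = FALSE]
}

# Merge qualifying min-length windows into candidate intervals (local coords).
qualifying_intervals <- function(m, L, t) {
  n <- length(m)
  if (n < L) return(NULL)
  cs <- c(0L, cumsum(m))
  ws <- cs[(L + 1L):(n + 1L)] - cs[1:(n - L + 1L)]
  q <- which(ws >= ceiling(t * L))
  if (!length(q)) return(NULL)
  merge_sorted_intervals(q, q + L - 1L)
}

finalize_blocks <- function(m, iv, lo, d, L, t) {
  res <- NULL
  for (r in seq_len(nrow(iv))) {
    res <- rbind(res, refine_block(m, iv[r, 1], iv[r, 2], L, t))
  }
  if (is.null(res)) return(NULL)
  data.frame(a_start = res[, 1] + lo - 1L, a_end = res[, 2] + lo - 1L,
             b_start = res[, 1] + lo - 1L - d, b_end = res[, 2] + lo - 1L - d,
             length = res[, 2] - res[, 1] + 1L, identity = res[, 3])
}

# Trim a candidate interval so every terminal sub-segment meets identity t;
# split recursively if the trimmed interval misses t overall.
refine_block <- function(m, s, e, L, t) {
  s <- trim_end(m, s, e, L, t, from_left = TRUE)
  if (is.na(s)) return(NULL)
  e <- trim_end(m, s, e, L, t, from_left = FALSE)
  if (is.na(e) || e - s + 1L < L) return(NULL)
  ident <- sum(m[s:e]) / (e - s + 1L)
  if (ident >= t) return(cbind(s, e, ident))
  # identity dip between qualifying windows: split at the weakest point
  seg <- m[s:e]
  cs <- c(0L, cumsum(seg))
  n <- length(seg)
  ws <- cs[(L + 1L):(n + 1L)] - cs[1:(n - L + 1L)]
  cut <- which.min(ws) + L %/% 2L
  left <- refine_block(m, s, s + cut - 1L, L, t)
  right <- refine_block(m, s + cut, e, L, t)
  rbind(left, right)
}

# Largest j such that every terminal sub-segment of length <= L meets t.
trim_end <- function(m, s, e, L, t, from_left) {
  repeat {
    if (e - s + 1L < L) return(NA_integer_)
    idx <- if (from_left) s:min(e, s + L - 1L) else e:max(s, e - L + 1L)
    seg <- m[idx]
    cum <- cumsum(seg)
    need <- ceiling(t * seq_along(seg))
    bad <- which(cum < need)
    if (!length(bad)) return(if (from_left) s else e)
    # move past the offending end base(s): advance to the next match
    if (from_left) {
      s <- s + 1L
      while (s <= e && !m[s]) s <- s + 1L
    } else {
      e <- e - 1L
      while (e >= s && !m[e]) e <- e - 1L
    }
  }
}
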