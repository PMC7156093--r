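#' Scored local alignment with expectation-style significance
#'
#' Wraps Smith-Waterman local alignment (via \pkg{Biostrings}) to produce
#' scored local hits between a query and a subject, on both strands. Hit
#' significance is an expectation statistic computed from the score by an
#' ungapped Karlin-Altschul formula, \eqn{E = K m n e^{-\lambda S}}, with
#' \eqn{\lambda} solved from the scoring scheme at uniform base frequencies
#' and the parameters recorded on the result. The statistic is a documented
#' approximation, not a BLAST replication; thresholds on it are configurable
#' score-equivalents.
#'
#' For long subjects the search is restricted to candidate regions found by
#' \code{\link{find_similarity_blocks}} at permissive settings, so a hit list
#' (not just the single best alignment) is returned.
#'
#' @param query,subject DNA sequence strings.
#' @param scoring list with \code{match} (> 0), \code{mismatch} (< 0),
#'   \code{gap_open}, \code{gap_extend} (penalties, <= 0).
#' @param both_strands search the reverse complement of the query as well.
#' @param min_identity,min_seed_length candidate-region settings for long
#'   subjects.
#' @return data.frame of hits sorted by descending score: \code{q_start},
#'   \code{q_end}, \code{s_start}, \code{s_end}, \code{strand},
#'   \code{score}, \code{identity}, \code{evalue}. Attributes
#'   \code{scoring} and \code{ka_params} record the parameters used.
#' @export
local_align <- function(query, subject,
                        scoring = list(match = 1, mismatch = -2,
                                       gap_open = -5, gap_extend = -2),
                        both_strands = TRUE,
                        min_identity = 0.8, min_seed_length = 30) {
  query <- as_dna_string(query); subject <- as_dna_string(subject)
  if (scoring$match <= 0)
    stopf("degenerate scoring: match score must be positive")
  if (scoring$mismatch >= 0)
    stopf("degenerate scoring: mismatch score must be negative")
  ka <- karlin_altschul_params(scoring$match, scoring$mismatch)
  strands <- if (both_strands) c("+", "-") else "+"
  hits <- NULL
  for (st in strands) {
    q <- if (st == "+") query else revcomp(query)
    h <- align_one_strand(q, subject, scoring)
    if (!is.null(h) && nrow(h)) {
      if (st == "-") {
        nq <- nchar(query)
        tmp <- nq - h$q_end + 1L
        h$q_end <- nq - h$q_start + 1L
        h$q_start <- tmp
      }
      h$strand <- st
      hits <- rbind(hits, h)
    }
  }
  if (is.null(hits) || !nrow(hits)) {
    hits <- data.frame(q_start = integer(0), q_end = integer(0),
                       s_start = integer(0), s_end = integer(0),
                       strand = character(0), score = numeric(0),
                       identity = numeric(0), evalue = numeric(0))
  } else {
    hits$evalue <- ka$K * nchar(query) * nchar(subject) *
      exp(-ka$lambda * hits$score)
    hits <- hits[order(-hits$score), , drop = FALSE]
    rownames(hits) <- NULL
    hits <- hits[, c("q_start", "q_end", "s_start", "s_end", "strand",
                     "score", "identity", "evalue")]
  }
  attr(hits, "scoring") <- scoring
  attr(hits, "ka_params") <- ka
  hits
}

# Ungapped Karlin-Altschul lambda for a match/mismatch scheme at uniform base
# frequencies: sum_ij p_i p_j exp(lambda * s_ij) = 1. K defaults to 0.1.
karlin_altschul_params <- function(match, mismatch, K = 0.1) {
  f <- function(lam) 0.25 * exp(lam * match) + 0.75 * exp(lam * mismatch) - 1
  lambda <- uniroot(f, c(1e-6, 10))$root
  list(lambda = lambda, K = K)
}

align_one_strand <- function(q, s, scoring) {
  regions <- if (nchar(s) > 100000L) {
    b <- find_similarity_blocks(q, s, min_length = 30, min_identity = 0.8,
                                k = 11)
    if (!nrow(b)) return(NULL)
    pad <- nchar(q)
    iv <- IRanges::reduce(IRanges::IRanges(pmax(1L, b$b_start - pad),
                                           pmin(nchar(s), b$b_end + pad)))
    cbind(IRanges::start(iv), IRanges::end(iv))
  } else {
    cbind(1L, nchar(s))
  }
  out <- NULL
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  for (r in seq_len(nrow(regions))) {
    sub <- substr(s, regions[r, 1], regions[r, 2])
    al <- Biostrings::pairwiseAlignment(
      pattern = q, subject = sub, type = "local",
      substitutionMatrix = mat,
      gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
    sc <- Biostrings::score(al)
    if (sc <= 0) next
    pr <- al@pattern@range
    sr <- al@subject@range
    nmatch <- Biostrings::nmatch(al)
    alen <- nmatch + Biostrings::nmismatch(al)
    out <- rbind(out, data.frame(
      q_start = IRanges::start(pr), q_end = IRanges::end(pr),
      s_start = IRanges::start(sr) + regions[r, 1] - 1L,
      s_end = IRanges::end(sr) + regions[r, 1] - 1L,
      score = sc, identity = if (alen > 0) nmatch / alen else 0))
  }
  out
}
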