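#' Retrieve TE insertions matching a consensus
#'
#' Homology-based retrieval of element copies from a genome, in the style of
#' member-retrieval tools: similarity blocks against the consensus are
#' chained per locus (best-scoring chain per locus, merged across the small
#' gaps that substitutions introduce), each accepted locus is reported once
#' with its flanking sequences, and the copy is structurally classified as
#' full length, truncated, or solo LTR. Significance is the ungapped
#' Karlin-Altschul expectation of the best block score; the default cutoff
#' (1e-3) is deliberately permissive, mirroring a lenient retrieval e-value.
#'
#' @param genome named character vector of chromosome sequences (or a file
#'   read with \code{\link{read_fasta}}).
#' @param consensus a \code{\link{te_consensus}}.
#' @param significance_cutoff expectation cutoff for accepting a locus.
#' @param end_mismatch_tolerance boundary tolerance in bases: full-length
#'   calls must reach within this distance of both consensus ends.
#' @param flank flanking bases captured on each side (shorter near contig
#'   ends, flagged via \code{flank_complete}).
#' @param min_identity,min_block block thresholds used for the search
#'   (permissive defaults tuned for up to ~10\% element divergence).
#' @return data.frame with one row per insertion: \code{id},
#'   \code{chromosome}, \code{start}, \code{end}, \code{strand},
#'   \code{identity_to_consensus}, \code{structure}, \code{consensus_cov},
#'   \code{cov_start}, \code{cov_end}, \code{evalue}, \code{flank5},
#'   \code{flank3}, \code{flank_complete}, \code{tsd}; sorted by chromosome
#'   then start.
#' @export
retrieve_insertions <- function(genome, consensus,
                                significance_cutoff = 1e-3,
                                end_mismatch_tolerance = 20, flank = 500,
                                min_identity = 0.85, min_block = 80) {
  stopifnot(inherits(consensus, "te_consensus"))
  if (nchar(consensus$sequence) < 2 * end_mismatch_tolerance)
    stopf("consensus shorter than twice the end mismatch tolerance")
  if (nchar(consensus$sequence) < 2 * min_block)
    stopf("consensus too short for the block search (< 2 x min_block)")
  if (length(genome) == 0) return(insertion_empty())
  ka <- karlin_altschul_params(1, -2)
  rows <- NULL
  n_id <- 0L
  for (ch in names(genome)) {
    seq <- genome[[ch]]
    if (nchar(seq) < min_block) next
    blocks <- find_similarity_blocks(seq, consensus$sequence,
                                     min_length = min_block,
                                     min_identity = min_identity,
                                     both_strands = TRUE, k = 12L)
    if (!nrow(blocks)) next
    loci <- chain_te_blocks(blocks, nchar(consensus$sequence))
    for (lc in loci) {
      score <- max(lc$length * (3 * lc$identity - 2))
      ev <- ka$K * nchar(seq) * nchar(consensus$sequence) *
        exp(-ka$lambda * score)
      if (ev > significance_cutoff) next
      n_id <- n_id + 1L
      start <- min(lc$a_start); end <- max(lc$a_end)
      cov_iv <- IRanges::reduce(IRanges::IRanges(lc$b_start, lc$b_end))
      cov <- sum(IRanges::width(cov_iv))
      ident <- sum(lc$identity * lc$length) / sum(lc$length)
      strand <- if (sum(lc$length[lc$orientation == "reverse"]) >
                    sum(lc$length[lc$orientation == "forward"])) "-" else "+"
      # project the consensus-implied element ends onto the genome: block
      # ends are anchored at clean matches, so divergent terminal bases
      # would otherwise be clipped from the reported interval. Use only the
      # dominant diagonal chain (an LTR also matches the other consensus
      # LTR on a shifted diagonal and must not mask the projection).
      clen <- nchar(consensus$sequence)
      dom <- lc[lc$orientation == (if (strand == "+") "forward"
                                   else "reverse"), , drop = FALSE]
      dg <- ifelse(dom$orientation == "forward", dom$a_start - dom$b_start,
                   dom$a_start + dom$b_end)
      main_dg <- dg[which.max(dom$length)]
      dom <- dom[abs(dg - main_dg) <= 600, , drop = FALSE]
      head_miss <- min(dom$b_start) - 1L
      tail_miss <- clen - max(dom$b_end)
      start <- min(dom$a_start); end <- max(dom$a_end)
      if (head_miss <= 50 && tail_miss <= 50) {
        if (strand == "+") {
          start <- max(1L, start - head_miss)
          end <- min(nchar(seq), end + tail_miss)
        } else {
          start <- max(1L, start - tail_miss)
          end <- min(nchar(seq), end + head_miss)
        }
      }
      f5s <- max(1L, start - flank)
      f3e <- min(nchar(seq), end + flank)
      flank5 <- substr_(seq, f5s, start - 1L)
      flank3 <- substr_(seq, end + 1L, f3e)
      complete <- nchar(flank5) == flank && nchar(flank3) == flank
      rows <- rbind(rows, data.frame(
        id = NA_character_, chromosome = ch, start = start, end = end,
        strand = strand, identity_to_consensus = ident,
        structure = classify_structure_internal(
          cov_iv, end - start + 1L, consensus, end_mismatch_tolerance),
        consensus_cov = cov,
        cov_start = min(lc$b_start), cov_end = max(lc$b_end),
        cov_intervals = paste(sprintf("%d-%d", IRanges::start(cov_iv),
                                      IRanges::end(cov_iv)),
                              collapse = ";"),
        evalue = ev, flank5 = flank5, flank3 = flank3,
        flank_complete = complete,
        tsd = detect_tsd(flank5, flank3),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows)) return(insertion_empty())
  rows <- rows[order(rows$chromosome, rows$start), , drop = FALSE]
  rows$id <- sprintf("%s_ins_%04d", consensus$name, seq_len(nrow(rows)))
  rownames(rows) <- NULL
  rows
}

insertion_empty <- function() {
  data.frame(id = character(0), chromosome = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             identity_to_consensus = numeric(0), structure = character(0),
             consensus_cov = integer(0), cov_start = integer(0),
             cov_end = integer(0), cov_intervals = character(0),
             evalue = numeric(0),
             flank5 = character(0), flank3 = character(0),
             flank_complete = logical(0), tsd = character(0))
}

# Merge consensus blocks into per-locus chains. A chain requires
# collinearity: blocks must lie near one diagonal (genome offset consistent
# with their consensus coordinates), so a neighbouring solo LTR 1 kb away is
# a separate locus, not part of the element. Clusters whose genome
# intervals coincide (an LTR matching both consensus LTRs) are re-merged.
chain_te_blocks <- function(blocks, cons_len, diag_slack = 500L) {
  blocks <- blocks[order(blocks$a_start), , drop = FALSE]
  blocks$diag <- ifelse(blocks$orientation == "forward",
                        blocks$a_start - blocks$b_start,
                        blocks$a_start + blocks$b_end)
  loci <- list()
  for (ori in unique(blocks$orientation)) {
    bo <- blocks[blocks$orientation == ori, , drop = FALSE]
    cl <- integer(nrow(bo)); cur <- 0L
    ref_diag <- NA_integer_; last_end <- -Inf
    for (i in seq_len(nrow(bo))) {
      if (is.na(ref_diag) || abs(bo$diag[i] - ref_diag) > diag_slack ||
          bo$a_start[i] - last_end > cons_len) {
        cur <- cur + 1L
        ref_diag <- bo$diag[i]
      }
      cl[i] <- cur
      last_end <- max(last_end, bo$a_end[i])
      ref_diag <- round(0.7 * ref_diag + 0.3 * bo$diag[i])
    }
    loci <- c(loci, split(bo, paste0(ori, cl)))
  }
  if (length(loci) <= 1L) return(loci)
  # re-merge clusters occupying the same genome interval
  iv <- t(vapply(loci, function(lc) c(min(lc$a_start), max(lc$a_end)),
                 numeric(2)))
  ord <- order(iv[, 1])
  loci <- loci[ord]; iv <- iv[ord, , drop = FALSE]
  merged <- list(); cur <- loci[[1]]; cur_iv <- iv[1, ]
  for (i in seq_along(loci)[-1]) {
    ov <- min(cur_iv[2], iv[i, 2]) - max(cur_iv[1], iv[i, 1]) + 1
    smaller <- min(cur_iv[2] - cur_iv[1], iv[i, 2] - iv[i, 1]) + 1
    if (ov >= 0.5 * smaller) {
      cur <- rbind(cur, loci[[i]])
      cur_iv <- c(min(cur_iv[1], iv[i, 1]), max(cur_iv[2], iv[i, 2]))
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- loci[[i]]; cur_iv <- iv[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  merged
}

# Structure label from covered consensus intervals.
classify_structure_internal <- function(cov_iv, locus_len, consensus,
                                        tol) {
  clen <- nchar(consensus$sequence)
  cov <- sum(IRanges::width(cov_iv))
  st <- min(IRanges::start(cov_iv)); en <- max(IRanges::end(cov_iv))
  if (cov >= clen - 2 * tol && st <= tol + 1L && en >= clen - tol)
    return("full_length")
  if (!is.null(consensus$ltr_length)) {
    l <- consensus$ltr_length
    ltr_iv <- IRanges::IRanges(c(1L, clen - l + 1L), c(l, clen))
    outside <- IRanges::setdiff(cov_iv, ltr_iv)
    if (sum(IRanges::width(outside)) <= tol && locus_len <= l + 2 * tol)
      return("solo_ltr")
  }
  "truncated"
}

#' Classify the structure of a retrieved insertion
#'
#' \code{full_length} when the covered consensus span reaches both element
#' ends within the tolerance and covers at least the consensus length minus
#' twice the tolerance; \code{solo_ltr} when the match is confined to the
#' LTR interval(s) and the genomic locus is a single LTR long; otherwise
#' \code{truncated}.
#'
#' @param insertion one row of the \code{\link{retrieve_insertions}} result.
#' @param consensus the \code{\link{te_consensus}} it was retrieved against.
#' @param end_mismatch_tolerance boundary tolerance in bases.
#' @return list(\code{structure}, \code{covered}) where covered is the
#'   consensus interval spanned.
#' @export
classify_insertion_structure <- function(insertion, consensus,
                                         end_mismatch_tolerance = 20) {
  cov_iv <- if (!is.null(insertion$cov_intervals) &&
                nzchar(insertion$cov_intervals)) {
    parts <- strsplit(strsplit(insertion$cov_intervals, ";")[[1]], "-")
    IRanges::IRanges(as.integer(vapply(parts, `[`, "", 1)),
                     as.integer(vapply(parts, `[`, "", 2)))
  } else {
    IRanges::IRanges(insertion$cov_start, insertion$cov_end)
  }
  list(structure = classify_structure_internal(
         cov_iv, insertion$end - insertion$start + 1L, consensus,
         end_mismatch_tolerance),
       covered = cov_iv)
}

# TSD: exact match between the last bases of the 5' flank and the first
# bases of the 3' flank, longest first (10 down to 4).
detect_tsd <- function(flank5, flank3, max_len = 10L, min_len = 4L) {
  n5 <- nchar(flank5)
  for (k in seq(min(max_len, n5, nchar(flank3)), min_len)) {
    if (k < min_len) break
    a <- substr(flank5, n5 - k + 1L, n5)
    if (a == substr(flank3, 1L, k)) return(a)
  }
  ""
}

#' Write retrieved insertions as BED
#'
#' 0-based half-open conversion from the internal 1-based closed intervals.
#'
#' @param insertions result of \code{\link{retrieve_insertions}}.
#' @param path output file.
#' @export
write_insertions_bed <- function(insertions, path) {
  write.table(data.frame(insertions$chromosome, insertions$start - 1L,
                         insertions$end, insertions$id, 0L,
                         insertions$strand),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
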