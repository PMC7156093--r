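#' Match TE insertions across two genomes by flank similarity
#'
#' Pairs each genome-A insertion with at most one genome-B insertion by best
#' reciprocal flank similarity (both 500-bp flanks scored by similarity
#' blocks; the score is the total matched bases across both flanks).
#' Insertions without a partner above the cutoff are candidate
#' species-specific insertions. When two A-insertions both clear the cutoff
#' against a single B-insertion the losers are flagged for copy-number
#' review rather than silently dropped (two donor-genome insertions with
#' high flanking similarity to a single derived-genome insertion mark a
#' tandem duplication).
#'
#' @param insertions_a,insertions_b results of
#'   \code{\link{retrieve_insertions}} on the two genomes.
#' @param flank_match_cutoff minimum total matched bases (of the up-to-1000
#'   flanking bases) for a pair; a score-threshold stand-in for a stringent
#'   alignment e-value cutoff.
#' @param full_length_only restrict matching to full-length insertions (the
#'   retrieval set the comparison is anchored on).
#' @param min_block,min_identity block thresholds for flank comparison.
#' @return list with \code{pairs} (a_id, b_id, score), \code{unmatched_a},
#'   \code{unmatched_b} (character ids), and \code{cnv_review} (a_id, b_id,
#'   score of supernumerary matches).
#' @export
match_insertions_across_genomes <- function(insertions_a, insertions_b,
                                            flank_match_cutoff = 300,
                                            full_length_only = TRUE,
                                            min_block = 60,
                                            min_identity = 0.9) {
  check_flanks <- function(ins, tag) {
    bad <- which(!nzchar(ins$flank5) & !nzchar(ins$flank3))
    if (length(bad))
      stopf("insertions without flanks in %s: %s", tag,
            paste(ins$id[bad], collapse = ", "))
  }
  if (nrow(insertions_a)) check_flanks(insertions_a, "genome A")
  if (nrow(insertions_b)) check_flanks(insertions_b, "genome B")
  ia <- insertions_a; ib <- insertions_b
  if (full_length_only) {
    ia <- ia[ia$structure == "full_length", , drop = FALSE]
    ib <- ib[ib$structure == "full_length", , drop = FALSE]
  }
  empty <- list(pairs = data.frame(a_id = character(0), b_id = character(0),
                                   score = numeric(0)),
                unmatched_a = ia$id, unmatched_b = ib$id,
                cnv_review = data.frame(a_id = character(0),
                                        b_id = character(0),
                                        score = numeric(0)))
  if (!nrow(ia) || !nrow(ib)) return(empty)
  # candidate prefilter: flanks sharing at least one exact 16-mer
  sig <- function(f5, f3) {
    h <- c(kmer_hashes(encode_dna(f5), 16L), kmer_hashes(encode_dna(f3), 16L))
    unique(h[!is.na(h)])
  }
  sa <- lapply(seq_len(nrow(ia)), function(i) sig(ia$flank5[i], ia$flank3[i]))
  sb <- lapply(seq_len(nrow(ib)), function(i) sig(ib$flank5[i], ib$flank3[i]))
  scores <- NULL
  for (i in seq_len(nrow(ia))) {
    for (j in seq_len(nrow(ib))) {
      if (ia$chromosome[i] != ib$chromosome[j]) next
      if (!any(sa[[i]] %in% sb[[j]])) next
      s <- flank_pair_score(ia[i, ], ib[j, ], min_block, min_identity)
      if (s >= flank_match_cutoff)
        scores <- rbind(scores, data.frame(a_id = ia$id[i], b_id = ib$id[j],
                                           score = s,
                                           stringsAsFactors = FALSE))
    }
  }
  if (is.null(scores)) return(empty)
  scores <- scores[order(-scores$score), , drop = FALSE]
  used_a <- character(0); used_b <- character(0); pairs <- NULL
  for (r in seq_len(nrow(scores))) {
    if (scores$a_id[r] %in% used_a || scores$b_id[r] %in% used_b) next
    pairs <- rbind(pairs, scores[r, ])
    used_a <- c(used_a, scores$a_id[r]); used_b <- c(used_b, scores$b_id[r])
  }
  leftovers <- scores[!(scores$a_id %in% pairs$a_id), , drop = FALSE]
  cnv_review <- leftovers[leftovers$b_id %in% pairs$b_id, , drop = FALSE]
  list(pairs = pairs,
       unmatched_a = setdiff(ia$id, pairs$a_id),
       unmatched_b = setdiff(ib$id, pairs$b_id),
       cnv_review = cnv_review)
}

flank_pair_score <- function(a, b, min_block, min_identity) {
  sc <- 0
  for (side in c("flank5", "flank3")) {
    fa <- a[[side]]; fb <- b[[side]]
    if (nchar(fa) < min_block || nchar(fb) < min_block) next
    bl <- find_similarity_blocks(fa, fb, min_block, min_identity, k = 12L)
    if (nrow(bl)) sc <- sc + sum(bl$length * bl$identity)
  }
  sc
}

#' Locate an orthologous locus by chromosome walking
#'
#' Extends the flanking sequence on each side of an anchor interval in
#' geometrically growing steps and aligns it to the partner chromosome until
#' a significant anchor block is found on both sides; the orthologous locus
#' is the partner-genome interval bracketed by the nearest anchors. Walk
#' extents up to \code{max_extent} cover multi-megabase rearrangements.
#'
#' @param genome_a donor genome (named character vector).
#' @param anchor list/row with \code{chromosome}, \code{start}, \code{end}
#'   (the insertion or locus to place).
#' @param genome_b partner genome.
#' @param b_chromosome partner chromosome searched (defaults to the anchor's
#'   chromosome name).
#' @param step initial flank size in bases (doubles each round).
#' @param max_extent maximum walked distance per side.
#' @param min_anchor minimum matched bases for a significant anchor.
#' @param min_block,min_identity block thresholds.
#' @return list with \code{found}; when found: \code{b_interval} (bracketed
#'   interval on B), \code{a_interval} (between the outer anchor borders on
#'   A), \code{left_anchor}/\code{right_anchor} (block rows in absolute
#'   coordinates), \code{walked} (bases examined per side).
#' @export
chromosome_walk <- function(genome_a, anchor, genome_b,
                            b_chromosome = NULL, step = 5000,
                            max_extent = 5e6, min_anchor = 200,
                            min_block = 100, min_identity = 0.95) {
  ch <- anchor$chromosome
  if (is.null(b_chromosome)) b_chromosome <- ch
  A <- genome_a[[ch]]
  B <- genome_b[[b_chromosome]]
  if (anchor$start < 1 || anchor$end > nchar(A))
    stopf("anchor outside genome A bounds")
  walk_side <- function(side) {
    extent <- step
    repeat {
      if (side == "left") {
        lo <- max(1L, anchor$start - extent); hi <- anchor$start - 1L
      } else {
        lo <- anchor$end + 1L; hi <- min(nchar(A), anchor$end + extent)
      }
      if (hi - lo + 1L >= min_block) {
        seg <- substr_(A, lo, hi)
        bl <- find_similarity_blocks(seg, B, min_block, min_identity,
                                     k = 12L)
        if (nrow(bl)) {
          bl$a_start <- bl$a_start + lo - 1L
          bl$a_end <- bl$a_end + lo - 1L
          good <- bl[bl$length * bl$identity >= min_anchor, , drop = FALSE]
          if (nrow(good)) {
            ord <- if (side == "left") order(-good$a_end, -good$length)
                   else order(good$a_start, -good$length)
            return(list(anchors = utils::head(good[ord, , drop = FALSE],
                                              8L),
                        walked = extent))
          }
        }
      }
      at_edge <- if (side == "left") anchor$start - extent <= 1
                 else anchor$end + extent >= nchar(A)
      if (extent >= max_extent || at_edge)
        return(list(anchors = NULL, walked = extent))
      extent <- min(max_extent, extent * 2)
    }
  }
  left <- walk_side("left")
  right <- walk_side("right")
  if (is.null(left$anchors) || is.null(right$anchors))
    return(list(found = FALSE, walked = c(left = left$walked,
                                          right = right$walked)))
  # choose the anchor pair whose derived-genome gap is geometrically
  # consistent with the donor-side gap (repetitive elements such as solo
  # LTRs otherwise anchor to the wrong copy): a deletion shrinks the gap,
  # junction repeats overlap it slightly, and inserts enlarge it boundedly
  best <- NULL; best_pen <- Inf; best_score <- -Inf
  for (i in seq_len(nrow(left$anchors))) {
    for (j in seq_len(nrow(right$anchors))) {
      la <- left$anchors[i, ]; ra <- right$anchors[j, ]
      a_gap <- ra$a_start - la$a_end - 1L
      b_gap <- ra$b_start - la$b_end - 1L
      pen <- max(0, b_gap - a_gap - 20000) + max(0, -b_gap - 5000)
      score <- la$length * la$identity + ra$length * ra$identity
      if (pen < best_pen || (pen == best_pen && score > best_score)) {
        best <- list(la = la, ra = ra); best_pen <- pen
        best_score <- score
      }
    }
  }
  la <- best$la; ra <- best$ra
  list(found = TRUE,
       b_interval = c(la$b_end + 1L, ra$b_start - 1L),
       a_interval = c(la$a_end + 1L, ra$a_start - 1L),
       left_anchor = la, right_anchor = ra,
       b_chromosome = b_chromosome,
       walked = c(left = left$walked, right = right$walked))
}

#' Classify the polymorphism source of an unmatched insertion
#'
#' Applies the documented decision tree to an A-specific insertion and its
#' ortholocus evidence, cheapest-to-verify and most-exculpatory first:
#' \code{assembly_artifact} (N run within the artifact window of a putative
#' breakpoint), then \code{empty_site_tsd} (the derived-side junction is the
#' donor flanks joined across a single TSD copy), then
#' \code{internal_deletion}/\code{chimeric_deletion} (element present at the
#' ortholocus but partially deleted, within / beyond its boundaries), then
#' \code{replaced_by_insertion} (non-homologous derived-side insert of at
#' least \code{replacement_min} bases), then \code{long_indel_candidate}.
#'
#' @param insertion one row of the A-side \code{\link{retrieve_insertions}}.
#' @param walk result of \code{\link{chromosome_walk}} for this insertion.
#' @param genome_a,genome_b the genomes.
#' @param consensus the anchor-family \code{\link{te_consensus}}.
#' @param artifact_window N-run search distance from a breakpoint (bases).
#' @param replacement_min smallest derived-side insert called a replacement.
#' @param min_block,min_identity block thresholds.
#' @return a \code{polymorphism_call} list: \code{insertion_id},
#'   \code{category}, \code{ortholocus}, \code{evidence} (free-text audit
#'   trail), and the per-locus \code{indel} pre-call.
#' @export
classify_polymorphism <- function(insertion, walk, genome_a, genome_b,
                                  consensus, artifact_window = 100,
                                  replacement_min = 1000,
                                  min_block = 100, min_identity = 0.95) {
  ev <- character(0)
  out <- list(insertion_id = insertion$id, match_id = "",
              category = NA_character_, ortholocus = NULL,
              evidence = character(0), indel = NULL)
  class(out) <- "polymorphism_call"
  if (!isTRUE(walk$found)) {
    out$category <- "long_indel_candidate"
    out$evidence <- "no ortholocus anchors found within the walk extent"
    return(out)
  }
  ch <- insertion$chromosome
  A <- genome_a[[ch]]; B <- genome_b[[walk$b_chromosome]]
  pad <- 200L
  a1 <- max(1L, walk$left_anchor$a_start)
  a2 <- min(nchar(A), walk$right_anchor$a_end)
  b1 <- max(1L, walk$left_anchor$b_start)
  b2 <- min(nchar(B), walk$right_anchor$b_end)
  locus_a <- substr_(A, a1, a2)
  locus_b <- substr_(B, b1, b2)
  out$ortholocus <- c(b1, b2)
  if (nchar(locus_a) < min_block || nchar(locus_b) < min_block) {
    out$category <- "long_indel_candidate"
    out$evidence <- "degenerate ortholocus bracket; retained as candidate"
    return(out)
  }
  ic <- call_indel(locus_a, locus_b, min_block, min_identity,
                   locus_id = insertion$id, a_offset = a1 - 1L,
                   b_offset = b1 - 1L, chromosome = ch)
  out$indel <- ic
  if (ic$partial) {
    out$category <- "long_indel_candidate"
    out$evidence <- "partial anchor support; retained as candidate"
    return(out)
  }
  # 1. assembly artifact
  if (ic$artifact) {
    out$category <- "assembly_artifact"
    out$evidence <- sprintf(
      "N run within %d bp of a putative breakpoint; excluded from indel calling",
      artifact_window)
    return(out)
  }
  # 2. empty site with a single TSD copy at the junction
  tsd <- insertion$tsd
  gap_b_seq <- substr_(B, ic$breakpoint5["b"] + 1L, ic$breakpoint3["b"] - 1L)
  junction_mh <- if (ic$ambiguity_width > 0)
    substr_(B, ic$breakpoint5["b"] - ic$ambiguity_width + 1L,
            ic$breakpoint5["b"])
  else ""
  removed <- ic$removed_length
  el_len <- insertion$end - insertion$start + 1L
  # the deleted donor interval is essentially the element itself, and the
  # junction retains a short duplication (the TSD, when retrieval caught it)
  tsd_match <- nzchar(tsd) &&
    (identical(gap_b_seq, tsd) || identical(junction_mh, tsd))
  tsd_like <- ic$ambiguity_width >= 3 && ic$ambiguity_width <= 12
  if ((tsd_match || tsd_like) &&
      abs(removed - el_len) <= el_len * 0.02 + 50) {
    out$category <- "empty_site_tsd"
    out$evidence <- if (tsd_match)
      sprintf("single TSD copy ('%s') at the derived junction", tsd)
    else "element-length deletion with a short junction duplication"
    return(out)
  }
  # 3. element partially present at the ortholocus: internal / chimeric
  cons_b <- find_similarity_blocks(locus_b, consensus$sequence,
                                   min_length = min_block,
                                   min_identity = 0.85,
                                   both_strands = TRUE, k = 12L)
  cons_cov <- if (nrow(cons_b)) covered_width(cons_b$b_start, cons_b$b_end)
              else 0L
  gap_a <- c(ic$breakpoint5["a"] + 1L, ic$breakpoint3["a"] - 1L)
  gap_in_element <- removed >= min_block &&
    gap_a[1] <= insertion$end && gap_a[2] >= insertion$start
  if (cons_cov >= 2L * min_block && removed < el_len && gap_in_element) {
    within <- gap_a[1] >= insertion$start && gap_a[2] <= insertion$end
    out$category <- if (within) "internal_deletion" else "chimeric_deletion"
    out$evidence <- sprintf(
      "element present at ortholocus (%d consensus bases) minus %d deleted bases%s",
      cons_cov, max(0L, ic$removed_length),
      if (within) " within the element" else " extending into the flank")
    return(out)
  }
  if (removed < min_block && ic$b_length < min_block &&
      ic$rearrangement_type %in% c("none", "deletion_in_b")) {
    out$category <- "monomorphic"
    out$evidence <- "ortholocus intact; no rearrangement at block resolution"
    return(out)
  }
  # 4. replaced by a long non-homologous insertion
  if (ic$b_length >= replacement_min &&
      identical(ic$rearrangement_type, "replacement")) {
    out$category <- "replaced_by_insertion"
    out$evidence <- sprintf("derived-side insert of %d bases at the junction",
                            ic$b_length)
    return(out)
  }
  out$category <- "long_indel_candidate"
  out$evidence <- sprintf("donor-side loss of %d bases (junction remnant %d)",
                          ic$removed_length, max(0L, ic$b_gap))
  out
}
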