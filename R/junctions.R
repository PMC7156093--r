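#' Microhomology at a deletion junction
#'
#' Finds the longest exact direct repeat that flanks the deleted segment on
#' both ends of the donor locus and is retained as a single copy at the
#' derived junction (the MMEJ signature: e.g. a deletion bordered by a
#' mononucleotide 'A' at both ends whose derived junction carries one 'A'
#' between the conserved flanks). By the leftmost-placement convention the
#' retained copy is the one immediately after the deleted interval.
#'
#' @param donor donor-locus sequence string.
#' @param deletion integer c(start, end), 1-based closed, leftmost placement
#'   of the deleted interval within \code{donor}.
#' @param max_mh maximum microhomology length considered (MMEJ uses < 10 bp).
#' @return list with \code{microhomology}, \code{length}, and
#'   \code{single_copy_retained} (TRUE when the motif occurs exactly once at
#'   the derived junction between the conserved anchors).
#' @export
find_junction_microhomology <- function(donor, deletion, max_mh = 9) {
  d1 <- deletion[1]; d2 <- deletion[2]
  n <- nchar(donor)
  if (d1 < 1 || d2 > n || d2 < d1)
    stopf("deletion interval [%s,%s] invalid for donor of length %d",
          d1, d2, n)
  del_start <- substr_(donor, d1, min(d2, d1 + max_mh - 1L))
  after <- substr_(donor, d2 + 1L, min(n, d2 + max_mh))
  k <- common_prefix_len(del_start, after)
  mh <- substr_(donor, d1, d1 + k - 1L)
  single <- TRUE
  if (k > 0) {
    # left anchor must not end with the motif, and the retained copy must
    # not be tandemly repeated, otherwise >1 copy sits at the junction
    left_tail <- substr_(donor, max(1L, d1 - k), d1 - 1L)
    next_k <- substr_(donor, d2 + k + 1L, min(n, d2 + 2L * k))
    single <- !identical(left_tail, mh) && !identical(next_k, mh)
  }
  list(microhomology = mh, length = k, single_copy_retained = single)
}

#' Reconstruct SD-MMEJ repair explanations for a junction
#'
#' Synthesis-dependent microhomology-mediated end joining: a short primer
#' repeat at a broken end anneals to a nearby template, limited fill-in
#' synthesis copies a tract, and the newly created end anneals to the other
#' side of the break via junction microhomology -- explaining templated
#' ("filler") net insertions, or creating the microhomology that yields an
#' apparently blunt junction. This function exhaustively enumerates
#' explanations with at most \code{max_rounds} rounds of annealing/synthesis,
#' primer repeats of length >= \code{min_primer} found within \code{window}
#' bases of either breakpoint (both flanks, direct loop-out and inverted
#' snap-back classes, and from either broken end).
#'
#' A reconstruction is valid when left flank + explained net insertion +
#' right flank reproduces the derived junction exactly; the synthesis tract
#' equals the net insertion plus the junction microhomology (a prefix of the
#' far flank) and must occur, immediately preceded by the primer repeat, in
#' the donor context (reverse-complemented for the inverted class).
#'
#' Ranking: fewest rounds, then longest junction microhomology, then
#' shortest total synthesis, then smallest primer-to-break distance. All
#' co-optimal reconstructions are reported.
#'
#' @param donor_context list with \code{left} (flank ending at the 5'
#'   breakpoint) and \code{right} (flank starting at the 3' breakpoint) on
#'   the donor genome.
#' @param net_insertion the net inserted sequence observed at the derived
#'   junction ("" for an apparently blunt junction).
#' @param window primer-repeat search window, bases from each breakpoint.
#' @param max_rounds maximum synthesis rounds (1 or 2).
#' @param min_primer minimum primer-repeat length.
#' @param max_primer maximum primer-repeat length.
#' @param max_mh maximum junction-microhomology length.
#' @param min_template minimum primer+tract template length; annealing below
#'   ~4 bases is not considered evidence (chance matches).
#' @return data.frame ranked best-first: \code{rounds}, \code{primer_repeat},
#'   \code{primer_side}, \code{repeat_class}, \code{template}, \code{tract1},
#'   \code{tract2}, \code{synthesis_tract}, \code{synthesis_length},
#'   \code{junction_microhomology}, \code{net_insertion}. Zero rows means no
#'   SD-MMEJ explanation exists within the search space.
#' @export
reconstruct_sdmmej <- function(donor_context, net_insertion = "",
                               window = 35, max_rounds = 2, min_primer = 1,
                               max_primer = 8, max_mh = 9,
                               min_template = 4) {
  L <- as_dna_string(donor_context$left)
  R <- as_dna_string(donor_context$right)
  net <- as_dna_string(net_insertion)
  if (nchar(net) == 0) net <- ""
  out <- sdmmej_enumerate(L, R, net, window, max_rounds, min_primer,
                          max_primer, max_mh, min_template,
                          primer_side = "left")
  # symmetric case: synthesis primed from the right-hand broken end
  mirror <- sdmmej_enumerate(revcomp(R), revcomp(L), revcomp(net), window,
                             max_rounds, min_primer, max_primer, max_mh,
                             min_template, primer_side = "right")
  # mirror rows carry tract/microhomology in the right-end primer frame
  # (reverse complement); the net insertion is reported on the top strand
  if (!is.null(mirror) && nrow(mirror)) mirror$net_insertion <- net
  out <- rbind(out, mirror)
  if (is.null(out) || !nrow(out)) return(sdmmej_empty())
  out <- out[!duplicated(out[, c("rounds", "primer_repeat", "primer_side",
                                 "repeat_class", "template",
                                 "synthesis_tract")]), , drop = FALSE]
  ord <- order(out$rounds, -nchar(out$junction_microhomology),
               out$synthesis_length, out$primer_distance)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

sdmmej_empty <- function() {
  data.frame(rounds = integer(0), primer_repeat = character(0),
             primer_side = character(0), repeat_class = character(0),
             template = character(0), tract1 = character(0),
             tract2 = character(0), synthesis_tract = character(0),
             synthesis_length = integer(0),
             junction_microhomology = character(0),
             net_insertion = character(0), primer_distance = integer(0))
}

# Enumerate left-end-primed reconstructions of junction L + net + R.
sdmmej_enumerate <- function(L, R, net, window, max_rounds, min_primer,
                             max_primer, max_mh, min_template, primer_side) {
  nL <- nchar(L); nR <- nchar(R)
  res <- NULL
  mh_max <- min(max_mh, nR)
  cache <- new.env(parent = emptyenv())
  occs <- function(p, tract) {
    key <- paste0(p, "|", tract)
    if (!is.null(cache[[key]])) return(cache[[key]])
    o <- if (nchar(p) + nchar(tract) < min_template)
      data.frame(template = character(0), class = character(0),
                 distance = integer(0))
    else template_occurrences(p, tract, L, R, window, nchar(p))
    cache[[key]] <- o
    o
  }
  for (mu_len in seq_len(mh_max)) {
    mu <- substr(R, 1L, mu_len)
    total <- paste0(net, mu)
    tlen <- nchar(total)
    # one round
    for (plen in min_primer:min(max_primer, nL)) {
      p <- substr(L, nL - plen + 1L, nL)
      occ <- occs(p, total)
      for (r in seq_len(nrow(occ))) {
        res <- rbind(res, data.frame(
          rounds = 1L, primer_repeat = p, primer_side = primer_side,
          repeat_class = occ$class[r], template = occ$template[r],
          tract1 = total, tract2 = "", synthesis_tract = total,
          synthesis_length = tlen, junction_microhomology = mu,
          net_insertion = net, primer_distance = occ$distance[r],
          stringsAsFactors = FALSE))
      }
    }
    # two rounds: total = tract1 + tract2
    if (max_rounds >= 2 && tlen >= 2) {
      for (split in seq_len(tlen - 1L)) {
        t1 <- substr(total, 1L, split)
        t2 <- substr(total, split + 1L, tlen)
        L2 <- paste0(L, t1)
        for (p1len in min_primer:min(max_primer, nL)) {
          p1 <- substr(L, nL - p1len + 1L, nL)
          occ1 <- occs(p1, t1)
          if (!nrow(occ1)) next
          for (p2len in min_primer:min(max_primer, nchar(L2))) {
            p2 <- substr(L2, nchar(L2) - p2len + 1L, nchar(L2))
            occ2 <- occs(p2, t2)
            if (!nrow(occ2)) next
            res <- rbind(res, data.frame(
              rounds = 2L, primer_repeat = p1, primer_side = primer_side,
              repeat_class = paste(occ1$class[1], occ2$class[1], sep = "+"),
              template = paste(occ1$template[1], occ2$template[1],
                               sep = ";"),
              tract1 = t1, tract2 = t2, synthesis_tract = total,
              synthesis_length = tlen, junction_microhomology = mu,
              net_insertion = net,
              primer_distance = min(occ1$distance) + min(occ2$distance),
              stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  res
}

# Occurrences of primer immediately followed by tract, in either flank,
# direct or inverted (reverse-complement) orientation, with the primer
# within `window` bases of the corresponding breakpoint.
template_occurrences <- function(primer, tract, L, R, window, plen) {
  pat <- paste0(primer, tract)
  rc_pat <- revcomp(pat)
  nL <- nchar(L)
  hits <- NULL
  scan <- function(seqname, seq, pattern, cls) {
    if (nchar(pattern) > nchar(seq)) return(NULL)
    pos <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
    if (pos[1] == -1L) return(NULL)
    pos
  }
  add <- function(side, seq, pattern, cls) {
    pos <- scan(side, seq, pattern, cls)
    if (is.null(pos)) return()
    for (s in pos) {
      e <- s + nchar(pattern) - 1L
      dist <- if (side == "left") nchar(seq) - e else s - 1L
      if (dist <= window) {
        hits <<- rbind(hits, data.frame(
          template = sprintf("%s:%d-%d%s", side, s, e,
                             if (cls == "inverted") "(rc)" else ""),
          class = cls, distance = dist, stringsAsFactors = FALSE))
      }
    }
  }
  # exclude the trivial self-match of the primer at the very end of L: the
  # template must provide sequence beyond the broken end itself
  addL <- function(pattern, cls) {
    pos <- gregexpr(pattern, L, fixed = TRUE)[[1]]
    if (pos[1] == -1L) return()
    for (s in pos) {
      e <- s + nchar(pattern) - 1L
      if (cls == "direct" && e > nL - 1L && nchar(tract) == 0L) next
      dist <- nL - e
      if (dist <= window)
        hits <<- rbind(hits, data.frame(
          template = sprintf("left:%d-%d%s", s, e,
                             if (cls == "inverted") "(rc)" else ""),
          class = cls, distance = dist, stringsAsFactors = FALSE))
    }
  }
  addL(pat, "direct")
  add("right", R, pat, "direct")
  addL(rc_pat, "inverted")
  add("right", R, rc_pat, "inverted")
  if (is.null(hits))
    hits <- data.frame(template = character(0), class = character(0),
                       distance = integer(0))
  hits
}

#' Long direct repeats flanking a deletion
#'
#' Searches the donor locus for the longest direct-repeat pair with one copy
#' overlapping each breakpoint region: the template configuration for
#' unequal intra-strand recombination, which deletes the segment between the
#' repeats and retains a single (possibly hybrid) copy.
#'
#' @param donor_locus donor-locus sequence.
#' @param breakpoints c(bp5, bp3) positions within \code{donor_locus} (the
#'   similarity borders of the deletion).
#' @param min_length,min_identity repeat thresholds (the block criterion).
#' @return list with \code{repeat_length}, \code{identity},
#'   \code{r1_interval}, \code{r2_interval}, or \code{NULL} when no
#'   qualifying repeat pair exists.
#' @export
find_flanking_direct_repeats <- function(donor_locus, breakpoints,
                                         min_length = 100,
                                         min_identity = 0.95) {
  bp5 <- breakpoints[1]; bp3 <- breakpoints[2]
  blocks <- self_repeat_blocks(donor_locus, min_length, min_identity)
  blocks <- blocks[blocks$orientation == "forward", , drop = FALSE]
  if (!nrow(blocks)) return(NULL)
  pad <- min_length
  near <- function(s, e, p) s <= p + pad & e >= p - pad
  cand <- blocks[near(blocks$a_start, blocks$a_end, bp5) &
                   near(blocks$b_start, blocks$b_end, bp3), , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  best <- cand[which.max(cand$length), ]
  list(repeat_length = best$length, identity = best$identity,
       r1_interval = c(best$a_start, best$a_end),
       r2_interval = c(best$b_start, best$b_end))
}

#' Test whether a deletion arose by inter-element LTR recombination
#'
#' TRUE when both breakpoints fall inside LTR annotations of the same family
#' in the same orientation (e.g. both borders within tandem same-family
#' LTRs), the configuration left by recombination between the LTRs of
#' neighbouring elements.
#'
#' @param breakpoints list/data.frame with \code{chromosome}, \code{bp5},
#'   \code{bp3} (donor-genome coordinates).
#' @param te_annotation annotation data.frame with columns \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{family}, \code{part}.
#' @return list(\code{is_ltr_recombination}, \code{elements}).
#' @export
detect_ltr_recombination <- function(breakpoints, te_annotation) {
  if (is.null(te_annotation) || !nrow(te_annotation))
    return(list(is_ltr_recombination = FALSE, elements = NULL))
  ltr <- te_annotation[te_annotation$part == "LTR" &
                         te_annotation$chrom == breakpoints$chromosome, ,
                       drop = FALSE]
  if (!nrow(ltr)) return(list(is_ltr_recombination = FALSE, elements = NULL))
  hit <- function(p) ltr[ltr$start <= p & ltr$end >= p, , drop = FALSE]
  h5 <- hit(breakpoints$bp5); h3 <- hit(breakpoints$bp3)
  if (!nrow(h5) || !nrow(h3))
    return(list(is_ltr_recombination = FALSE, elements = NULL))
  for (i in seq_len(nrow(h5))) for (j in seq_len(nrow(h3))) {
    same <- h5$family[i] == h3$family[j] && h5$strand[i] == h3$strand[j] &&
      !(h5$start[i] == h3$start[j] && h5$end[i] == h3$end[j])
    if (same)
      return(list(is_ltr_recombination = TRUE,
                  elements = rbind(h5[i, ], h3[j, ])))
  }
  list(is_ltr_recombination = FALSE, elements = NULL)
}

#' Test whether a net insertion is an introgression of foreign sequence
#'
#' TRUE when the inserted sequence has no similarity block at the configured
#' thresholds against the donor genome or any supplied reference genome
#' (modeled on an insert not identified in either parental genome).
#'
#' @param net_insertion inserted sequence (>= \code{min_insert} to qualify).
#' @param donor_genome named character vector of donor chromosomes.
#' @param reference_genomes list of additional named character vectors.
#' @param min_insert minimum insert length considered.
#' @param min_length,min_identity block thresholds for the homology search.
#' @return list(\code{introgressed}, \code{best_hit}) where best_hit names
#'   the genome/chromosome of the longest block found (NULL if none).
#' @export
detect_introgression <- function(net_insertion, donor_genome,
                                 reference_genomes = list(),
                                 min_insert = 1000,
                                 min_length = 100, min_identity = 0.95) {
  if (nchar(net_insertion) < min_insert)
    return(list(introgressed = FALSE, best_hit = NULL,
                note = "insert below minimum length"))
  genomes <- c(list(donor = donor_genome), reference_genomes)
  best <- NULL
  for (g in seq_along(genomes)) {
    for (ch in names(genomes[[g]])) {
      b <- find_similarity_blocks(net_insertion, genomes[[g]][[ch]],
                                  min_length, min_identity,
                                  both_strands = TRUE)
      if (nrow(b)) {
        top <- b[which.max(b$length), ]
        cand <- list(genome = names(genomes)[g], chromosome = ch,
                     length = top$length, identity = top$identity)
        if (is.null(best) || cand$length > best$length) best <- cand
      }
    }
  }
  list(introgressed = is.null(best), best_hit = best)
}

#' Classify the repair mechanism of an indel junction
#'
#' Applies the documented precedence to an \code{\link{call_indel}} result:
#' copy-number variation; replacement with a foreign insert (introgression);
#' long flanking direct repeats (unequal intra-strand recombination, or
#' inter-element LTR recombination when both breakpoints lie in same-family,
#' same-orientation LTR annotations); templated net insertion explained by
#' SD-MMEJ reconstruction; microhomology of 1-9 bp retained in a single copy
#' (MMEJ); otherwise blunt/C-NHEJ-or-ambiguous. All evidence gathered along
#' the way is retained in the signature regardless of the final label.
#'
#' @param indel an \code{indel_call} from \code{\link{call_indel}}.
#' @param donor_genome,derived_genome named character vectors.
#' @param te_annotation optional TE annotation (see
#'   \code{\link{detect_ltr_recombination}}).
#' @param reference_genomes optional list for the introgression check.
#' @param sdmmej_window,max_filler SD-MMEJ search window and the largest net
#'   insertion treated as a junction filler rather than a replacement.
#' @param min_intro smallest replacement insert tested for introgression.
#' @return a \code{junction_signature} list.
#' @export
classify_mechanism <- function(indel, donor_genome, derived_genome,
                               te_annotation = NULL,
                               reference_genomes = list(),
                               sdmmej_window = 35, max_filler = 50,
                               min_intro = 1000) {
  notes <- character(0)
  sig <- list(locus_id = indel$locus_id, mechanism = NA_character_,
              microhomology = "", microhomology_length = 0L,
              flanking_repeat_length = 0L, flanking_repeat_identity = NA_real_,
              net_insertion = "", reconstructions = sdmmej_empty(),
              notes = notes, evidence = list())
  class(sig) <- "junction_signature"
  if (identical(indel$rearrangement_type, "copy_number_variation")) {
    sig$mechanism <- "cnv_duplication"
    return(sig)
  }
  ch <- indel$chromosome
  donor <- donor_genome[[ch]]
  bp5 <- indel$breakpoint5["a"]; bp3 <- indel$breakpoint3["a"]
  net <- junction_net_insertion(indel, derived_genome)
  sig$net_insertion <- net
  # 1. replacement by a long non-homologous insert -> introgression
  if (nchar(net) >= min_intro) {
    intro <- detect_introgression(net, donor_genome, reference_genomes,
                                  min_insert = min_intro)
    sig$evidence$introgression <- intro
    if (intro$introgressed) {
      sig$mechanism <- "introgression"
      return(sig)
    }
    sig$notes <- c(sig$notes,
                   "long replacement insert homologous to donor/reference")
    sig$mechanism <- "blunt_cnhej_or_ambiguous"
    return(sig)
  }
  # microhomology evidence is computed (and retained) regardless of label;
  # leftmost placement of the deleted interval: the called breakpoints bound
  # the unaligned donor gap, and the junction repeat (= ambiguity width)
  # sits immediately left of it
  del <- c(bp5 + 1L - indel$ambiguity_width, bp3 - 1L)
  mh <- if (del[2] >= del[1])
    find_junction_microhomology(donor, del)
  else list(microhomology = "", length = 0L, single_copy_retained = FALSE)
  sig$microhomology <- mh$microhomology
  sig$microhomology_length <- mh$length
  # 2. long flanking direct repeats (searched in a window around the locus)
  w1 <- max(1L, bp5 - 15000L)
  sub <- substr_(donor, w1, min(nchar(donor), bp3 + 15000L))
  reps <- find_flanking_direct_repeats(sub, c(bp5, bp3) - w1 + 1L)
  if (!is.null(reps)) {
    reps$r1_interval <- reps$r1_interval + w1 - 1L
    reps$r2_interval <- reps$r2_interval + w1 - 1L
    sig$flanking_repeat_length <- reps$repeat_length
    sig$flanking_repeat_identity <- reps$identity
    sig$evidence$flanking_repeats <- reps
    ltr <- detect_ltr_recombination(
      list(chromosome = ch, bp5 = bp5, bp3 = bp3), te_annotation)
    sig$evidence$ltr <- ltr
    sig$mechanism <- if (ltr$is_ltr_recombination) "ltr_recombination"
                     else "unequal_recombination"
    return(sig)
  }
  # 3. templated net insertion -> SD-MMEJ
  ctx <- junction_contexts(indel, donor_genome)
  if (nchar(net) > 0 && nchar(net) <= max_filler) {
    rec <- reconstruct_sdmmej(ctx, net, window = sdmmej_window)
    sig$reconstructions <- rec
    if (nrow(rec)) {
      sig$mechanism <- "sdmmej"
      return(sig)
    }
    sig$notes <- c(sig$notes, "net insertion not explained by SD-MMEJ search")
    sig$mechanism <- "blunt_cnhej_or_ambiguous"
    return(sig)
  }
  # 4. MMEJ: 1-9 bp microhomology retained in a single copy
  if (mh$length >= 1 && mh$length <= 9 && mh$single_copy_retained &&
      nchar(net) == 0) {
    sig$mechanism <- "mmej"
    return(sig)
  }
  if (mh$length >= 10)
    sig$notes <- c(sig$notes, sprintf(
      "intermediate homology (%d bp) between the repeat and microhomology regimes",
      mh$length))
  # 5. blunt: try an SD-MMEJ explanation of the apparently blunt junction
  rec <- reconstruct_sdmmej(ctx, "", window = sdmmej_window)
  sig$reconstructions <- rec
  if (nrow(rec))
    sig$notes <- c(sig$notes,
                   "apparently blunt junction admits an SD-MMEJ explanation")
  if (!is.null(indel$a_length) && indel$a_length >= 1000)
    sig$notes <- c(sig$notes,
                   "deletion length makes repair via C-NHEJ less likely; MMEJ-family repair favored")
  sig$mechanism <- "blunt_cnhej_or_ambiguous"
  sig
}

# Derived-junction net insertion (the derived-side sequence between the
# flanking anchor blocks), "" for clean deletions.
junction_net_insertion <- function(indel, derived_genome) {
  if (is.null(indel$b_gap) || indel$b_gap <= 0) return("")
  der <- derived_genome[[indel$chromosome]]
  substr_(der, indel$breakpoint5["b"] + 1L, indel$breakpoint3["b"] - 1L)
}

junction_contexts <- function(indel, donor_genome, flank = 80) {
  donor <- donor_genome[[indel$chromosome]]
  bp5 <- indel$breakpoint5["a"]; bp3 <- indel$breakpoint3["a"]
  list(left = substr_(donor, max(1L, bp5 - flank + 1L), bp5),
       right = substr_(donor, bp3, min(nchar(donor), bp3 + flank - 1L)))
}
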