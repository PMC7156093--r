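#' Length of a 1-based closed interval
#'
#' The coordinate convention used throughout: locus length is the genetic
#' distance between the 5' and 3' breakpoints, \code{end - start + 1}.
#'
#' @param start,end 1-based positions, \code{end >= start}.
#' @return integer length in bases.
#' @examples
#' interval_length(566939353, 567135082)  # 195730
#' @export
interval_length <- function(start, end) {
  if (any(end < start)) stopf("interval_length(): end < start")
  as.integer(end - start + 1)
}

#' Call an indel between two orthologous loci
#'
#' Computes similarity blocks between the two loci and places the indel
#' breakpoints at the inner borders of the outermost flanking blocks: the 5'
#' breakpoint at the end of the leftmost anchor block and the 3' breakpoint
#' at the start of the rightmost anchor block, on both genomes. When the two
#' junction sides share an exact repeat the flanking blocks overlap on the
#' derived genome; the overlap length is reported as \code{ambiguity_width}
#' and breakpoints follow the leftmost-placement convention, so the donor
#' bases removed equal \code{a_length + ambiguity_width}.
#'
#' Rearrangement type: \code{deletion_in_b} when the derived-side junction
#' remnant is at most \code{junction_remnant_bound} bases \emph{or} is itself
#' homologous to the donor flanks (a long remnant made of the recombined
#' repeat still marks a deletion); \code{replacement} when both sides exceed
#' the bound; \code{copy_number_variation} when the junction overlap spans a
#' full tandem unit; \code{inversion} when a run of reverse-orientation
#' blocks lies between the anchors; \code{none} for identical loci. A call
#' whose breakpoint region abuts a run of Ns is flagged as a likely assembly
#' artifact and marked low-confidence rather than silently emitted.
#'
#' @param locus_a,locus_b locus sequences (donor / derived).
#' @param min_block,min_identity block thresholds ("word size" and identity).
#' @param junction_remnant_bound deletion vs replacement bound, bases.
#' @param cnv_min_unit smallest junction overlap investigated as a tandem
#'   unit.
#' @param locus_id identifier carried into downstream reports.
#' @param a_offset,b_offset genome coordinates of position 1 of each locus
#'   minus one (so reported positions can be absolute).
#' @param chromosome chromosome name carried through.
#' @return an \code{indel_call} list: \code{locus_id}, \code{chromosome},
#'   \code{breakpoint5}/\code{breakpoint3} (named vectors with \code{a},
#'   \code{b}), \code{a_interval}, \code{b_interval}, \code{a_length},
#'   \code{b_length}, \code{a_gap}, \code{b_gap}, \code{ambiguity_width},
#'   \code{removed_length} (ambiguity-normalized donor loss),
#'   \code{rearrangement_type}, \code{partial}, \code{artifact},
#'   \code{low_confidence}, \code{cnv} (a \code{cnv_call} or NULL),
#'   \code{inversion}, \code{nested}, \code{blocks}.
#' @export
call_indel <- function(locus_a, locus_b, min_block = 100,
                       min_identity = 0.95, junction_remnant_bound = 100,
                       cnv_min_unit = 1000, locus_id = "locus",
                       a_offset = 0L, b_offset = 0L, chromosome = NA) {
  locus_a <- as_dna_string(locus_a); locus_b <- as_dna_string(locus_b)
  blocks <- find_similarity_blocks(locus_a, locus_b, min_block, min_identity,
                                   both_strands = TRUE)
  out <- list(locus_id = locus_id, chromosome = chromosome,
              rearrangement_type = "none", partial = FALSE,
              artifact = FALSE, low_confidence = FALSE,
              ambiguity_width = 0L, cnv = NULL, inversion = NULL,
              nested = NULL, blocks = blocks, a_gap = 0L, b_gap = 0L,
              a_length = 0L, b_length = 0L, removed_length = 0L)
  class(out) <- "indel_call"
  fb <- blocks[blocks$orientation == "forward", , drop = FALSE]
  if (!nrow(fb)) {
    out$partial <- TRUE
    return(out)
  }
  li <- which.min(fb$a_start)
  ri <- which.max(fb$a_end)
  left <- fb[li, ]; right <- fb[ri, ]
  if (li == ri) {
    # single block: identical loci (or one-sided anchor only)
    covers <- left$a_start <= min_block &&
      left$a_end >= nchar(locus_a) - min_block + 1L
    out$partial <- !covers
    out$breakpoint5 <- c(a = left$a_end + a_offset, b = left$b_end + b_offset)
    out$breakpoint3 <- c(a = left$a_end + a_offset, b = left$b_end + b_offset)
    return(out)
  }
  bp5 <- c(a = left$a_end, b = left$b_end)
  bp3 <- c(a = right$a_start, b = right$b_start)
  a_gap <- bp3["a"] - bp5["a"] - 1L
  b_gap <- bp3["b"] - bp5["b"] - 1L
  amb <- max(0L, -min(a_gap, b_gap))
  out$a_gap <- unname(a_gap); out$b_gap <- unname(b_gap)
  out$ambiguity_width <- as.integer(amb)
  out$a_length <- max(0L, a_gap)
  out$b_length <- max(0L, b_gap)
  out$removed_length <- max(0L, a_gap) + max(0L, -b_gap)
  # inversion: reverse-orientation blocks strictly between the anchors on
  # BOTH genomes, covering most of both gaps (a reverse-strand element that
  # is simply absent from the derived locus does not qualify)
  slop <- 30L   # border-anchoring slack at the anchor/inversion junctions
  rv <- blocks[blocks$orientation == "reverse" &
                 blocks$a_start > bp5["a"] - slop &
                 blocks$a_end < bp3["a"] + slop &
                 blocks$b_start > bp5["b"] - slop &
                 blocks$b_end < bp3["b"] + slop, , drop = FALSE]
  inv <- detect_inversion(rv)
  if (!is.null(inv)) {
    span_a <- inv$a_interval[2] - inv$a_interval[1] + 1L
    span_b <- inv$b_interval[2] - inv$b_interval[1] + 1L
    if (a_gap < 2L * min_block || b_gap < 2L * min_block ||
        span_a < 0.5 * a_gap || span_b < 0.5 * b_gap)
      inv <- NULL
  }
  if (!is.null(inv)) {
    out$rearrangement_type <- "inversion"
    out$inversion <- inv
    out$inversion$a_interval <- inv$a_interval + a_offset
    out$inversion$b_interval <- inv$b_interval + b_offset
    # nested events inside the inverted segment
    sub_a <- substr_(locus_a, inv$a_interval[1], inv$a_interval[2])
    sub_b <- revcomp(substr_(locus_b, inv$b_interval[1], inv$b_interval[2]))
    if (nchar(sub_a) >= 4L * min_block && nchar(sub_b) >= 4L * min_block) {
      nested <- call_indel(sub_a, sub_b, min_block, min_identity,
                           junction_remnant_bound, cnv_min_unit,
                           locus_id = paste0(locus_id, "_nested"))
      if (nested$rearrangement_type != "none") out$nested <- nested
    }
  }
  # N-abutting breakpoints: likely assembly artifact
  njunc <- function(seq, p, w = 100L) {
    s <- substr_(seq, max(1L, p - w), min(nchar(seq), p + w))
    grepl("NNNNN", s, fixed = TRUE)
  }
  if (njunc(locus_a, bp5["a"]) || njunc(locus_a, bp3["a"]) ||
      njunc(locus_b, bp5["b"]) || njunc(locus_b, bp3["b"])) {
    out$artifact <- TRUE
    out$low_confidence <- TRUE
  }
  if (out$rearrangement_type == "none") {
    if (amb >= cnv_min_unit) {
      cnv <- detect_copy_number_variation(locus_a, locus_b, min_block,
                                          min_identity, locus_id = locus_id)
      if (!is.null(cnv) && cnv$copies_a != cnv$copies_b) {
        out$rearrangement_type <- "copy_number_variation"
        cnv$unit_interval_a <- cnv$unit_interval_a + a_offset
        out$cnv <- cnv
      }
    }
    if (out$rearrangement_type == "none") {
      if (a_gap <= 0 && b_gap <= 0 && amb < cnv_min_unit &&
          a_gap == b_gap) {
        out$rearrangement_type <- "none"
      } else if (b_gap <= junction_remnant_bound) {
        out$rearrangement_type <- if (out$removed_length > 0) "deletion_in_b"
                                  else "none"
      } else {
        # homology-based rule first: a long derived-side remnant that is
        # homologous to the donor flanks marks a deletion, not a replacement
        remnant <- substr_(locus_b, bp5["b"] + 1L, bp3["b"] - 1L)
        hb <- find_similarity_blocks(remnant, locus_a, min_block,
                                     min_identity, both_strands = TRUE)
        cov <- if (nrow(hb)) covered_width(hb$a_start, hb$a_end) else 0L
        out$rearrangement_type <-
          if (cov >= 0.5 * nchar(remnant)) "deletion_in_b" else "replacement"
      }
    }
  }
  out$breakpoint5 <- c(a = unname(bp5["a"]) + a_offset,
                       b = unname(bp5["b"]) + b_offset)
  out$breakpoint3 <- c(a = unname(bp3["a"]) + a_offset,
                       b = unname(bp3["b"]) + b_offset)
  out$a_interval <- c(out$breakpoint5["a"] + 1L, out$breakpoint3["a"] - 1L)
  out$b_interval <- c(out$breakpoint5["b"] + 1L, out$breakpoint3["b"] - 1L)
  out
}

covered_width <- function(starts, ends) {
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(starts, ends))))
}

#' Detect tandem copy-number variation between two loci
#'
#' Repeat-unit borders are taken from the off-diagonal blocks of each locus
#' against itself (the self dot plot); copy numbers are one plus the number
#' of distinct tandem offsets. Borders from the self plot and the cross plot
#' agree within the junction ambiguity by construction.
#'
#' @param locus_a,locus_b locus sequences including the full repeat array
#'   plus flanks.
#' @param min_length,min_identity block thresholds.
#' @param locus_id identifier.
#' @return a \code{cnv_call} list: \code{locus_id}, \code{unit_interval_a},
#'   \code{unit_length}, \code{copies_a}, \code{copies_b},
#'   \code{unit_identity}; copies are 1/1 when no tandem repeat is found.
#' @export
detect_copy_number_variation <- function(locus_a, locus_b, min_length = 100,
                                         min_identity = 0.95,
                                         locus_id = "locus") {
  tand <- function(seq) {
    sb <- self_repeat_blocks(seq, min_length, min_identity)
    sb <- sb[sb$orientation == "forward", , drop = FALSE]
    if (!nrow(sb)) return(NULL)
    sb$offset <- sb$b_start - sb$a_start
    sb <- sb[sb$offset > 0, , drop = FALSE]
    if (!nrow(sb)) return(NULL)
    # group blocks by diagonal offset (a split high-identity match still
    # belongs to one repeat pairing), then keep tandem-adjacent groups:
    # offset no larger than ~the covered unit span
    sb$group <- round(sb$offset / (min_length / 2))
    groups <- split(sb, sb$group)
    rows <- lapply(groups, function(g) {
      span <- covered_width(g$a_start, g$a_end)
      data.frame(offset = g$offset[which.max(g$length)],
                 a_start = min(g$a_start), a_end = max(g$a_end),
                 span = span,
                 identity = sum(g$identity * g$length) / sum(g$length))
    })
    gr <- do.call(rbind, rows)
    gr <- gr[gr$offset <= 1.25 * (gr$span + min_length), , drop = FALSE]
    if (!nrow(gr)) return(NULL)
    gr
  }
  sa <- tand(locus_a); sbk <- tand(locus_b)
  n_copies <- function(g) {
    if (is.null(g)) return(1L)
    base <- min(g$offset)
    1L + length(unique(pmax(1L, round(g$offset / base))))
  }
  copies_a <- n_copies(sa); copies_b <- n_copies(sbk)
  if (is.null(sa) && is.null(sbk)) {
    return(list(locus_id = locus_id, unit_interval_a = c(NA, NA),
                unit_length = NA_integer_, copies_a = 1L, copies_b = 1L,
                unit_identity = NA_real_))
  }
  main <- if (!is.null(sa)) sa[which.min(sa$offset), ]
          else sbk[which.min(sbk$offset), ]
  unit <- c(main$a_start, main$a_start + main$offset - 1L)
  structure(list(locus_id = locus_id, unit_interval_a = unit,
                 unit_length = main$offset, copies_a = copies_a,
                 copies_b = copies_b, unit_identity = main$identity),
            class = "cnv_call")
}

#' Detect an inversion from a block set
#'
#' A maximal run of reverse-orientation blocks that are collinear in
#' reversed order (a-intervals ascending while b-intervals descend) marks an
#' inverted segment; its interval on both genomes is returned.
#'
#' @param blocks data.frame of similarity blocks (as returned by
#'   \code{\link{find_similarity_blocks}}).
#' @return list(\code{a_interval}, \code{b_interval}, \code{n_blocks}) or
#'   \code{NULL} when no reverse-orientation blocks are present.
#' @export
detect_inversion <- function(blocks) {
  rv <- blocks[blocks$orientation == "reverse", , drop = FALSE]
  if (!nrow(rv)) return(NULL)
  rv <- rv[order(rv$a_start), , drop = FALSE]
  # longest run with descending b intervals
  best <- c(1L, 1L); cur <- 1L
  if (nrow(rv) > 1) {
    runs <- list(); start <- 1L
    for (i in 2:nrow(rv)) {
      if (rv$b_end[i] > rv$b_start[i - 1]) {   # not descending: break run
        runs[[length(runs) + 1L]] <- c(start, i - 1L)
        start <- i
      }
    }
    runs[[length(runs) + 1L]] <- c(start, nrow(rv))
    spans <- vapply(runs, function(r)
      sum(rv$length[r[1]:r[2]]), numeric(1))
    best <- runs[[which.max(spans)]]
  }
  sel <- rv[best[1]:best[2], , drop = FALSE]
  list(a_interval = c(min(sel$a_start), max(sel$a_end)),
       b_interval = c(min(sel$b_start), max(sel$b_end)),
       n_blocks = nrow(sel))
}
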