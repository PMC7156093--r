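#' Read an annotation track (BED or GFF3)
#'
#' BED input (0-based half-open) is converted to the internal 1-based closed
#' convention at this boundary; GFF3 is read via \pkg{rtracklayer} when
#' available. The track is a data.frame with columns \code{chrom},
#'   \code{start}, \code{end}, \code{name}, \code{class}, \code{strand},
#' sorted by chromosome and start.
#'
#' @param path file path (.bed, .gff, .gff3).
#' @param format "bed", "gff3", or NULL to infer from the extension.
#' @param classes optional feature-class filter (GFF3 type / BED name prefix
#'   kept as-is; default keeps all).
#' @return annotation track data.frame.
#' @export
read_annotation_track <- function(path, format = NULL, classes = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else "gff3"
  }
  if (format == "bed") {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, comment.char = "#")
    tr <- data.frame(chrom = df[[1]], start = df[[2]] + 1L, end = df[[3]],
                     name = if (ncol(df) >= 4) df[[4]] else ".",
                     class = if (ncol(df) >= 4) df[[4]] else ".",
                     strand = if (ncol(df) >= 6) df[[6]] else "*",
                     stringsAsFactors = FALSE)
  } else {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      g <- rtracklayer::import(path, format = "gff3")
      nm <- if (!is.null(g$Name)) as.character(g$Name)
            else if (!is.null(g$ID)) as.character(g$ID) else "."
      tr <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                       start = GenomicRanges::start(g),
                       end = GenomicRanges::end(g),
                       name = nm, class = as.character(g$type),
                       strand = as.character(GenomicRanges::strand(g)),
                       stringsAsFactors = FALSE)
    } else {
      df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                       stringsAsFactors = FALSE, quote = "")
      tr <- data.frame(chrom = df[[1]], start = df[[4]], end = df[[5]],
                       name = sub(".*(Name|ID)=([^;]+).*", "\\2", df[[9]]),
                       class = df[[3]], strand = df[[7]],
                       stringsAsFactors = FALSE)
    }
  }
  if (!is.null(classes)) tr <- tr[tr$class %in% classes, , drop = FALSE]
  tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
  rownames(tr) <- NULL
  tr
}

# Simulator TE annotation -> annotation track.
sim_te_track <- function(te_annotation) {
  if (is.null(te_annotation)) return(NULL)
  ann <- te_annotation[te_annotation$part %in% c("complete", "LTR",
                                                 "repeat"), , drop = FALSE]
  data.frame(chrom = ann$chrom, start = ann$start, end = ann$end,
             name = ann$name, class = ann$family, strand = ann$strand,
             stringsAsFactors = FALSE)
}

#' TE content of an interval
#'
#' Percentage of interval bases covered by the union of overlapping track
#' features (clipped to the interval), reported to two decimals, e.g. a
#' segment consisting of 71.49\% TEs.
#'
#' @param interval c(start, end), 1-based closed.
#' @param track annotation track (see \code{\link{read_annotation_track}}).
#' @param chromosome chromosome of the interval (filtered against the track
#'   when the track carries chromosome names).
#' @return numeric percentage in \[0, 100\], rounded to two decimals.
#' @export
te_content <- function(interval, track, chromosome = NULL) {
  len <- interval_length(interval[1], interval[2])
  if (is.null(track) || !nrow(track)) return(0)
  if (!is.null(chromosome))
    track <- track[track$chrom == chromosome, , drop = FALSE]
  s <- pmax(track$start, interval[1])
  e <- pmin(track$end, interval[2])
  keep <- e >= s
  if (!any(keep)) return(0)
  cov <- covered_width(s[keep], e[keep])
  round(100 * cov / len, 2)
}

#' Annotation context of a breakpoint
#'
#' The feature containing the position, or the nearest feature within the
#' window, with intactness judged against the family consensus length when
#' one is provided (a breakpoint inside a much-shorter-than-consensus copy
#' sits in a truncated element).
#'
#' @param position 1-based breakpoint position.
#' @param track annotation track.
#' @param chromosome chromosome name.
#' @param window nearest-feature search distance, bases.
#' @param consensus_lengths named numeric vector of family consensus
#'   lengths (names matching track \code{class}).
#' @param tolerance boundary tolerance for intactness, bases.
#' @return list(\code{feature}, \code{class}, \code{distance},
#'   \code{status}) or NULL when no feature lies within the window.
#' @export
breakpoint_context <- function(position, track, chromosome = NULL,
                               window = 1000, consensus_lengths = NULL,
                               tolerance = 20) {
  if (is.null(track) || !nrow(track)) return(NULL)
  if (!is.null(chromosome))
    track <- track[track$chrom == chromosome, , drop = FALSE]
  if (!nrow(track)) return(NULL)
  d <- ifelse(track$start > position, track$start - position,
              ifelse(track$end < position, position - track$end, 0L))
  i <- which.min(d)
  if (d[i] > window) return(NULL)
  status <- NA_character_
  if (!is.null(consensus_lengths) &&
      track$class[i] %in% names(consensus_lengths)) {
    flen <- track$end[i] - track$start[i] + 1L
    status <- if (flen >= consensus_lengths[[track$class[i]]] -
                  2 * tolerance) "intact" else "truncated"
  }
  list(feature = track$name[i], class = track$class[i],
       distance = as.integer(d[i]), status = status)
}
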