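#' Pipeline parameters
#'
#' Collected tunables for \code{\link{run_pipeline}}, with the thresholds
#' used throughout: 500-bp retrieval flanks, 20-base end-mismatch tolerance,
#' 100-bp/95\%-identity similarity blocks for breakpoints, geometric
#' chromosome-walk schedule up to 5 Mb.
#'
#' @param flank retrieval flank size, bases.
#' @param end_mismatch_tolerance element-boundary tolerance, bases.
#' @param significance_cutoff retrieval expectation cutoff.
#' @param retrieval_min_identity,retrieval_min_block retrieval block
#'   thresholds.
#' @param flank_match_cutoff cross-genome flank-match score cutoff.
#' @param walk_step,walk_max_extent chromosome-walk schedule, bases.
#' @param min_block,min_identity breakpoint block thresholds ("word size"
#'   and repeat identity).
#' @param junction_remnant_bound deletion vs replacement bound, bases.
#' @param replacement_min smallest insert called a replacement, bases.
#' @param artifact_window N-run distance defining assembly artifacts, bases.
#' @param sdmmej_window SD-MMEJ primer-repeat search window, bases.
#' @param locus_pad flanking context added around called loci, bases.
#' @return named list of parameters.
#' @export
pipeline_params <- function(flank = 500, end_mismatch_tolerance = 20,
                            significance_cutoff = 1e-3,
                            retrieval_min_identity = 0.85,
                            retrieval_min_block = 80,
                            flank_match_cutoff = 300,
                            walk_step = 5000, walk_max_extent = 5e6,
                            min_block = 100, min_identity = 0.95,
                            junction_remnant_bound = 100,
                            replacement_min = 1000,
                            artifact_window = 100, sdmmej_window = 35,
                            locus_pad = 3000) {
  as.list(environment())
}

#' Run the full rearrangement-discovery pipeline
#'
#' Orchestrates all stages on a genome pair: retrieve TE insertions from
#' both genomes, match them across genomes by flank similarity, locate
#' orthologous loci of the unmatched (candidate species-specific)
#' insertions by chromosome walking, classify each polymorphism source, call
#' indel breakpoints / copy-number variation / inversions at the borders of
#' similarity blocks, classify every junction by its repair mechanism, and
#' annotate TE content and breakpoint context. Assembly-artifact loci are
#' routed to an exclusion report instead of the indel table.
#'
#' @param genome_a,genome_b named character vectors (or FASTA paths).
#' @param consensus a \code{\link{te_consensus}}.
#' @param te_annotation optional annotation track (data.frame as from
#'   \code{\link{read_annotation_track}}, or a simulator TE annotation).
#' @param reference_genomes optional list of genomes for the introgression
#'   check.
#' @param outdir optional output directory for TSV/BED/JSON reports and the
#'   run log.
#' @param params see \code{\link{pipeline_params}}.
#' @param verbose log progress to stderr.
#' @return a \code{pipeline_report} list: \code{summary} (one row per
#'   characterized locus: coordinates and lengths on both genomes,
#'   rearrangement type, mechanism, TE content, breakpoint context),
#'   \code{exclusions}, \code{insertions_a}, \code{insertions_b},
#'   \code{matches}, \code{polymorphisms}, \code{calls} (full
#'   \code{indel_call}s), \code{signatures}, \code{params}.
#' @export
run_pipeline <- function(genome_a, genome_b, consensus,
                         te_annotation = NULL, reference_genomes = list(),
                         outdir = NULL, params = pipeline_params(),
                         verbose = FALSE) {
  t_start <- Sys.time()
  log_lines <- character(0)
  logmsg <- function(stage, ...) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    stage, sprintf(...))
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  run_stage <- function(stage, locus, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed at locus '%s': %s", stage, locus,
            conditionMessage(e)))
  }
  if (is.character(genome_a) && length(genome_a) == 1 &&
      file.exists(genome_a)) genome_a <- read_fasta(genome_a)
  if (is.character(genome_b) && length(genome_b) == 1 &&
      file.exists(genome_b)) genome_b <- read_fasta(genome_b)
  if (!is.null(te_annotation) && "part" %in% names(te_annotation))
    te_track <- sim_te_track(te_annotation)
  else te_track <- te_annotation
  logmsg("config", "thresholds: block %d bp at %.2f identity; flanks %d bp",
         params$min_block, params$min_identity, params$flank)

  logmsg("retrieve", "genome A (%d chromosomes)", length(genome_a))
  ins_a <- run_stage("retrieve", "genome_a", retrieve_insertions(
    genome_a, consensus, params$significance_cutoff,
    params$end_mismatch_tolerance, params$flank,
    params$retrieval_min_identity, params$retrieval_min_block))
  logmsg("retrieve", "genome B")
  ins_b <- run_stage("retrieve", "genome_b", retrieve_insertions(
    genome_b, consensus, params$significance_cutoff,
    params$end_mismatch_tolerance, params$flank,
    params$retrieval_min_identity, params$retrieval_min_block))
  logmsg("retrieve", "%d insertions in A, %d in B", nrow(ins_a), nrow(ins_b))

  matches <- run_stage("compare", "all", match_insertions_across_genomes(
    ins_a, ins_b, params$flank_match_cutoff))
  logmsg("compare", "%d pairs, %d A-specific, %d B-specific, %d CNV-review",
         nrow(matches$pairs), length(matches$unmatched_a),
         length(matches$unmatched_b), nrow(matches$cnv_review))

  polymorphisms <- list(); calls <- list(); signatures <- list()
  summary_rows <- NULL; exclusion_rows <- NULL
  claimed <- list()  # per-chromosome claimed A intervals (dedup)
  overlaps_claimed <- function(ch, iv) {
    if (is.null(claimed[[ch]])) return(FALSE)
    any(claimed[[ch]][, 1] <= iv[2] & claimed[[ch]][, 2] >= iv[1])
  }
  claim <- function(ch, iv) claimed[[ch]] <<- rbind(claimed[[ch]], iv)

  # --- tandem copy-number variation from supernumerary flank matches ------
  if (nrow(matches$cnv_review)) {
    for (r in seq_len(nrow(matches$cnv_review))) {
      loser <- matches$cnv_review$a_id[r]
      b_id <- matches$cnv_review$b_id[r]
      winner <- matches$pairs$a_id[matches$pairs$b_id == b_id][1]
      ra <- ins_a[ins_a$id %in% c(loser, winner), , drop = FALSE]
      rb <- ins_b[ins_b$id == b_id, , drop = FALSE]
      ch <- ra$chromosome[1]
      span <- max(ra$end) - min(ra$start) + 1L
      a1 <- max(1L, min(ra$start) - params$locus_pad)
      a2 <- min(nchar(genome_a[[ch]]), max(ra$end) + params$locus_pad)
      b1 <- max(1L, rb$start[1] - span - params$locus_pad)
      b2 <- min(nchar(genome_b[[rb$chromosome[1]]]),
                rb$end[1] + span + params$locus_pad)
      lid <- sprintf("cnv_%s", loser)
      ic <- run_stage("callindels", lid, call_indel(
        substr_(genome_a[[ch]], a1, a2),
        substr_(genome_b[[rb$chromosome[1]]], b1, b2),
        params$min_block, params$min_identity,
        params$junction_remnant_bound, locus_id = lid,
        a_offset = a1 - 1L, b_offset = b1 - 1L, chromosome = ch))
      calls[[lid]] <- ic
      if (!overlaps_claimed(ch, c(a1, a2))) {
        claim(ch, c(a1, a2))
        sig <- classify_mechanism(ic, genome_a, genome_b, te_annotation,
                                  reference_genomes,
                                  sdmmej_window = params$sdmmej_window)
        signatures[[lid]] <- sig
        summary_rows <- rbind(summary_rows, summarize_locus(
          lid, ch, ic, sig, te_track, consensus))
        logmsg("callindels", "%s: copy number %s/%s", lid,
               if (!is.null(ic$cnv)) ic$cnv$copies_a else NA,
               if (!is.null(ic$cnv)) ic$cnv$copies_b else NA)
      }
    }
  }

  # --- A-specific insertions: walk, classify polymorphism, call indels ---
  for (aid in matches$unmatched_a) {
    ins <- ins_a[ins_a$id == aid, ]
    anchor <- list(chromosome = ins$chromosome, start = ins$start,
                   end = ins$end)
    walk <- run_stage("walk", aid, chromosome_walk(
      genome_a, anchor, genome_b, step = params$walk_step,
      max_extent = params$walk_max_extent,
      min_block = params$min_block, min_identity = params$min_identity))
    pc <- run_stage("classify_polymorphism", aid, classify_polymorphism(
      ins, walk, genome_a, genome_b, consensus,
      params$artifact_window, params$replacement_min,
      params$min_block, params$min_identity))
    polymorphisms[[aid]] <- pc
    logmsg("classify_polymorphism", "%s -> %s", aid, pc$category)
    ic <- pc$indel
    if (is.null(ic) || pc$category == "monomorphic") next
    calls[[aid]] <- ic
    ch <- ins$chromosome
    iv <- c(ic$breakpoint5["a"], ic$breakpoint3["a"])
    if (overlaps_claimed(ch, iv)) next
    claim(ch, iv)
    if (pc$category == "assembly_artifact") {
      exclusion_rows <- rbind(exclusion_rows, data.frame(
        locus_id = aid, chromosome = ch,
        a_start = unname(iv[1]), a_end = unname(iv[2]),
        reason = pc$evidence[1], stringsAsFactors = FALSE))
      next
    }
    sig <- run_stage("classify_junction", aid, classify_mechanism(
      ic, genome_a, genome_b, te_annotation, reference_genomes,
      sdmmej_window = params$sdmmej_window,
      min_intro = params$replacement_min))
    # polymorphism categories with a mechanism of their own take precedence
    if (pc$category == "empty_site_tsd")
      sig$mechanism <- "te_insertion_full_empty"
    if (pc$category %in% c("internal_deletion", "chimeric_deletion"))
      sig$mechanism <- "internal_deletion"
    signatures[[aid]] <- sig
    summary_rows <- rbind(summary_rows,
                          summarize_locus(aid, ch, ic, sig, te_track,
                                          consensus, category = pc$category))
  }

  if (!is.null(summary_rows)) rownames(summary_rows) <- NULL
  report <- structure(list(
    summary = summary_rows, exclusions = exclusion_rows,
    insertions_a = ins_a, insertions_b = ins_b, matches = matches,
    polymorphisms = polymorphisms, calls = calls, signatures = signatures,
    params = params, log = log_lines,
    elapsed = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "pipeline_report")
  logmsg("report", "%d loci in summary, %d excluded",
         if (is.null(summary_rows)) 0L else nrow(summary_rows),
         if (is.null(exclusion_rows)) 0L else nrow(exclusion_rows))
  report$log <- log_lines
  if (!is.null(outdir)) write_pipeline_report(report, outdir)
  report
}

summarize_locus <- function(locus_id, chromosome, ic, sig, te_track,
                            consensus, category = NA_character_) {
  bp5 <- ic$breakpoint5; bp3 <- ic$breakpoint3
  a_iv <- c(bp5["a"] + 1L, max(bp5["a"] + 1L, bp3["a"] - 1L))
  cl <- setNames(nchar(consensus$sequence), consensus$name)
  ctx <- function(p) {
    x <- breakpoint_context(p, te_track, chromosome,
                            consensus_lengths = cl)
    if (is.null(x)) "" else sprintf("%s(%s,%s,d=%d)", x$feature, x$class,
                                    ifelse(is.na(x$status), "?", x$status),
                                    x$distance)
  }
  data.frame(
    locus_id = locus_id, chromosome = chromosome,
    a_start = unname(bp5["a"] + 1L), a_end = unname(bp3["a"] - 1L),
    b_start = unname(bp5["b"] + 1L), b_end = unname(bp3["b"] - 1L),
    a_length = ic$a_length, b_length = ic$b_length,
    removed_length = ic$removed_length,
    ambiguity_width = ic$ambiguity_width,
    rearrangement_type = ic$rearrangement_type,
    category = category,
    mechanism = if (is.null(sig)) NA_character_ else sig$mechanism,
    microhomology = if (is.null(sig)) "" else sig$microhomology,
    net_insertion_length = if (is.null(sig)) 0L else nchar(sig$net_insertion),
    copies_a = if (!is.null(ic$cnv)) ic$cnv$copies_a else NA_integer_,
    copies_b = if (!is.null(ic$cnv)) ic$cnv$copies_b else NA_integer_,
    te_pct = if (!is.null(te_track))
      te_content(a_iv, te_track, chromosome) else NA_real_,
    context5 = ctx(bp5["a"]), context3 = ctx(bp3["a"]),
    low_confidence = ic$low_confidence,
    stringsAsFactors = FALSE)
}

#' Write a pipeline report bundle
#'
#' TSV summary (Table-1-shaped: one row per locus), exclusion report, BED
#' tracks per genome (0-based half-open), JSON detail, and the run log (all
#' parameters, ISO timestamps).
#'
#' @param report a \code{pipeline_report}.
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
write_pipeline_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  hdr <- "# coordinates are 1-based closed; lengths are end - start + 1"
  p <- file.path(outdir, "summary.tsv")
  writeLines(hdr, p)
  if (!is.null(report$summary))
    suppressWarnings(write.table(report$summary, p, sep = "\t",
                                 quote = FALSE, row.names = FALSE,
                                 append = TRUE))
  paths <- c(paths, p)
  p <- file.path(outdir, "exclusions.tsv")
  writeLines(hdr, p)
  if (!is.null(report$exclusions))
    suppressWarnings(write.table(report$exclusions, p, sep = "\t",
                                 quote = FALSE, row.names = FALSE,
                                 append = TRUE))
  paths <- c(paths, p)
  if (!is.null(report$summary)) {
    s <- report$summary
    for (side in c("a", "b")) {
      p <- file.path(outdir, sprintf("loci_%s.bed", toupper(side)))
      write.table(data.frame(s$chromosome, s[[paste0(side, "_start")]] - 1L,
                             pmax(s[[paste0(side, "_end")]],
                                  s[[paste0(side, "_start")]]),
                             s$locus_id, 0L, "+"),
                  p, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
      paths <- c(paths, p)
    }
  }
  p <- file.path(outdir, "report.json")
  detail <- list(summary = report$summary, exclusions = report$exclusions,
                 params = report$params,
                 matches = report$matches[c("pairs", "unmatched_a",
                                            "unmatched_b")])
  jsonlite::write_json(detail, p, auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths <- c(paths, p)
  p <- file.path(outdir, "run.log")
  writeLines(report$log, p)
  paths <- c(paths, p)
  invisible(paths)
}
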