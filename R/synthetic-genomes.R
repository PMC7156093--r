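#' Synthetic TE consensus sequence
#'
#' Builds a desk-scale LTR-retrotransposon consensus: two identical long
#' terminal repeats (LTRs) flanking an internal domain, with i.i.d. random
#' sequence at the requested GC content. Used as the default query element
#' for the simulator and retrieval tests; real consensus sequences (e.g. a
#' 9997-bp gypsy family consensus with 473-bp solo LTR) can be supplied
#' instead via \code{\link{te_consensus}}.
#'
#' @param name consensus name.
#' @param length total element length in bases.
#' @param ltr_length LTR length in bases (must satisfy 2 * ltr_length < length).
#' @param gc GC fraction.
#' @param seed RNG seed used to draw the consensus (kept separate from the
#'   simulation seed so the same element family can recur across configs).
#' @return a \code{te_consensus} object.
#' @export
synthetic_te_consensus <- function(name = "RLG_synth_consensus-1",
                                   length = 3000, ltr_length = 300,
                                   gc = 0.46, seed = 99) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ltr <- random_dna(ltr_length, gc)
  internal <- random_dna(length - 2 * ltr_length, gc)
  te_consensus(name, paste0(ltr, internal, ltr), ltr_length)
}

#' TE consensus constructor
#'
#' @param name consensus name.
#' @param sequence nucleotide string.
#' @param ltr_length optional LTR length in bases; if set it must satisfy
#'   2 * ltr_length < element length.
#' @return a \code{te_consensus} object (list with \code{name},
#'   \code{sequence}, \code{ltr_length}).
#' @export
te_consensus <- function(name, sequence, ltr_length = NULL) {
  sequence <- as_dna_string(sequence)
  if (!is.null(ltr_length) && 2 * ltr_length >= nchar(sequence))
    stopf("te_consensus '%s': 2 * ltr_length must be < consensus length", name)
  structure(list(name = name, sequence = sequence, ltr_length = ltr_length),
            class = "te_consensus")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulation configuration
#'
#' Defines the study conditions for a synthetic genome pair: an ancestral
#' genome carrying TE insertions, from which a derived genome is produced by
#' mechanism-explicit rearrangement events with recorded ground truth. All
#' coordinates are 1-based closed.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length chromosome length in bases; must be at least ten
#'   times the longest event footprint.
#' @param gc_content background GC fraction (wheat-like default 0.46).
#' @param te_library list of \code{\link{te_consensus}} objects; the first is
#'   the anchor family used by events.
#' @param te_copies_per_chromosome standalone (monomorphic) full-length TE
#'   copies planted per chromosome.
#' @param te_mutation_rate per-base substitution rate applied to each planted
#'   copy relative to its consensus, in \[0, 0.2\].
#' @param tsd_length_range integer range (min, max) for target site
#'   duplication lengths.
#' @param event_specs list of \code{\link{event_spec}} templates.
#' @param n_gap_rate extra \code{assembly_artifact} events appended, as a
#'   fraction of \code{length(event_specs)}.
#' @param seed integer seed; a fixed seed makes all outputs byte-identical.
#' @return a \code{sim_config} object.
#' @export
sim_config <- function(n_chromosomes = 1, chromosome_length = 200000,
                       gc_content = 0.46,
                       te_library = list(synthetic_te_consensus()),
                       te_copies_per_chromosome = 8,
                       te_mutation_rate = 0.02,
                       tsd_length_range = c(4, 6),
                       event_specs = list(),
                       n_gap_rate = 0,
                       seed = 1) {
  stopifnot(gc_content >= 0, gc_content <= 1,
            te_mutation_rate >= 0, te_mutation_rate <= 0.2,
            length(tsd_length_range) == 2)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 gc_content = gc_content, te_library = te_library,
                 te_copies_per_chromosome = as.integer(te_copies_per_chromosome),
                 te_mutation_rate = te_mutation_rate,
                 tsd_length_range = as.integer(tsd_length_range),
                 event_specs = event_specs, n_gap_rate = n_gap_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Rearrangement event template
#'
#' Describes one rearrangement to plant between the ancestral (A) and derived
#' (B) genome. Required motifs (microhomologies, primer repeats, direct
#' repeats, tandem units, TSDs) are written into the ancestor by
#' \code{\link{make_ancestor}} and recorded in the finalized event.
#'
#' @param microhomology explicit MMEJ microhomology sequence (overrides
#'   \code{microhomology_length}).
#' @param mechanism one of \code{"unequal_recombination"},
#'   \code{"ltr_recombination"}, \code{"mmej"}, \code{"sdmmej"},
#'   \code{"blunt"}, \code{"tandem_duplication"}, \code{"introgression"},
#'   \code{"te_insertion_full_empty"}, \code{"inversion"},
#'   \code{"internal_deletion"}, \code{"assembly_artifact"}.
#' @param event_id optional identifier (auto-generated if missing).
#' @param chromosome optional chromosome index to place the event on.
#' @param deletion_length length of the deleted core segment (deletion-class
#'   mechanisms); it always contains a full TE copy of the anchor family so
#'   the deletion is discoverable from insertion polymorphism.
#' @param microhomology_length MMEJ microhomology length (1-9).
#' @param repeat_length,repeat_identity flanking direct-repeat parameters for
#'   unequal recombination.
#' @param primer_length,net_insertion_length,mh_length,synthesis_rounds
#'   SD-MMEJ junction parameters (primer repeat, templated net insertion,
#'   junction microhomology, 1 or 2 rounds).
#' @param unit_length,unit_identity tandem-duplication unit parameters.
#' @param insert_length introgressed-segment length.
#' @param span inverted-segment length (inversion).
#' @param internal_deletion_length bases removed from the element interior.
#' @param n_length length of the N run for assembly artifacts.
#' @param tsd_length optional TSD length (otherwise drawn from the configured
#'   range).
#' @return an \code{event_spec} object.
#' @export
event_spec <- function(mechanism,
                       event_id = NULL, chromosome = NULL,
                       deletion_length = 5000,
                       microhomology = NULL, microhomology_length = 4,
                       repeat_length = 300, repeat_identity = 0.99,
                       primer_length = 2, net_insertion_length = 4,
                       mh_length = 3, synthesis_rounds = 1,
                       unit_length = 6000, unit_identity = 0.99,
                       insert_length = 2500, span = 8000,
                       internal_deletion_length = 1200,
                       n_length = 500, tsd_length = NULL) {
  mech <- match.arg(mechanism, c(
    "unequal_recombination", "ltr_recombination", "mmej", "sdmmej", "blunt",
    "tandem_duplication", "introgression", "te_insertion_full_empty",
    "inversion", "internal_deletion", "assembly_artifact"))
  mechanism <- mech
  if (!is.null(microhomology)) microhomology_length <- nchar(microhomology)
  if (mech == "mmej" &&
      (microhomology_length < 1 || microhomology_length > 9))
    stopf("mmej microhomology length must be 1-9")
  if (mech == "unequal_recombination" &&
      (repeat_length < 100 || repeat_identity < 0.95))
    stopf("unequal_recombination requires repeats >= 100 bp at >= 95%% identity")
  structure(as.list(environment()), class = "event_spec")
}

#' Event templates for a full mechanism suite
#'
#' One deletion-class or structural event per repair mechanism, repeated
#' \code{n_per_mechanism} times: unequal intra-strand recombination,
#' inter-element LTR recombination, MMEJ, SD-MMEJ, blunt joining, tandem
#' duplication, and introgression. The standard validation workload for
#' end-to-end mechanism recovery.
#'
#' @param n_per_mechanism events per mechanism.
#' @return list of \code{\link{event_spec}} templates, mechanism-interleaved
#'   so round-robin placement spreads mechanisms across chromosomes.
#' @export
mechanism_suite_specs <- function(n_per_mechanism = 6) {
  mechs <- c("unequal_recombination", "ltr_recombination", "mmej", "sdmmej",
             "blunt", "tandem_duplication", "introgression")
  unlist(lapply(seq_len(n_per_mechanism), function(i)
    lapply(mechs, event_spec)), recursive = FALSE)
}

#' Generate the ancestral genome
#'
#' Draws i.i.d. background sequence, plants standalone TE copies (with TSDs
#' and per-copy divergence from consensus) and the structures each event
#' template requires, and finalizes every event with absolute coordinates.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{sim_ancestor} list: \code{genome} (named character vector
#'   of chromosome sequences), \code{te_annotation} and
#'   \code{repeat_annotation} data.frames, \code{events} (finalized
#'   \code{rearrangement_event} list), \code{config}.
#' @export
make_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cons <- config$te_library[[1]]
  specs <- config$event_specs
  n_art <- round(config$n_gap_rate * length(specs))
  if (n_art > 0)
    specs <- c(specs, replicate(n_art, event_spec("assembly_artifact"),
                                simplify = FALSE))
  # assign events to chromosomes round-robin unless pinned
  chrom_of <- integer(length(specs))
  free <- which(vapply(specs, function(s) is.null(s$chromosome), logical(1)))
  pin <- setdiff(seq_along(specs), free)
  for (i in pin) chrom_of[i] <- specs[[i]]$chromosome
  if (length(free))
    chrom_of[free] <- rep_len(seq_len(config$n_chromosomes), length(free))
  genome <- character(config$n_chromosomes)
  names(genome) <- paste0("chr", seq_len(config$n_chromosomes))
  te_ann <- NULL; rep_ann <- NULL; events <- list()
  copy_counter <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    idx <- which(chrom_of == ci)
    structs <- vector("list", length(idx) + config$te_copies_per_chromosome)
    for (j in seq_along(idx)) {
      structs[[j]] <- build_event_struct(specs[[idx[j]]], cons, config,
                                         sprintf("ev%02d_%s", idx[j],
                                                 specs[[idx[j]]]$mechanism))
    }
    for (j in seq_len(config$te_copies_per_chromosome)) {
      copy_counter <- copy_counter + 1L
      structs[[length(idx) + j]] <-
        build_te_struct(cons, config, sprintf("te_copy_%03d", copy_counter))
    }
    placed <- place_structs(structs, config, names(genome)[ci])
    genome[ci] <- placed$seq
    te_ann <- rbind(te_ann, placed$te)
    rep_ann <- rbind(rep_ann, placed$repeats)
    events <- c(events, placed$events)
  }
  validate_event_overlaps(events)
  structure(list(genome = genome, te_annotation = te_ann,
                 repeat_annotation = rep_ann, events = events,
                 config = config),
            class = "sim_ancestor")
}

validate_event_overlaps <- function(events) {
  if (length(events) < 2) return(invisible(TRUE))
  df <- do.call(rbind, lapply(events, function(e)
    data.frame(id = e$event_id, chrom = e$chromosome,
               start = e$a_interval[1], end = e$a_interval[2])))
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    bad <- which(d$start[-1] <= d$end[-nrow(d)])
    if (length(bad))
      stopf("events collide on %s: %s", ch,
            paste(unique(c(d$id[bad], d$id[bad + 1])), collapse = ", "))
  }
  invisible(TRUE)
}

# ---- structure builders ----------------------------------------------------

# Mutated TE copy with TSDs. Returns seq = tsd te tsd plus relative annotation.
te_with_tsd <- function(cons, rate, tsd_len, id, strand = "+") {
  mut <- mutate_seq(cons$sequence, rate)
  el <- if (strand == "+") mut$seq else revcomp(mut$seq)
  tsd <- random_dna(tsd_len, 0.5)
  list(seq = paste0(tsd, el, tsd), tsd = tsd,
       te_rel = c(tsd_len + 1L, tsd_len + nchar(el)),
       divergence = mut$n_sub / nchar(cons$sequence),
       strand = strand, id = id)
}

# Deletion core of the requested length containing one full TE copy.
deletion_core <- function(len, cons, cfg, id) {
  tsd_len <- sample(cfg$tsd_length_range[1]:cfg$tsd_length_range[2], 1L)
  te <- te_with_tsd(cons, cfg$te_mutation_rate, tsd_len, id,
                    strand = sample(c("+", "-"), 1L))
  core_len <- nchar(te$seq)
  if (len < core_len + 200L)
    stopf("deletion_length %d too small for a TE copy (%d bp + margin)",
          len, core_len)
  left <- random_dna(floor((len - core_len) / 2), cfg$gc_content)
  right <- random_dna(len - core_len - nchar(left), cfg$gc_content)
  list(seq = paste0(left, te$seq, right),
       te_rel = te$te_rel + nchar(left), te = te)
}

# Force the first/last character of a segment to differ from given characters.
force_char_ne <- function(seq, pos, avoid) {
  ch <- substr(seq, pos, pos)
  if (!(ch %in% avoid)) return(seq)
  repl <- setdiff(c("A", "C", "G", "T"), avoid)
  substr(seq, pos, pos) <- sample(repl, 1L)
  seq
}

te_ann_rows <- function(te, offset, cons, id) {
  s <- te$te_rel[1] + offset; e <- te$te_rel[2] + offset
  rows <- data.frame(start = s, end = e, strand = te$strand,
                     name = id, family = cons$name, part = "complete",
                     divergence = te$divergence, tsd = te$tsd,
                     stringsAsFactors = FALSE)
  if (!is.null(cons$ltr_length)) {
    l <- cons$ltr_length
    rows <- rbind(rows,
      data.frame(start = s, end = s + l - 1L, strand = te$strand,
                 name = paste0(id, "_LTR5"), family = cons$name, part = "LTR",
                 divergence = te$divergence, tsd = "", stringsAsFactors = FALSE),
      data.frame(start = e - l + 1L, end = e, strand = te$strand,
                 name = paste0(id, "_LTR3"), family = cons$name, part = "LTR",
                 divergence = te$divergence, tsd = "", stringsAsFactors = FALSE))
  }
  rows
}

# Each builder returns list(seq, truth, te (rel rows), repeats (rel rows)).
# Coordinates inside `truth` are relative to the structure start (1-based);
# place_structs() converts to absolute. `truth$deletion_rel` is the interval
# absent from the derived genome (leftmost placement).
build_te_struct <- function(cons, cfg, id) {
  tsd_len <- sample(cfg$tsd_length_range[1]:cfg$tsd_length_range[2], 1L)
  te <- te_with_tsd(cons, cfg$te_mutation_rate, tsd_len, id,
                    strand = sample(c("+", "-"), 1L))
  list(seq = te$seq, truth = NULL, te = te_ann_rows(te, 0L, cons, id),
       repeats = NULL)
}

build_event_struct <- function(spec, cons, cfg, id) {
  builder <- switch(spec$mechanism,
    mmej = build_mmej, blunt = build_blunt, sdmmej = build_sdmmej,
    unequal_recombination = build_unequal, ltr_recombination = build_ltrrec,
    te_insertion_full_empty = build_full_empty,
    internal_deletion = build_internal_del,
    assembly_artifact = build_artifact,
    tandem_duplication = build_tandem, introgression = build_introgression,
    inversion = build_inversion)
  out <- builder(spec, cons, cfg, id)
  out$truth$event_id <- id
  out$truth$mechanism <- spec$mechanism
  out
}

new_truth <- function(...) {
  t <- list(microhomology = "", net_insertion = "", primer_repeat = "",
            synthesis_rounds = 0L, repeat_unit_length = NA_integer_,
            tsd = "", ambiguity_width = 0L)
  utils::modifyList(t, list(...))
}

first_char <- function(x) substr(x, 1L, 1L)
last_char <- function(x) substr(x, nchar(x), nchar(x))

# The guard_*_ne truth fields name characters the adjacent background (or
# replacement sequence) must avoid so that the recorded deletion placement is
# leftmost and junction borders cannot slide by chance matches.
build_mmej <- function(spec, cons, cfg, id) {
  mh <- if (!is.null(spec$microhomology)) spec$microhomology
        else random_dna(spec$microhomology_length, 0.5)
  core <- deletion_core(spec$deletion_length, cons, cfg, id)
  d <- core$seq
  seq <- paste0(mh, d, mh)
  nmh <- nchar(mh)
  truth <- new_truth(
    microhomology = mh, ambiguity_width = nmh,
    deletion_rel = c(1L, nmh + nchar(d)),
    guard_left_ne = c(last_char(d), last_char(mh)),
    guard_right_ne = c(first_char(d), first_char(mh)))
  list(seq = seq, truth = truth,
       te = te_ann_rows(core$te, nmh + (core$te_rel[1] - core$te$te_rel[1]),
                        cons, id),
       repeats = NULL)
}

build_blunt <- function(spec, cons, cfg, id) {
  core <- deletion_core(spec$deletion_length, cons, cfg, id)
  truth <- new_truth(deletion_rel = c(1L, nchar(core$seq)),
                     ambiguity_width = 0L,
                     guard_left_ne = last_char(core$seq),
                     guard_right_ne = first_char(core$seq))
  list(seq = core$seq, truth = truth,
       te = te_ann_rows(core$te, core$te_rel[1] - core$te$te_rel[1], cons, id),
       repeats = NULL)
}

build_unequal <- function(spec, cons, cfg, id) {
  r1 <- random_dna(spec$repeat_length, cfg$gc_content)
  r2 <- mutate_seq(r1, 1 - spec$repeat_identity)$seq
  if (r2 == r1) {   # keep the two copies distinguishable
    mid <- ceiling(nchar(r1) / 2)
    r2 <- force_char_ne(r2, mid, substr(r1, mid, mid))
  }
  core <- deletion_core(spec$deletion_length, cons, cfg, id)
  seq <- paste0(r1, core$seq, r2)
  truth <- new_truth(
    deletion_rel = c(1L, spec$repeat_length + nchar(core$seq)),
    flanking_repeat_length = spec$repeat_length,
    flanking_repeat_identity = spec$repeat_identity,
    guard_left_ne = last_char(core$seq),
    guard_right_ne = first_char(core$seq),
    ambiguity_width = common_prefix_len(paste0(r1, substr(core$seq, 1, 50)),
                                        r2))
  reps <- data.frame(
    start = c(1L, spec$repeat_length + nchar(core$seq) + 1L),
    end = c(spec$repeat_length, spec$repeat_length + nchar(core$seq) +
              spec$repeat_length),
    strand = "+", name = paste0(id, c("_rep1", "_rep2")),
    family = "direct_repeat", part = "repeat", divergence = 0, tsd = "",
    stringsAsFactors = FALSE)
  list(seq = seq, truth = truth,
       te = te_ann_rows(core$te,
                        spec$repeat_length + core$te_rel[1] -
                          core$te$te_rel[1], cons, id),
       repeats = reps)
}

build_ltrrec <- function(spec, cons, cfg, id) {
  if (is.null(cons$ltr_length))
    stopf("ltr_recombination event requires a consensus with ltr_length")
  ltr <- substr(cons$sequence, 1, cons$ltr_length)
  l1 <- mutate_seq(ltr, 0.005)$seq
  l2 <- mutate_seq(ltr, 0.005)$seq
  if (l2 == l1) {
    mid <- ceiling(nchar(l1) / 2)
    l2 <- force_char_ne(l2, mid, substr(l1, mid, mid))
  }
  core <- deletion_core(spec$deletion_length, cons, cfg, id)
  seq <- paste0(l1, core$seq, l2)
  nl <- nchar(ltr)
  truth <- new_truth(
    deletion_rel = c(1L, nl + nchar(core$seq)),
    flanking_repeat_length = nl,
    guard_left_ne = last_char(core$seq),
    guard_right_ne = first_char(core$seq),
    ambiguity_width = common_prefix_len(paste0(l1, substr(core$seq, 1, 50)),
                                        l2))
  ltr_rows <- data.frame(
    start = c(1L, nl + nchar(core$seq) + 1L),
    end = c(nl, nl + nchar(core$seq) + nl),
    strand = "+", name = paste0(id, c("_soloLTR1", "_soloLTR2")),
    family = cons$name, part = "LTR", divergence = 0.005, tsd = "",
    stringsAsFactors = FALSE)
  list(seq = seq, truth = truth,
       te = rbind(ltr_rows,
                  te_ann_rows(core$te, nl + core$te_rel[1] -
                                core$te$te_rel[1], cons, id)),
       repeats = NULL)
}

# SD-MMEJ, one round, loop-out (direct) primer repeat in cis. Layout:
#   [p t] spacer [p] | deleted core | [mh] guard
# with tract t = net_insertion + mh; derived junction ... p net mh ...
build_sdmmej <- function(spec, cons, cfg, id) {
  for (attempt in 1:25) {
    p <- random_dna(spec$primer_length, 0.5)
    net <- random_dna(spec$net_insertion_length, 0.5)
    mh <- random_dna(spec$mh_length, 0.5)
    tract <- paste0(net, mh)
    spacer <- random_dna(sample(8:18, 1L), cfg$gc_content)
    core <- deletion_core(spec$deletion_length, cons, cfg, id)
    core$seq <- force_char_ne(core$seq, 1L, first_char(net))
    core$seq <- force_char_ne(core$seq, nchar(core$seq), last_char(net))
    guard <- random_dna(40, cfg$gc_content)
    seq <- paste0(p, tract, spacer, p, core$seq, mh, guard)
    left_len <- nchar(p) + nchar(tract) + nchar(spacer) + nchar(p)
    del <- c(left_len + 1L, left_len + nchar(core$seq))
    # verify the planted reconstruction is recovered as top rank
    lctx <- paste0(random_dna(40, cfg$gc_content), substr(seq, 1, left_len))
    rctx <- substr(seq, del[2] + 1L, nchar(seq))
    rec <- reconstruct_sdmmej(list(left = lctx, right = rctx), net)
    ok <- nrow(rec) > 0 && rec$net_insertion[1] == net &&
      rec$synthesis_tract[1] == tract && rec$rounds[1] == 1L
    if (ok) {
      truth <- new_truth(
        microhomology = mh, net_insertion = net, primer_repeat = p,
        synthesis_rounds = 1L, deletion_rel = del, ambiguity_width = 0L)
      return(list(seq = seq, truth = truth,
                  te = te_ann_rows(core$te, left_len + core$te_rel[1] -
                                     core$te$te_rel[1], cons, id),
                  repeats = NULL))
    }
  }
  stopf("event %s: could not realize an unambiguous SD-MMEJ template", id)
}

build_full_empty <- function(spec, cons, cfg, id) {
  tsd_len <- if (is.null(spec$tsd_length))
    sample(cfg$tsd_length_range[1]:cfg$tsd_length_range[2], 1L)
  else spec$tsd_length
  te <- te_with_tsd(cons, cfg$te_mutation_rate, tsd_len, id)
  seq <- te$seq
  el_len <- te$te_rel[2] - te$te_rel[1] + 1L
  el <- substr(seq, tsd_len + 1L, tsd_len + el_len)
  truth <- new_truth(tsd = te$tsd, microhomology = te$tsd,
                     deletion_rel = c(1L, tsd_len + el_len),
                     guard_left_ne = c(last_char(el), last_char(te$tsd)),
                     guard_right_ne = c(first_char(el), first_char(te$tsd)),
                     ambiguity_width = tsd_len)
  list(seq = seq, truth = truth, te = te_ann_rows(te, 0L, cons, id),
       repeats = NULL)
}

build_internal_del <- function(spec, cons, cfg, id) {
  tsd_len <- sample(cfg$tsd_length_range[1]:cfg$tsd_length_range[2], 1L)
  te <- te_with_tsd(cons, cfg$te_mutation_rate, tsd_len, id)
  el_len <- te$te_rel[2] - te$te_rel[1] + 1L
  ltr <- if (is.null(cons$ltr_length)) 0L else cons$ltr_length
  avail <- el_len - 2L * ltr - 200L
  dl <- min(spec$internal_deletion_length, avail)
  if (dl < 100L) stopf("event %s: element too short for internal deletion", id)
  d1 <- te$te_rel[1] + ltr + 100L
  truth <- new_truth(deletion_rel = c(d1, d1 + dl - 1L))
  list(seq = te$seq, truth = truth, te = te_ann_rows(te, 0L, cons, id),
       repeats = NULL)
}

build_artifact <- function(spec, cons, cfg, id) {
  tsd_len <- sample(cfg$tsd_length_range[1]:cfg$tsd_length_range[2], 1L)
  te <- te_with_tsd(cons, cfg$te_mutation_rate, tsd_len, id)
  # the N run replaces the TSD and the 5' half of the element
  repl_end <- te$te_rel[1] + floor((te$te_rel[2] - te$te_rel[1]) / 2)
  truth <- new_truth(deletion_rel = c(1L, repl_end),
                     n_length = spec$n_length)
  list(seq = te$seq, truth = truth, te = te_ann_rows(te, 0L, cons, id),
       repeats = NULL)
}

build_tandem <- function(spec, cons, cfg, id) {
  core <- deletion_core(spec$unit_length, cons, cfg, id)
  u1 <- core$seq
  u2 <- mutate_seq(u1, 1 - spec$unit_identity)$seq
  if (u2 == u1) {
    mid <- ceiling(nchar(u1) / 2)
    u2 <- force_char_ne(u2, mid, substr(u1, mid, mid))
  }
  seq <- paste0(u1, u2)
  truth <- new_truth(repeat_unit_length = nchar(u1),
                     deletion_rel = c(nchar(u1) + 1L, nchar(u1) + nchar(u2)),
                     unit_identity = spec$unit_identity,
                     guard_left_ne = last_char(u1),
                     guard_right_ne = first_char(u2),
                     ambiguity_width = common_prefix_len(u1, u2))
  list(seq = seq, truth = truth,
       te = te_ann_rows(core$te, core$te_rel[1] - core$te$te_rel[1], cons, id),
       repeats = data.frame(
                   start = c(1L, nchar(u1) + 1L),
                   end = c(nchar(u1), nchar(u1) + nchar(u2)),
                   strand = "+", name = paste0(id, c("_unit1", "_unit2")),
                   family = "tandem_unit", part = "repeat", divergence = 0,
                   tsd = "", stringsAsFactors = FALSE))
}

build_introgression <- function(spec, cons, cfg, id) {
  core <- deletion_core(spec$deletion_length, cons, cfg, id)
  foreign <- random_dna(spec$insert_length, 0.5)
  foreign <- force_char_ne(foreign, 1L, first_char(core$seq))
  foreign <- force_char_ne(foreign, nchar(foreign), last_char(core$seq))
  truth <- new_truth(deletion_rel = c(1L, nchar(core$seq)),
                     net_insertion = foreign,
                     guard_left_ne = last_char(core$seq),
                     guard_right_ne = first_char(core$seq))
  list(seq = core$seq, truth = truth,
       te = te_ann_rows(core$te, core$te_rel[1] - core$te$te_rel[1], cons, id),
       repeats = NULL)
}

build_inversion <- function(spec, cons, cfg, id) {
  core <- deletion_core(spec$span, cons, cfg, id)
  # the inverted segment's start must not chance-extend the flanking match
  comp_end <- chartr("ACGT", "TGCA", last_char(core$seq))
  core$seq <- force_char_ne(core$seq, 1L, comp_end)
  truth <- new_truth(inversion_rel = c(1L, nchar(core$seq)))
  list(seq = core$seq, truth = truth,
       te = te_ann_rows(core$te, core$te_rel[1] - core$te$te_rel[1], cons, id),
       repeats = NULL)
}

# ---- placement -------------------------------------------------------------

place_structs <- function(structs, cfg, chrom_name, min_gap = 3500L) {
  lens <- vapply(structs, function(s) nchar(s$seq), integer(1))
  if (length(lens) && cfg$chromosome_length < 10L * max(lens))
    stopf("chromosome_length must be >= 10 x the longest event span (%d)",
          max(lens))
  n <- length(structs)
  free <- cfg$chromosome_length - sum(lens) - (n + 1L) * min_gap
  if (free < 0)
    stopf("chromosome %s too short for %d structures", chrom_name, n)
  extra <- if (n + 1L > 1L && free > 0) {
    w <- runif(n + 1L); floor(free * w / sum(w))
  } else rep(0L, n + 1L)
  gaps <- min_gap + extra
  pieces <- character(2L * n + 1L)
  te <- NULL; reps <- NULL; events <- list()
  pos <- 0L
  pending_right_guard <- NULL
  for (i in seq_len(n)) {
    g <- random_dna(gaps[i], cfg$gc_content)
    if (!is.null(pending_right_guard))
      g <- force_char_ne(g, 1L, pending_right_guard)
    s <- structs[[i]]
    # boundary guards: the truth deletion placement must not slide into the
    # background, and flanking blocks must not chance-extend across junctions
    if (!is.null(s$truth) && !is.null(s$truth$guard_left_ne))
      g <- force_char_ne(g, nchar(g), s$truth$guard_left_ne)
    pending_right_guard <- if (!is.null(s$truth)) s$truth$guard_right_ne
                           else NULL
    pieces[2L * i - 1L] <- g
    pos <- pos + gaps[i]
    pieces[2L * i] <- s$seq
    offset <- pos
    if (!is.null(s$te)) {
      t <- s$te; t$start <- t$start + offset; t$end <- t$end + offset
      t$chrom <- chrom_name; te <- rbind(te, t)
    }
    if (!is.null(s$repeats)) {
      r <- s$repeats; r$start <- r$start + offset; r$end <- r$end + offset
      r$chrom <- chrom_name; reps <- rbind(reps, r)
    }
    if (!is.null(s$truth)) {
      ev <- s$truth
      ev$chromosome <- chrom_name
      ev$a_interval <- c(offset + 1L, offset + nchar(s$seq))
      if (!is.null(ev$deletion_rel)) {
        ev$deletion <- ev$deletion_rel + offset
        ev$removed_length <- ev$deletion[2] - ev$deletion[1] + 1L
        ev$deletion_rel <- NULL
      }
      if (!is.null(ev$inversion_rel)) {
        ev$inversion <- ev$inversion_rel + offset
        ev$inversion_rel <- NULL
      }
      class(ev) <- "rearrangement_event"
      events[[ev$event_id]] <- ev
    }
    pos <- pos + nchar(s$seq)
  }
  tailpiece <- random_dna(cfg$chromosome_length - pos, cfg$gc_content)
  if (!is.null(pending_right_guard))
    tailpiece <- force_char_ne(tailpiece, 1L, pending_right_guard)
  pieces[2L * n + 1L] <- tailpiece
  chrom <- paste(pieces, collapse = "")
  if (!is.null(te)) te <- te[order(te$start),
                             c("chrom", "start", "end", "strand", "name",
                               "family", "part", "divergence", "tsd")]
  if (!is.null(reps)) reps <- reps[order(reps$start),
                                   c("chrom", "start", "end", "strand",
                                     "name", "family", "part", "divergence",
                                     "tsd")]
  list(seq = chrom, te = te, repeats = reps, events = events)
}

# ---- event application -----------------------------------------------------

#' Apply one rearrangement event to a genome
#'
#' Performs the mechanism-defined surgery on the named chromosome: deletion
#' mechanisms excise the recorded interval (leaving a single copy of any
#' microhomology/repeat/TSD, by the leftmost-placement convention) and insert
#' the recorded net insertion at the junction; \code{tandem_duplication}
#' removes the second unit; \code{introgression} replaces the excised segment
#' with the recorded foreign sequence; \code{inversion} reverse-complements
#' the recorded interval; \code{assembly_artifact} replaces the interval with
#' a run of Ns. Purely deterministic: all random choices were fixed when the
#' event was finalized, so replaying an event always reproduces the same
#' derived junction.
#'
#' @param genome named character vector of chromosome sequences.
#' @param event a finalized \code{rearrangement_event}.
#' @return list with \code{genome} (mutated) and \code{event} (with the
#'   derived-side junction recorded).
#' @export
apply_event <- function(genome, event) {
  ch <- event$chromosome
  if (!ch %in% names(genome)) stopf("event %s: unknown chromosome %s",
                                    event$event_id, ch)
  seq <- genome[[ch]]
  n <- nchar(seq)
  iv <- if (!is.null(event$deletion)) event$deletion else event$inversion
  if (is.null(iv)) stopf("event %s: no interval to apply", event$event_id)
  if (iv[1] < 1 || iv[2] > n)
    stopf("event %s: interval [%d,%d] exceeds chromosome bounds",
          event$event_id, iv[1], iv[2])
  left <- substr_(seq, 1L, iv[1] - 1L)
  right <- substr_(seq, iv[2] + 1L, n)
  mid <- switch(event$mechanism,
    inversion = revcomp(substr_(seq, iv[1], iv[2])),
    assembly_artifact = strrep("N", event$n_length),
    introgression = event$net_insertion,
    event$net_insertion)  # deletion mechanisms: usually ""
  genome[[ch]] <- paste0(left, mid, right)
  event$b_junction <- nchar(left) + 1L
  event$b_replacement_length <- nchar(mid)
  list(genome = genome, event = event)
}

#' Simulate a genome pair with ground truth
#'
#' Builds the ancestor (genome A), applies every finalized event to derive
#' genome B, and returns both genomes plus a truth table giving each event's
#' final coordinates on both genomes. Event footprints never overlap, so
#' outside them the two genomes are identical.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{sim_pair} list: \code{genome_a}, \code{genome_b} (named
#'   character vectors), \code{truth} (data.frame, one row per event),
#'   \code{events} (finalized event list), \code{te_annotation},
#'   \code{repeat_annotation}, \code{config}.
#' @export
simulate_genome_pair <- function(config) {
  anc <- make_ancestor(config)
  genome_b <- anc$genome
  evs <- anc$events
  ord <- order(vapply(evs, function(e) e$chromosome, character(1)),
               -vapply(evs, function(e) e$a_interval[1], numeric(1)))
  for (i in ord) {
    res <- apply_event(genome_b, evs[[i]])
    genome_b <- res$genome
    evs[[i]] <- res$event
  }
  # derived-genome coordinates: cumulative length change of events upstream
  truth <- NULL
  for (ch in names(anc$genome)) {
    idx <- which(vapply(evs, function(e) e$chromosome, character(1)) == ch)
    if (!length(idx)) next
    idx <- idx[order(vapply(evs[idx], function(e) e$a_interval[1],
                            numeric(1)))]
    shift <- 0L
    for (i in idx) {
      e <- evs[[i]]
      iv <- if (!is.null(e$deletion)) e$deletion else e$inversion
      a_len <- iv[2] - iv[1] + 1L
      b_len <- e$b_replacement_length
      b_start <- iv[1] + shift
      evs[[i]]$b_interval <- c(b_start, b_start + max(b_len, 1L) - 1L)
      truth <- rbind(truth, data.frame(
        event_id = e$event_id, mechanism = e$mechanism, chromosome = ch,
        a_start = e$a_interval[1], a_end = e$a_interval[2],
        del_start = iv[1], del_end = iv[2],
        removed_length = if (!is.null(e$removed_length)) e$removed_length
                         else 0L,
        b_start = b_start, b_end = b_start + max(b_len, 1L) - 1L,
        b_replacement_length = b_len,
        microhomology = e$microhomology,
        net_insertion_length = nchar(e$net_insertion),
        primer_repeat = e$primer_repeat,
        synthesis_rounds = e$synthesis_rounds,
        repeat_unit_length = e$repeat_unit_length,
        tsd = e$tsd, ambiguity_width = e$ambiguity_width,
        stringsAsFactors = FALSE))
      shift <- shift + b_len - a_len
    }
  }
  if (!is.null(truth)) rownames(truth) <- NULL
  structure(list(genome_a = anc$genome, genome_b = genome_b, truth = truth,
                 events = evs, te_annotation = anc$te_annotation,
                 repeat_annotation = anc$repeat_annotation, config = config),
            class = "sim_pair")
}

#' Write a simulated genome pair to disk
#'
#' FASTA (60-column wrap) for both genomes, the truth table as JSON (one
#' object per event) and BED (0-based half-open, converted from the internal
#' 1-based closed coordinates; one track per genome).
#'
#' @param pair a \code{sim_pair}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_genome_pair <- function(pair, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pa <- file.path(outdir, "genome_A.fa")
  pb <- file.path(outdir, "genome_B.fa")
  write_fasta(pair$genome_a, pa)
  write_fasta(pair$genome_b, pb)
  pj <- file.path(outdir, "truth.json")
  jsonlite::write_json(pair$truth, pj, auto_unbox = TRUE, digits = NA,
                       na = "null")
  bed_a <- file.path(outdir, "truth_A.bed")
  bed_b <- file.path(outdir, "truth_B.bed")
  tr <- pair$truth
  if (!is.null(tr)) {
    write.table(data.frame(tr$chromosome, tr$a_start - 1L, tr$a_end,
                           tr$event_id, 0L, "+"),
                bed_a, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    write.table(data.frame(tr$chromosome, tr$b_start - 1L, tr$b_end,
                           tr$event_id, 0L, "+"),
                bed_b, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(c(pa, pb, pj, bed_a, bed_b))
}

#' Write sequences as wrapped FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
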