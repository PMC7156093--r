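test_that("a fixed seed makes the simulation byte-identical", {
  cfg <- sim_config(chromosome_length = 60000, te_copies_per_chromosome = 2,
                    event_specs = list(event_spec("mmej"),
                                       event_spec("blunt")), seed = 1)
  p1 <- simulate_genome_pair(cfg)
  p2 <- simulate_genome_pair(cfg)
  expect_identical(p1$genome_a, p2$genome_a)
  expect_identical(p1$genome_b, p2$genome_b)
  expect_identical(p1$truth, p2$truth)
})

test_that("zero mutation rate plants exact consensus copies", {
  cfg <- sim_config(chromosome_length = 60000, te_copies_per_chromosome = 4,
                    te_mutation_rate = 0, seed = 2)
  anc <- make_ancestor(cfg)
  cons <- cfg$te_library[[1]]$sequence
  ann <- anc$te_annotation[anc$te_annotation$part == "complete", ]
  expect_equal(nrow(ann), 4L)
  for (i in seq_len(nrow(ann))) {
    copy <- substr(anc$genome[[ann$chrom[i]]], ann$start[i], ann$end[i])
    if (ann$strand[i] == "-") copy <- revcomp(copy)
    expect_identical(copy, cons)
  }
})

test_that("per-copy divergence follows the configured substitution rate", {
  rate <- 0.03
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 80000,
                    te_copies_per_chromosome = 5, te_mutation_rate = rate,
                    seed = 3)
  anc <- make_ancestor(cfg)
  cons <- cfg$te_library[[1]]$sequence
  ann <- anc$te_annotation[anc$te_annotation$part == "complete", ]
  expect_equal(nrow(ann), 10L)          # 5 copies x 2 chromosomes
  n <- nchar(cons)
  band <- 3 * sqrt(n * rate * (1 - rate))
  for (i in seq_len(nrow(ann))) {
    copy <- substr(anc$genome[[ann$chrom[i]]], ann$start[i], ann$end[i])
    if (ann$strand[i] == "-") copy <- revcomp(copy)
    subs <- sum(utf8ToInt(copy) != utf8ToInt(cons))   # direct count oracle
    expect_lte(abs(subs - n * rate), band)
    expect_equal(subs / n, ann$divergence[i], tolerance = 1e-9)
  }
})

test_that("an MMEJ junction retains exactly one microhomology copy", {
  cfg <- sim_config(chromosome_length = 160000, te_copies_per_chromosome = 4,
                    event_specs = list(event_spec(
                      "mmej", microhomology = "GCGT",
                      deletion_length = 13000)), seed = 4)
  pair <- simulate_genome_pair(cfg)
  tr <- pair$truth
  expect_equal(tr$microhomology, "GCGT")
  expect_equal(tr$removed_length, 13004L)
  junc <- substr(pair$genome_b[[tr$chromosome]], tr$b_start - 30,
                 tr$b_start + 33)
  expect_equal(lengths(regmatches(junc, gregexpr("GCGT", junc))), 1L)
  # the conserved flanks around the single copy match the donor
  A <- pair$genome_a[[tr$chromosome]]
  expect_identical(substr(pair$genome_b[[tr$chromosome]], tr$b_start - 30,
                          tr$b_start - 1),
                   substr(A, tr$del_start - 30, tr$del_start - 1))
})

test_that("no events means identical genomes", {
  cfg <- sim_config(chromosome_length = 40000, te_copies_per_chromosome = 2,
                    seed = 5)
  pair <- simulate_genome_pair(cfg)
  expect_identical(pair$genome_a, pair$genome_b)
  expect_null(pair$truth)
})

test_that("unequal recombination matches the direct string-surgery oracle", {
  cfg <- sim_config(chromosome_length = 90000, te_copies_per_chromosome = 3,
                    event_specs = list(event_spec("unequal_recombination",
                                                  repeat_length = 150)),
                    seed = 6)
  pair <- simulate_genome_pair(cfg)
  tr <- pair$truth
  A <- pair$genome_a[[tr$chromosome]]
  oracle <- paste0(substr(A, 1, tr$del_start - 1),
                   substr(A, tr$del_end + 1, nchar(A)))
  expect_identical(pair$genome_b[[tr$chromosome]], oracle)
})

test_that("one event of each mechanism: 11 truth rows, diffs confined to footprints", {
  pair <- pair11()
  expect_equal(nrow(pair$truth), 11L)
  expect_setequal(pair$truth$mechanism, all_mechanisms)
  # whole-genome diff oracle: between consecutive event footprints the two
  # genomes are identical
  for (ch in names(pair$genome_a)) {
    tr <- pair$truth[pair$truth$chromosome == ch, ]
    tr <- tr[order(tr$del_start), ]
    bounds_a <- c(1L, tr$del_end + 1L)
    ends_a <- c(tr$del_start - 1L, nchar(pair$genome_a[[ch]]))
    shift <- cumsum(c(0L, tr$b_replacement_length -
                        (tr$del_end - tr$del_start + 1L)))
    for (k in seq_along(bounds_a)) {
      seg_a <- substr(pair$genome_a[[ch]], bounds_a[k], ends_a[k])
      seg_b <- substr(pair$genome_b[[ch]], bounds_a[k] + shift[k],
                      ends_a[k] + shift[k])
      expect_identical(seg_a, seg_b)
    }
  }
})

test_that("a full/empty site leaves one TSD copy at the empty site", {
  cfg <- sim_config(chromosome_length = 60000,
                    te_copies_per_chromosome = 2,
                    event_specs = list(event_spec("te_insertion_full_empty",
                                                  tsd_length = 5)),
                    seed = 8)
  pair <- simulate_genome_pair(cfg)
  tr <- pair$truth
  tsd <- tr$tsd
  expect_equal(nchar(tsd), 5L)
  A <- pair$genome_a[[tr$chromosome]]; B <- pair$genome_b[[tr$chromosome]]
  # full site: element flanked by two identical 5-mers
  expect_identical(substr(A, tr$del_start, tr$del_start + 4), tsd)
  expect_identical(substr(A, tr$del_end + 1, tr$del_end + 5), tsd)
  # empty site: a single copy
  empty <- substr(B, tr$b_start, tr$b_start + 4)
  expect_identical(empty, tsd)
  expect_false(substr(B, tr$b_start + 5, tr$b_start + 9) == tsd)
})

test_that("event intervals beyond chromosome bounds are rejected by id", {
  cfg <- sim_config(chromosome_length = 40000, te_copies_per_chromosome = 2,
                    seed = 9)
  anc <- make_ancestor(cfg)
  ev <- structure(list(event_id = "ev_bad", mechanism = "blunt",
                       chromosome = "chr1", deletion = c(39000L, 99000L),
                       net_insertion = "", n_length = 0L),
                  class = "rearrangement_event")
  expect_error(apply_event(anc$genome, ev), "ev_bad")
})

test_that("colliding event placements are reported with their ids", {
  mk <- function(id, s, e) list(event_id = id, chromosome = "chr1",
                                a_interval = c(s, e))
  expect_error(teindel:::validate_event_overlaps(
    list(mk("ev_x", 100, 5000), mk("ev_y", 4500, 9000))), "ev_x.*ev_y")
  expect_silent(teindel:::validate_event_overlaps(
    list(mk("ev_x", 100, 5000), mk("ev_y", 5001, 9000))))
})

test_that("written outputs round-trip: FASTA, JSON truth, BED", {
  pair <- pair11()
  dir <- withr::local_tempdir()
  paths <- write_genome_pair(pair, dir)
  ga <- read_fasta(file.path(dir, "genome_A.fa"))
  expect_identical(unname(ga), unname(pair$genome_a))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth), nrow(pair$truth))
  bed <- read.table(file.path(dir, "truth_A.bed"), sep = "\t")
  expect_equal(bed[[2]], pair$truth$a_start - 1L)   # 0-based half-open
  expect_equal(bed[[3]], pair$truth$a_end)
})
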