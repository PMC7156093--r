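test_that("identical genomes: every insertion matched, none species-specific", {
  cfg <- sim_config(chromosome_length = 100000,
                    te_copies_per_chromosome = 6, seed = 41)
  pair <- simulate_genome_pair(cfg)   # no events: A == B
  cons <- cfg$te_library[[1]]
  ia <- retrieve_insertions(pair$genome_a, cons)
  ib <- retrieve_insertions(pair$genome_b, cons)
  m <- match_insertions_across_genomes(ia, ib)
  expect_equal(nrow(m$pairs), 6L)
  expect_length(m$unmatched_a, 0)
  expect_length(m$unmatched_b, 0)
})

test_that("shared and species-specific insertions are separated by flank matching", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 110000,
                    te_copies_per_chromosome = 5,
                    event_specs = list(event_spec("blunt"),
                                       event_spec("mmej"),
                                       event_spec("sdmmej")),
                    seed = 42)
  pair <- simulate_genome_pair(cfg)
  cons <- cfg$te_library[[1]]
  ia <- retrieve_insertions(pair$genome_a, cons)
  ib <- retrieve_insertions(pair$genome_b, cons)
  m <- match_insertions_across_genomes(ia, ib)
  # 10 standalone copies shared; 3 copies sit inside deleted segments
  expect_equal(nrow(m$pairs), 10L)
  expect_length(m$unmatched_a, 3)
  expect_length(m$unmatched_b, 0)
  # reciprocity: swapping the genomes swaps the role of the specific calls
  m2 <- match_insertions_across_genomes(ib, ia)
  expect_setequal(m2$unmatched_b, m$unmatched_a)
  expect_equal(nrow(m2$pairs), 10L)
})

test_that("two donor insertions over one derived insertion are flagged for CNV review", {
  cfg <- sim_config(chromosome_length = 130000,
                    te_copies_per_chromosome = 3,
                    event_specs = list(event_spec("tandem_duplication")),
                    seed = 43)
  pair <- simulate_genome_pair(cfg)
  cons <- cfg$te_library[[1]]
  ia <- retrieve_insertions(pair$genome_a, cons)
  ib <- retrieve_insertions(pair$genome_b, cons)
  m <- match_insertions_across_genomes(ia, ib)
  expect_equal(nrow(m$cnv_review), 1L)   # the losing duplicate is kept
  expect_true(m$cnv_review$b_id %in% m$pairs$b_id)
})

test_that("missing flanks raise an error naming the record", {
  ins <- data.frame(id = "ins_x", chromosome = "chr1", start = 10, end = 20,
                    strand = "+", identity_to_consensus = 1,
                    structure = "full_length", consensus_cov = 10,
                    cov_start = 1, cov_end = 10, evalue = 0,
                    flank5 = "", flank3 = "", flank_complete = FALSE,
                    tsd = "", stringsAsFactors = FALSE)
  expect_error(match_insertions_across_genomes(ins, ins), "ins_x")
})

test_that("chromosome walking brackets a large deletion", {
  cfg <- sim_config(chromosome_length = 140000,
                    te_copies_per_chromosome = 2,
                    event_specs = list(event_spec("blunt",
                                                  deletion_length = 9000)),
                    seed = 44)
  pair <- simulate_genome_pair(cfg)
  tr <- pair$truth
  ann <- pair$te_annotation
  te <- ann[ann$part == "complete" & ann$start > tr$del_start &
              ann$end < tr$del_end, ][1, ]
  walk <- chromosome_walk(pair$genome_a,
                          list(chromosome = te$chrom, start = te$start,
                               end = te$end),
                          pair$genome_b, step = 2000)
  expect_true(walk$found)
  # the bracketed derived-genome interval contains the deletion junction
  expect_true(walk$b_interval[1] <= tr$b_start &&
                walk$b_interval[2] >= tr$b_start - 1)
  # the walk had to span at least the distance to the deletion borders
  expect_gte(walk$walked["left"], te$start - tr$del_start)
  expect_gte(walk$walked["right"], tr$del_end - te$end)
})

test_that("an anchor whose flanks match immediately walks a single step", {
  cfg <- sim_config(chromosome_length = 80000,
                    te_copies_per_chromosome = 3, seed = 45)
  pair <- simulate_genome_pair(cfg)
  ann <- pair$te_annotation[pair$te_annotation$part == "complete", ][2, ]
  walk <- chromosome_walk(pair$genome_a,
                          list(chromosome = ann$chrom, start = ann$start,
                               end = ann$end),
                          pair$genome_b, step = 2000)
  expect_true(walk$found)
  expect_lte(walk$walked["left"], 2000)
  expect_lte(walk$walked["right"], 2000)
})

test_that("anchors inside a replaced segment are bracketed beyond it", {
  cfg <- sim_config(chromosome_length = 140000,
                    te_copies_per_chromosome = 2,
                    event_specs = list(event_spec("introgression")),
                    seed = 46)
  pair <- simulate_genome_pair(cfg)
  tr <- pair$truth
  ann <- pair$te_annotation
  te <- ann[ann$part == "complete" & ann$start > tr$del_start &
              ann$end < tr$del_end, ][1, ]
  walk <- chromosome_walk(pair$genome_a,
                          list(chromosome = te$chrom, start = te$start,
                               end = te$end),
                          pair$genome_b, step = 2000)
  expect_true(walk$found)
  # bracketing anchors lie outside the replaced segment on both genomes
  expect_lte(walk$left_anchor$a_end, tr$del_start)
  expect_gte(walk$right_anchor$a_start, tr$del_end)
  expect_lte(walk$b_interval[1], tr$b_start)
  expect_gte(walk$b_interval[2], tr$b_end)
})

test_that("polymorphism decision tree recovers every planted category", {
  rep <- report11()
  pc <- rep$polymorphisms
  cats <- vapply(pc, function(x) x$category, character(1))
  expect_true("empty_site_tsd" %in% cats)
  expect_true("internal_deletion" %in% cats)
  expect_true("assembly_artifact" %in% cats)
  expect_true("replaced_by_insertion" %in% cats)
  expect_true(sum(cats == "long_indel_candidate") >= 4)
})
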