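test_that("deletion-border microhomologies are recovered from the worked loci", {
  wx <- worked_junction_examples()
  d3 <- worked_example_donor(wx$`5B_3`)
  r <- find_junction_microhomology(d3$donor, d3$deletion)
  expect_equal(r$microhomology, "A")
  expect_equal(r$length, 1L)
  expect_true(r$single_copy_retained)
  d4 <- worked_example_donor(wx$`5B_4`)
  r <- find_junction_microhomology(d4$donor, d4$deletion)
  expect_equal(r$microhomology, "GCGT")
  expect_equal(r$length, 4L)
  expect_true(r$single_copy_retained)
  d5 <- worked_example_donor(wx$`3B_5`)
  r <- find_junction_microhomology(d5$donor, d5$deletion)
  expect_equal(r$microhomology, "")
  expect_equal(r$length, 0L)
})

test_that("the 3B_2 junction is explained by one round of templated synthesis", {
  wx <- worked_junction_examples()$`3B_2`
  rec <- reconstruct_sdmmej(list(left = wx$left, right = wx$right), wx$net)
  expect_gt(nrow(rec), 0)
  top <- rec[1, ]
  expect_equal(top$rounds, 1L)
  expect_equal(top$primer_repeat, "A")
  expect_equal(top$synthesis_tract, "AATTTG")
  expect_equal(top$synthesis_length, 6L)
  expect_equal(top$junction_microhomology, "TTG")
  expect_equal(top$net_insertion, "AAT")
})

test_that("the 3B_4 junction admits a two-round 14-bp templated insertion", {
  wx <- worked_junction_examples()$`3B_4`
  rec <- reconstruct_sdmmej(list(left = wx$left, right = wx$right), wx$net)
  two <- rec[rec$rounds == 2 & nchar(rec$net_insertion) == 14, ]
  expect_gt(nrow(two), 0)
  expect_true(any(two$tract1 == "TCT" &
                    two$tract2 == "AGCACAACTCCGTC" &
                    two$junction_microhomology == "GTC"))
})

test_that("apparently blunt junctions at 3B_5 and 3B_3 have SD-MMEJ explanations", {
  wx <- worked_junction_examples()
  rec5 <- reconstruct_sdmmej(list(left = wx$`3B_5`$left,
                                  right = wx$`3B_5`$right), "")
  expect_true(any(rec5$primer_repeat == "GA" & rec5$synthesis_tract == "TC"))
  rec3 <- reconstruct_sdmmej(list(left = wx$`3B_3`$left,
                                  right = wx$`3B_3`$right), "")
  expect_true(any(rec3$primer_repeat == "GT" &
                    rec3$synthesis_tract == "CCCC"))
})

test_that("reconstruction enumeration equals the brute-force oracle", {
  wx <- worked_junction_examples()
  for (nm in c("3B_2", "3B_5", "5B_3")) {
    ex <- wx[[nm]]
    rec <- reconstruct_sdmmej(list(left = ex$left, right = ex$right),
                              ex$net)
    got <- unique(data.frame(rounds = rec$rounds,
                             side = rec$primer_side,
                             tract = rec$synthesis_tract,
                             mh = rec$junction_microhomology))
    want <- oracle_sdmmej(ex$left, ex$right, ex$net)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(got) <- rownames(want) <- NULL
      ord <- function(d) d[order(d$rounds, d$side, d$tract, d$mh), ]
      expect_equal(ord(got), ord(want), ignore_attr = TRUE)
    }
  }
})

test_that("window growth never removes a reconstruction", {
  wx <- worked_junction_examples()$`3B_2`
  small <- reconstruct_sdmmej(list(left = wx$left, right = wx$right),
                              wx$net, window = 25)
  big <- reconstruct_sdmmej(list(left = wx$left, right = wx$right),
                            wx$net, window = 35)
  key <- function(d) paste(d$rounds, d$primer_side, d$tract1, d$tract2,
                           d$junction_microhomology)
  expect_true(all(key(small) %in% key(big)))
})

test_that("long flanking direct repeats are found at the planted identity", {
  set.seed(61)
  rep1 <- random_dna(300, 0.46)
  mk <- function(rep2) {
    core <- random_dna(4000, 0.46)
    paste0(random_dna(1500, 0.46), rep1, core, rep2,
           random_dna(1500, 0.46))
  }
  donor99 <- mk(mutate_seq(rep1, 0.01)$seq)
  bp <- c(1800, 1800 + 4000 + 300)
  found <- find_flanking_direct_repeats(donor99, bp)
  expect_false(is.null(found))
  expect_gte(found$repeat_length, 250)
  expect_gte(found$identity, 0.95)
  # a 4-bp microhomology is no repeat at these thresholds
  expect_null(find_flanking_direct_repeats(
    paste0(random_dna(1000, 0.46), "GCGT", random_dna(3000, 0.46), "GCGT",
           random_dna(1000, 0.46)), c(1004, 4004)))
  # 90%-identical repeats appear only when the threshold is lowered
  donor90 <- mk(mutate_seq(rep1, 0.10)$seq)
  expect_null(find_flanking_direct_repeats(donor90, bp))
  expect_false(is.null(find_flanking_direct_repeats(donor90, bp,
                                                    min_identity = 0.85)))
})

test_that("LTR recombination requires same-family, same-orientation LTRs", {
  ann <- data.frame(
    chrom = "chr1",
    start = c(1000, 6000, 8000, 12000),
    end = c(1300, 6300, 8500, 12300),
    strand = c("+", "+", "+", "-"),
    family = c("famX", "famX", "famX", "famX"),
    part = c("LTR", "LTR", "internal", "LTR"),
    stringsAsFactors = FALSE)
  hit <- function(bp5, bp3) detect_ltr_recombination(
    list(chromosome = "chr1", bp5 = bp5, bp3 = bp3), ann)
  expect_true(hit(1100, 6100)$is_ltr_recombination)     # both in + LTRs
  expect_false(hit(1100, 8200)$is_ltr_recombination)    # LTR vs internal
  expect_false(hit(1100, 12100)$is_ltr_recombination)   # opposite strand
})

test_that("introgression means no homology in donor or references", {
  set.seed(62)
  donor <- c(chr1 = random_dna(60000, 0.46))
  foreign <- random_dna(2000, 0.5)
  expect_true(detect_introgression(foreign, donor)$introgressed)
  copied <- substr(donor[[1]], 10001, 12000)
  expect_false(detect_introgression(copied, donor)$introgressed)
  diverged <- mutate_seq(copied, 0.04)$seq   # ~96% identity to the donor
  expect_false(detect_introgression(diverged, donor)$introgressed)
  # below the minimum insert size the check does not apply
  expect_false(detect_introgression(substr(foreign, 1, 500),
                                    donor)$introgressed)
})

test_that("flanking repeats take precedence over junction microhomology", {
  set.seed(63)
  rep1 <- random_dna(150, 0.46)
  core <- random_dna(4000, 0.46)
  core <- paste0("G", substr(core, 2, 3999), "T")
  L <- random_dna(2000, 0.46); R <- random_dna(2000, 0.46)
  R <- paste0("A", substr(R, 2, 2000))
  # deletion flanked by 150-bp repeats AND a 3-bp microhomology
  A <- c(chr1 = paste0(L, rep1, "CAT", core, rep1, "CAT", R))
  B <- c(chr1 = paste0(L, rep1, "CAT", R))
  ic <- call_indel(A[[1]], B[[1]], chromosome = "chr1")
  sig <- classify_mechanism(ic, A, B)
  expect_equal(sig$mechanism, "unequal_recombination")
  expect_gte(sig$flanking_repeat_length, 140)
  # microhomology evidence retained regardless of the repeat-based label
  # (capped at the MMEJ ceiling; here the junction repeat is much longer)
  expect_equal(sig$microhomology_length, 9L)
  expect_gte(ic$ambiguity_width, 150L)
})

test_that("simulated MMEJ calls keep a single microhomology copy and replay", {
  pair <- pair11()
  rep <- report11()
  tr <- pair$truth
  for (mech in c("mmej", "sdmmej")) {
    row <- tr[tr$mechanism == mech, ]
    srow <- summary_row_for(rep, row)
    sig <- rep$signatures[[srow$locus_id]]
    expect_equal(sig$mechanism, mech)
    ch <- row$chromosome
    if (mech == "mmej") {
      expect_equal(sig$microhomology, row$microhomology)
      # single-copy retention at the derived junction
      k <- nchar(sig$microhomology)
      B <- pair$genome_b[[ch]]
      expect_identical(substr(B, row$b_start, row$b_start + k - 1L),
                       sig$microhomology)
      expect_false(substr(B, row$b_start - k, row$b_start - 1L) ==
                     sig$microhomology)
      expect_false(substr(B, row$b_start + k, row$b_start + 2L * k - 1L) ==
                     sig$microhomology)
    }
    # replay: re-applying the recorded event reproduces the derived
    # junction byte-for-byte (compared locally; other events shift the
    # rest of the chromosome)
    ev <- pair$events[[row$event_id]]
    replayed <- apply_event(pair$genome_a, ev)$genome[[ch]]
    w <- 50 + row$b_replacement_length
    expect_identical(substr(replayed, row$del_start - 50,
                            row$del_start + w),
                     substr(pair$genome_b[[ch]], row$b_start - 50,
                            row$b_start + w))
  }
  # the SD-MMEJ signature's top reconstruction explains the planted junction
  row <- tr[tr$mechanism == "sdmmej", ]
  sig <- rep$signatures[[summary_row_for(rep, row)$locus_id]]
  expect_gt(nrow(sig$reconstructions), 0)
  expect_equal(sig$reconstructions$net_insertion[1],
               substr(pair$genome_b[[row$chromosome]], row$b_start,
                      row$b_start + row$net_insertion_length - 1L))
  # the planted primer repeat is among the co-optimal one-round
  # reconstructions (the same template also supports longer primer suffixes)
  top <- sig$reconstructions
  top <- top[top$rounds == top$rounds[1] &
               top$synthesis_tract == top$synthesis_tract[1], ]
  expect_true(row$primer_repeat %in% top$primer_repeat ||
                any(endsWith(top$primer_repeat, row$primer_repeat)))
})
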