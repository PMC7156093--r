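test_that("interval_length follows the 1-based closed convention", {
  expect_equal(interval_length(566939353, 567135082), 195730L)
  expect_equal(interval_length(349934346, 349934349), 4L)
  expect_equal(interval_length(5, 5), 1L)
  expect_error(interval_length(10, 9), "end < start")
})

test_that("interval_length reproduces every published locus length", {
  loci <- wheat_indel_loci()
  expect_equal(nrow(loci), 11L)
  expect_equal(interval_length(loci$emmer_start, loci$emmer_end),
               loci$emmer_length)
  expect_equal(interval_length(loci$bw_start, loci$bw_end), loci$bw_length)
})

test_that("a 64-kb deletion with 1-bp microhomology is called to the base", {
  set.seed(51)
  L <- random_dna(3000, 0.46); R <- random_dna(3000, 0.46)
  d <- random_dna(64176, 0.46)
  # deletion bordered by 'A' at both ends, junction guards in place
  d <- paste0("C", substr(d, 2, nchar(d) - 1), "G")
  if (substr(R, 1, 1) %in% c("A", "C")) R <- paste0("T", substr(R, 2, 3000))
  if (substr(L, 3000, 3000) %in% c("G", "A"))
    L <- paste0(substr(L, 1, 2999), "C")
  A <- paste0(L, "A", d, "A", R)
  B <- paste0(L, "A", R)
  ic <- call_indel(A, B, locus_id = "mh_del")
  expect_equal(ic$rearrangement_type, "deletion_in_b")
  expect_equal(ic$ambiguity_width, 1L)
  expect_equal(ic$removed_length, 64177L)         # a_length + ambiguity
  expect_equal(ic$a_length + ic$ambiguity_width, 64177L)
  expect_equal(unname(ic$breakpoint5["a"]), 3001)   # end of left anchor
})

test_that("identical loci give a 'none' call", {
  set.seed(52)
  x <- random_dna(4000, 0.46)
  ic <- call_indel(x, x)
  expect_equal(ic$rearrangement_type, "none")
  expect_equal(ic$removed_length, 0L)
})

test_that("a replacement is called with both lengths recovered", {
  set.seed(53)
  L <- random_dna(3000, 0.46); R <- random_dna(3000, 0.46)
  lost <- random_dna(41455, 0.46)
  gained <- random_dna(10671, 0.46)
  # guard junction characters so borders cannot slide
  substr(gained, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                  substr(lost, 1, 1))[1]
  substr(gained, 10671, 10671) <- setdiff(c("A", "C", "G", "T"),
                                          substr(lost, 41455, 41455))[1]
  ic <- call_indel(paste0(L, lost, R), paste0(L, gained, R))
  expect_equal(ic$rearrangement_type, "replacement")
  expect_equal(ic$a_length, 41455L)
  expect_equal(ic$b_length, 10671L)
})

test_that("tandem copy loss is detected with unit borders from the self plot", {
  set.seed(54)
  L <- random_dna(3000, 0.46); R <- random_dna(3000, 0.46)
  unit <- random_dna(5000, 0.46)
  unit2 <- mutate_seq(unit, 0.01)$seq
  A <- paste0(L, unit, unit2, R)
  B <- paste0(L, unit, R)
  ic <- call_indel(A, B, locus_id = "cnv")
  expect_equal(ic$rearrangement_type, "copy_number_variation")
  expect_equal(ic$cnv$copies_a, 2L)
  expect_equal(ic$cnv$copies_b, 1L)
  expect_gte(ic$cnv$unit_identity, 0.95)
  # unit borders from the self plot agree with the planted unit within the
  # junction ambiguity
  amb <- teindel:::common_prefix_len(unit, unit2)
  expect_lte(abs(ic$cnv$unit_interval_a[1] - 3001), amb + 1)
  expect_lte(abs(ic$cnv$unit_length - 5000), amb + 1)
  # cross-check: no duplication means copies 1/1
  flat <- detect_copy_number_variation(paste0(L, unit, R), paste0(L, unit, R))
  expect_equal(c(flat$copies_a, flat$copies_b), c(1L, 1L))
})

test_that("inversions are recovered from reverse-orientation block runs", {
  set.seed(55)
  L <- random_dna(4000, 0.46); R <- random_dna(4000, 0.46)
  V <- random_dna(30000, 0.46)
  ic <- call_indel(paste0(L, V, R), paste0(L, revcomp(V), R))
  expect_equal(ic$rearrangement_type, "inversion")
  expect_lte(abs(ic$inversion$a_interval[1] - 4001), 30)
  expect_lte(abs(ic$inversion$a_interval[2] - 34000), 30)
  # all-forward blocks: no inversion
  expect_null(detect_inversion(
    find_similarity_blocks(paste0(L, R), paste0(L, R))))
})

test_that("a deletion nested inside an inversion is called as well", {
  set.seed(56)
  L <- random_dna(4000, 0.46); R <- random_dna(4000, 0.46)
  V <- random_dna(30000, 0.46)
  Vdel <- paste0(substr(V, 1, 10000), substr(V, 16001, 30000))
  ic <- call_indel(paste0(L, V, R), paste0(L, revcomp(Vdel), R))
  expect_equal(ic$rearrangement_type, "inversion")
  expect_false(is.null(ic$nested))
  expect_equal(ic$nested$rearrangement_type, "deletion_in_b")
  expect_equal(ic$nested$removed_length + ic$nested$ambiguity_width -
                 max(0, -ic$nested$a_gap), 6000, tolerance = 5)
})

test_that("calls are invariant to extra flanking context", {
  set.seed(57)
  L <- random_dna(12000, 0.46); R <- random_dna(12000, 0.46)
  d <- random_dna(5000, 0.46)
  A <- paste0(L, d, R); B <- paste0(L, R)
  near <- call_indel(substr(A, 10001, nchar(A) - 10000),
                     substr(B, 10001, nchar(B) - 10000),
                     a_offset = 10000, b_offset = 10000)
  far <- call_indel(A, B)
  expect_equal(near$breakpoint5, far$breakpoint5, tolerance = 2)
  expect_equal(near$breakpoint3["a"], far$breakpoint3["a"], tolerance = 2)
  expect_equal(near$removed_length, far$removed_length)
})

test_that("breakpoints abutting N runs are flagged as likely artifacts", {
  set.seed(58)
  L <- random_dna(3000, 0.46); R <- random_dna(3000, 0.46)
  d <- random_dna(4000, 0.46)
  ic <- call_indel(paste0(L, d, R), paste0(L, strrep("N", 400), R))
  expect_true(ic$artifact)
  expect_true(ic$low_confidence)
})
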