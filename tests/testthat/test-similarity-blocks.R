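test_that("identical sequences yield one full-length identity-1 block", {
  set.seed(1)
  x <- random_dna(1000, 0.5)
  b <- find_similarity_blocks(x, x)
  expect_equal(nrow(b), 1L)
  expect_equal(unname(unlist(b[1, c("a_start", "a_end", "b_start",
                                    "b_end")])), c(1, 1000, 1, 1000))
  expect_identical(b$identity, 1)
})

test_that("an internal deletion splits the match into exactly two blocks", {
  set.seed(2)
  x <- random_dna(1000, 0.5)
  y <- paste0(substr(x, 1, 400), substr(x, 701, 1000))
  # exact substring-equality oracle for the two expected pairings
  expect_identical(substr(x, 1, 400), substr(y, 1, 400))
  expect_identical(substr(x, 701, 1000), substr(y, 401, 700))
  b <- find_similarity_blocks(x, y)
  expect_equal(nrow(b), 2L)
  expect_equal(b$a_start, c(1L, 701L))
  expect_equal(b$a_end, c(400L, 1000L))
  expect_equal(b$b_start, c(1L, 401L))
  expect_equal(b$b_end, c(400L, 700L))
})

test_that("independent random sequences yield no blocks", {
  set.seed(3); p <- random_dna(10000, 0.5)
  set.seed(4); q <- random_dna(10000, 0.5)
  expect_equal(nrow(find_similarity_blocks(p, q)), 0L)
})

test_that("self dot plot reports direct and inverted repeats, not the diagonal", {
  set.seed(5)
  x <- random_dna(5000, 0.5)
  b <- self_repeat_blocks(paste0(x, x))
  expect_equal(nrow(b), 1L)
  expect_equal(b$orientation, "forward")
  expect_true(b$a_start <= 5 && b$b_start >= 4996)
  r <- self_repeat_blocks(paste0(x, revcomp(x)))
  expect_true(all(r$orientation == "reverse"))
  expect_gte(sum(r$length), 9000)
  # a repeat-free sequence has no off-diagonal blocks
  set.seed(6)
  expect_equal(nrow(self_repeat_blocks(random_dna(8000, 0.5))), 0L)
})

test_that("planted divergent copy is recovered at its measured identity", {
  set.seed(7)
  x <- random_dna(5000, 0.5)
  xp <- mutate_seq(x, 0.04)$seq
  truth_id <- 1 - sum(utf8ToInt(x) != utf8ToInt(xp)) / 5000
  b <- self_repeat_blocks(paste0(x, xp))
  b <- b[b$orientation == "forward", ]
  expect_gte(sum(b$length), 0.9 * 5000)           # copy essentially covered
  wid <- sum(b$identity * b$length) / sum(b$length)
  expect_lt(abs(wid - truth_id), 0.01)
})

test_that("blocks are symmetric under swapping the sequences", {
  set.seed(8)
  core <- random_dna(3000, 0.5)
  a <- paste0(random_dna(500, 0.5), core, random_dna(400, 0.5))
  b <- paste0(random_dna(300, 0.5), mutate_seq(core, 0.02)$seq,
              random_dna(600, 0.5))
  f <- find_similarity_blocks(a, b)
  g <- find_similarity_blocks(b, a)
  expect_equal(f[, c("a_start", "a_end", "b_start", "b_end")],
               g[, c("b_start", "b_end", "a_start", "a_end")],
               ignore_attr = TRUE)
})

test_that("every block re-scores at or above the identity threshold", {
  set.seed(9)
  for (rate in c(0, 0.02, 0.045)) {
    core <- random_dna(2000, 0.5)
    a <- paste0(random_dna(300, 0.5), core, random_dna(300, 0.5))
    b <- paste0(random_dna(250, 0.5), mutate_seq(core, rate)$seq,
                random_dna(350, 0.5))
    bl <- find_similarity_blocks(a, b)
    expect_gt(nrow(bl), 0)
    for (r in seq_len(nrow(bl))) {
      sa <- utf8ToInt(substr(a, bl$a_start[r], bl$a_end[r]))
      sb <- utf8ToInt(substr(b, bl$b_start[r], bl$b_end[r]))
      expect_gte(mean(sa == sb), 0.95)
      expect_equal(mean(sa == sb), bl$identity[r], tolerance = 1e-9)
    }
  }
})

test_that("raising thresholds never extends coverage (monotonicity)", {
  set.seed(10)
  core <- random_dna(2500, 0.5)
  a <- paste0(random_dna(400, 0.5), core, random_dna(400, 0.5))
  b <- paste0(random_dna(300, 0.5), mutate_seq(core, 0.02)$seq,
              random_dna(500, 0.5))
  loose <- find_similarity_blocks(a, b, 100, 0.95)
  contained_in <- function(strict, loose) {
    all(vapply(seq_len(nrow(strict)), function(i)
      any(loose$a_start <= strict$a_start[i] &
            loose$a_end >= strict$a_end[i]), logical(1)))
  }
  expect_true(contained_in(find_similarity_blocks(a, b, 200, 0.95), loose))
  expect_true(contained_in(find_similarity_blocks(a, b, 100, 0.97), loose))
})

test_that("block set matches the exhaustive window-pair scan on small pairs", {
  set.seed(11)
  fixtures <- list()
  core <- random_dna(600, 0.5)
  fixtures[[1]] <- list(
    a = paste0(random_dna(300, 0.5), core, random_dna(200, 0.5)),
    b = paste0(random_dna(250, 0.5), core, random_dna(300, 0.5)))
  core2 <- random_dna(500, 0.5)
  fixtures[[2]] <- list(
    a = paste0(random_dna(200, 0.5), core2, random_dna(150, 0.5),
               core2, random_dna(150, 0.5)),
    b = paste0(random_dna(100, 0.5), mutate_seq(core2, 0.03)$seq,
               random_dna(300, 0.5)))
  fixtures[[3]] <- list(a = random_dna(1500, 0.5), b = random_dna(1500, 0.5))
  # agreement is up to the end-anchoring of block borders (borders sit at
  # the last stretch whose every terminal sub-segment meets the identity
  # threshold, which can trim a ragged tail): blocks lie inside the window
  # union and cover it up to a bounded per-end loss
  for (fx in fixtures) {
    blocks <- find_similarity_blocks(fx$a, fx$b)
    oh <- oracle_window_hits(fx$a, fx$b)
    expect_blocks_match_window_scan(blocks, oh)
  }
})
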