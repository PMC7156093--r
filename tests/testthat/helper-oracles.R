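# Independent oracles, implemented separately from the package internals.

# Exhaustive windowed dot-plot scan: every (diagonal, start) whose
# min_len-window identity reaches min_id, via stats::filter moving sums.
oracle_window_hits <- function(a, b, min_len = 100, min_id = 0.95) {
  va <- utf8ToInt(toupper(a)); vb <- utf8ToInt(toupper(b))
  na <- length(va); nb <- length(vb)
  need <- ceiling(min_id * min_len)
  hits <- NULL
  for (d in (1 - nb):(na - 1)) {
    lo <- max(1, 1 + d); hi <- min(na, nb + d)
    len <- hi - lo + 1
    if (len < min_len) next
    m <- as.numeric(va[lo:hi] == vb[(lo - d):(hi - d)])
    ws <- stats::filter(m, rep(1, min_len), sides = 1)
    starts <- which(ws[min_len:len] >= need)
    if (length(starts))
      hits <- rbind(hits, data.frame(diag = d, a_start = lo + starts - 1))
  }
  hits
}

# Merge qualifying windows (from oracle_window_hits) into per-diagonal
# union intervals [a_start, a_end].
oracle_window_union <- function(hits, min_len = 100) {
  out <- NULL
  for (d in unique(hits$diag)) {
    s <- sort(hits$a_start[hits$diag == d])
    e <- s + min_len - 1
    grp <- cumsum(c(TRUE, s[-1] > cummax(e)[-length(e)] + 1))
    for (g in unique(grp))
      out <- rbind(out, data.frame(diag = d, a_start = min(s[grp == g]),
                                   a_end = max(e[grp == g])))
  }
  out
}

# Compare a block set against the exhaustive window scan: every block must
# lie inside a window-union interval on its diagonal, and the blocks must
# cover each union interval up to the documented end-anchoring / split loss
# (at most one window length plus the exactness anchor per end).
expect_blocks_match_window_scan <- function(blocks, hits, min_len = 100,
                                            end_loss = 125) {
  if (is.null(hits)) {
    testthat::expect_equal(nrow(blocks), 0L)
    return(invisible())
  }
  uni <- oracle_window_union(hits, min_len)
  for (r in seq_len(nrow(blocks))) {
    d <- blocks$a_start[r] - blocks$b_start[r]
    testthat::expect_true(
      any(uni$diag == d & uni$a_start <= blocks$a_start[r] &
            uni$a_end >= blocks$a_end[r]),
      label = sprintf("block %d inside a window-union interval", r))
  }
  for (r in seq_len(nrow(uni))) {
    d <- uni$a_start[r] - 0
    sel <- blocks$a_start - blocks$b_start == uni$diag[r] &
      blocks$a_start <= uni$a_end[r] & blocks$a_end >= uni$a_start[r]
    cov <- if (any(sel))
      sum(pmin(blocks$a_end[sel], uni$a_end[r]) -
            pmax(blocks$a_start[sel], uni$a_start[r]) + 1)
    else 0
    need <- uni$a_end[r] - uni$a_start[r] + 1 - 2 * end_loss
    testthat::expect_gte(cov, need)
  }
  invisible()
}

# Full affine-gap Smith-Waterman in plain R (small inputs only).
oracle_smith_waterman <- function(q, s, match = 1, mismatch = -2,
                                  gap_open = 5, gap_ext = 2) {
  vq <- strsplit(toupper(q), "")[[1]]; vs <- strsplit(toupper(s), "")[[1]]
  n <- length(vq); m <- length(vs)
  H <- matrix(0, n + 1, m + 1); E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_ext, H[i, j - 1] - gap_open - gap_ext)
      FF[i, j] <- max(FF[i - 1, j] - gap_ext, H[i - 1, j] - gap_open - gap_ext)
      sub <- H[i - 1, j - 1] +
        if (vq[i - 1] == vs[j - 1]) match else mismatch
      H[i, j] <- max(0, sub, E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Brute-force SD-MMEJ enumeration, driven from the template side: every
# substring of the donor flanks (direct and reverse-complement) is tried as
# primer+tract, for one round and for all two-round splits.
oracle_sdmmej <- function(left, right, net, window = 35, max_primer = 8,
                          max_mh = 9, min_template = 4, max_rounds = 2) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  sides <- function(L, R) {
    segs <- list(direct_left = L, direct_right = R,
                 inverted_left = rc(L), inverted_right = rc(R))
    segs
  }
  found_pattern <- function(L, R, pattern, prim_len) {
    # is `pattern` (primer+tract) present with the primer within the window?
    ok <- FALSE
    for (nmo in c(FALSE, TRUE)) {
      pat <- if (nmo) rc(pattern) else pattern
      for (sd in c("L", "R")) {
        seq <- if (sd == "L") L else R
        st <- 1
        repeat {
          p <- regexpr(pat, substr(seq, st, nchar(seq)), fixed = TRUE)
          if (p == -1) break
          pos <- st + p - 1
          end <- pos + nchar(pat) - 1
          dist <- if (sd == "L") nchar(seq) - end else pos - 1
          if (dist <= window) ok <- TRUE
          st <- pos + 1
        }
      }
    }
    ok
  }
  one_side <- function(L, R, netx, side_tag) {
    out <- NULL
    for (mu_len in 1:min(max_mh, nchar(R))) {
      mu <- substr(R, 1, mu_len)
      total <- paste0(netx, mu)
      for (plen in 1:min(max_primer, nchar(L))) {
        p <- substr(L, nchar(L) - plen + 1, nchar(L))
        if (plen + nchar(total) >= min_template &&
            found_pattern(L, R, paste0(p, total), plen))
          out <- rbind(out, data.frame(rounds = 1, side = side_tag,
                                       tract = total, mh = mu))
      }
      if (max_rounds >= 2 && nchar(total) >= 2) {
        for (sp in 1:(nchar(total) - 1)) {
          t1 <- substr(total, 1, sp); t2 <- substr(total, sp + 1,
                                                   nchar(total))
          L2 <- paste0(L, t1)
          ok1 <- any(vapply(1:min(max_primer, nchar(L)), function(pl) {
            p <- substr(L, nchar(L) - pl + 1, nchar(L))
            pl + nchar(t1) >= min_template &&
              found_pattern(L, R, paste0(p, t1), pl)
          }, logical(1)))
          if (!ok1) next
          ok2 <- any(vapply(1:min(max_primer, nchar(L2)), function(pl) {
            p <- substr(L2, nchar(L2) - pl + 1, nchar(L2))
            pl + nchar(t2) >= min_template &&
              found_pattern(L, R, paste0(p, t2), pl)
          }, logical(1)))
          if (ok2)
            out <- rbind(out, data.frame(rounds = 2, side = side_tag,
                                         tract = total, mh = mu))
        }
      }
    }
    out
  }
  res <- rbind(one_side(left, right, net, "left"),
               one_side(rc(right), rc(left), rc(net), "right"))
  if (is.null(res)) return(res)
  unique(res)
}
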