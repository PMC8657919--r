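test_that("sequence weights follow the identity-counting rule", {
  a <- msa(rep("MKVL", 4))
  w <- sequence_weights(a)
  expect_equal(w$weights, rep(0.25, 4))
  expect_equal(w$neff, 1)

  a <- msa(c("AAAA", "CCCC", "WWWW"))
  w <- sequence_weights(a, 0.8)
  expect_equal(w$weights, rep(1, 3))
  expect_equal(w$neff, 3)

  # brute-force pairwise identity: rows 1,2 identical, row 3 distinct
  a <- msa(c("AAAA", "AAAA", "WWWW"))
  w <- sequence_weights(a, 0.8)
  expect_equal(w$weights, c(0.5, 0.5, 1))
})

test_that("weighted frequencies normalize and marginalize", {
  a <- msa("AA")
  w <- sequence_weights(a)
  fr <- weighted_frequencies(a, w, pseudocount = 0)
  expect_equal(fr$site[1, ], c(1, rep(0, 20)))  # indicator of 'A'
  expect_equal(rowSums(fr$site), rep(1, 2))

  a <- msa(c("AW", "CW"))
  fr <- weighted_frequencies(a, sequence_weights(a), 0)
  expect_equal(fr$site[1, 1:2], c(0.5, 0.5))
  # pair table marginalizes to the site table at zero pseudocount
  marg <- apply(fr$pair[1, 2, , ], 1, sum)
  expect_equal(marg, fr$site[1, ])
})

test_that("APC correction removes product structure", {
  # off-diagonal entries of a rank-1 product matrix are nearly annihilated
  # (exactly so as the spread of a shrinks; the diagonal is excluded from
  # the means and is not meaningful here)
  a <- seq(1, 1.5, length.out = 12)
  F <- outer(a, a); diag(F) <- 0
  corrected <- apc_correct(F)
  off <- corrected[upper.tri(corrected)]
  expect_lt(max(abs(off)) / max(F), 0.05)
  expect_equal(apc_correct(matrix(0, 3, 3)), matrix(0, 3, 3))

  # hand-computed 3x3 case
  F <- matrix(c(0, 2, 4,
                2, 0, 6,
                4, 6, 0), 3, 3)
  rm <- rowSums(F) / 2
  gm <- sum(F) / 6
  expect_equal(apc_correct(F), F - outer(rm, rm) / gm)
})

test_that("DCA has 442 channels and vanishes on constant alignments", {
  a <- random_msa(8, 30, 0.5, seed = 3)
  d <- compute_dca(a)
  expect_equal(d$n_channels, 442L)
  expect_equal(dim(d$couplings), c(8L, 8L, 441L))

  const <- msa(rep("MKVLAW", 10))
  d0 <- compute_dca(const, shrinkage = 0.1)
  off <- d0$couplings
  for (i in 1:6) off[i, i, ] <- 0  # self-blocks hold inverse variances
  expect_lt(max(abs(off)), 1e-8)
  expect_equal(d0$apc_score, matrix(0, 6, 6))
})

test_that("DCA couplings are block-transpose symmetric and row-order invariant", {
  a <- random_msa(10, 60, 0.5, seed = 8)
  d <- compute_dca(a)
  b25 <- matrix(d$couplings[2, 5, ], 21, 21)
  b52 <- matrix(d$couplings[5, 2, ], 21, 21)
  expect_equal(b25, t(b52), tolerance = 1e-10)
  expect_equal(d$apc_score, t(d$apc_score), tolerance = 1e-10)

  set.seed(42)
  perm <- c(1, sample(2:a$depth))  # keep the query row first
  a2 <- msa(a$sequences[perm], a$ids[perm])
  d2 <- compute_dca(a2)
  expect_equal(d2$apc_score, d$apc_score, tolerance = 1e-8)
})

test_that("APC scores shrink monotonically toward 0 as shrinkage grows", {
  a <- random_msa(10, 80, 0.5, seed = 9)
  tot <- vapply(c(0.5, 5, 50),
                function(s) sum(compute_dca(a, shrinkage = s)$apc_score^2),
                0)
  expect_true(all(diff(tot) < 0))
  expect_lt(tot[3], 1e-4 * tot[1])
})

test_that("DCA recovers planted Potts couplings", {
  spec <- potts_spec(L = 40, n_seq = 2000, n_pairs = 8, seed = 1)
  aln <- potts_sample(spec)
  apc <- compute_dca(aln)$apc_score
  ut <- which(upper.tri(apc) & abs(row(apc) - col(apc)) >= 5,
              arr.ind = TRUE)
  top8 <- ut[order(-apc[ut])[1:8], , drop = FALSE]
  planted <- paste(pmin(spec$planted_pairs[, 1], spec$planted_pairs[, 2]),
                   pmax(spec$planted_pairs[, 1], spec$planted_pairs[, 2]))
  expect_gte(sum(paste(top8[, 1], top8[, 2]) %in% planted), 6)
})

test_that("MSA-derived profiles have valid emissions", {
  a <- msa("MKVLW")
  p <- profile_from_msa(a)
  onehot <- diag(20)[encode_sequence("MKVLW"), ]
  expect_equal(unname(p$profile[, 1:20]), onehot)

  a <- msa(c("AC", "CA"))
  p <- profile_from_msa(a)
  expect_equal(unname(p$profile[1, c("A", "C")]), c(0.5, 0.5))
  a <- random_msa(12, 40, 0.5, seed = 5, gap_rate = 0.2)
  p <- profile_from_msa(a)
  expect_true(all(rowSums(p$profile[, 1:20]) <= 1 + 1e-9))
})

test_that("assembled input honors the 547-channel budget", {
  aln <- random_msa(9, 15, 0.3, seed = 6)
  pw <- assemble_input(aln)
  expect_equal(dim(pw$tensor), c(9L, 9L, 547L))
  # one-hot block of (i,j) equals the swapped block of (j,i)
  expect_equal(pw$tensor[3, 6, 1:21], pw$tensor[6, 3, 22:42])
  # index channels are 0-based positions
  expect_equal(pw$tensor[3, 6, 43], 2)
  expect_equal(pw$tensor[3, 6, 44], 5)
  expect_true(all(pw$tensor[, , 547] == 1))
  expect_equal(pw$tensor[2, 7, 546],
               compute_dca(aln)$apc_score[2, 7])

  short <- profile_from_msa(random_msa(5, 3, seed = 1))
  expect_error(assemble_input(aln, profile = short), "mismatch")
})

test_that("features of a subsampled MSA keep their shapes", {
  aln <- random_msa(7, 41, 0.4, seed = 10)
  sub <- subsample_msa(aln, 0.5, seed = 2)
  expect_equal(sub$depth, 21)  # query + round(0.5 * 40)
  expect_equal(dim(assemble_input(sub)$tensor),
               dim(assemble_input(aln)$tensor))
})
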