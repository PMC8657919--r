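test_that("coverage crops guarantee repeated full coverage", {
  expect_equal(length(coverage_crops(64, 64, 1)), 1)

  cover_count <- function(crops, L) {
    cover <- matrix(0L, L, L)
    for (cr in crops) {
      ri <- intersect(seq(cr$origin[1], cr$origin[1] + cr$size - 1),
                      0:(L - 1))
      ci <- intersect(seq(cr$origin[2], cr$origin[2] + cr$size - 1),
                      0:(L - 1))
      cover[ri + 1, ci + 1] <- cover[ri + 1, ci + 1] + 1L
    }
    cover
  }
  # the high-accuracy setting: 10 offsets -> every cell covered >= 10 times
  cov <- cover_count(coverage_crops(100, 64, 10), 100)
  expect_true(all(cov >= 10))
  # coverage holds for arbitrary small geometries, seeded or not
  for (case in list(c(16, 16, 1), c(20, 8, 3), c(37, 16, 5), c(9, 4, 2))) {
    expect_true(all(cover_count(
      coverage_crops(case[1], case[2], case[3]), case[1]) >= case[3]))
    expect_true(all(cover_count(
      coverage_crops(case[1], case[2], case[3], seed = 1), case[1]) >= 1))
  }
  # more offsets never uncover a cell
  c1 <- cover_count(coverage_crops(30, 16, 2), 30)
  c2 <- cover_count(coverage_crops(30, 16, 4), 30)
  expect_true(all(c2 >= c1))
})

test_that("aggregation averages covering crops and symmetrizes", {
  # all crops predicting one fixed distribution reproduce it everywhere
  p_fix <- (1:10) / sum(1:10)
  cs <- 8; L <- 20
  crops <- coverage_crops(L, cs, 2)
  preds <- lapply(crops, function(cr) {
    pr <- random_crop_prediction(cr$origin, cs)
    pr$dist <- array(rep(p_fix, each = cs * cs), c(cs, cs, 10))
    pr
  })
  dg <- aggregate_crops(preds, L)
  expect_equal(dg$probs[3, 17, ], p_fix, tolerance = 1e-12)

  # two crops covering one cell -> (p + q) / 2
  pr1 <- random_crop_prediction(c(0, 0), 4)
  pr2 <- random_crop_prediction(c(0, 0), 4)
  dg2 <- aggregate_crops(list(pr1, pr2), 4)
  want <- (pr1$dist + pr2$dist) / 2
  want <- (want + aperm(want, c(2, 1, 3))) / 2
  expect_equal(dg2$probs, want, tolerance = 1e-12)

  # random crop sets vs a brute-force per-cell mean oracle
  set.seed(12)
  crops <- coverage_crops(L, cs, 3)
  preds <- lapply(crops, function(cr) random_crop_prediction(cr$origin, cs))
  dg <- aggregate_crops(preds, L)
  bf <- array(0, c(L, L, 10)); cnt <- matrix(0, L, L)
  for (p in preds) for (a in 1:cs) for (b in 1:cs) {
    i <- p$origin[1] + a; j <- p$origin[2] + b
    if (i >= 1 && i <= L && j >= 1 && j <= L) {
      bf[i, j, ] <- bf[i, j, ] + p$dist[a, b, ]
      cnt[i, j] <- cnt[i, j] + 1
    }
  }
  bf <- bf / as.vector(cnt)
  bf <- (bf + aperm(bf, c(2, 1, 3))) / 2
  expect_lt(max(abs(dg$probs - bf)), 1e-10)
  expect_equal(dg$probs[2, 9, ], dg$probs[9, 2, ])

  # permutation invariance in crop order
  dg_perm <- aggregate_crops(rev(preds), L)
  expect_equal(dg_perm$probs, dg$probs, tolerance = 1e-12)

  # uncovered cells are reported
  expect_error(aggregate_crops(list(random_crop_prediction(c(0, 0), 4)), 10),
               "not covered")
})

test_that("ensembling is a simplex average with identity on singletons", {
  set.seed(5)
  preds <- lapply(coverage_crops(12, 6, 1),
                  function(cr) random_crop_prediction(cr$origin, 6))
  dg <- aggregate_crops(preds, 12)
  expect_equal(ensemble_distograms(list(dg))$probs, dg$probs,
               tolerance = 1e-12)
  expect_equal(ensemble_distograms(list(dg, dg, dg))$probs, dg$probs,
               tolerance = 1e-12)

  # one-hot classes 0 and 1 average to (0.5, 0.5, 0, ...)
  dg1 <- dg; dg2 <- dg
  oh <- function(k) { v <- rep(0, 10); v[k] <- 1; v }
  dg1$probs[1, 2, ] <- oh(1); dg1$probs[2, 1, ] <- oh(1)
  dg2$probs[1, 2, ] <- oh(2); dg2$probs[2, 1, ] <- oh(2)
  e <- ensemble_distograms(list(dg1, dg2))
  expect_equal(e$probs[1, 2, ], c(0.5, 0.5, rep(0, 8)))

  # renormalization is a numerical no-op on already-normalized input
  sums <- apply(ensemble_distograms(list(dg1, dg2))$probs, c(1, 2), sum)
  expect_equal(sums, matrix(1, 12, 12), tolerance = 1e-12)

  dg_short <- aggregate_crops(lapply(coverage_crops(6, 6, 1), function(cr)
    random_crop_prediction(cr$origin, 6)), 6)
  expect_error(ensemble_distograms(list(dg, dg_short)), "mismatch")
})

test_that("contact probability sums the first three bins", {
  preds <- lapply(coverage_crops(8, 8, 1),
                  function(cr) random_crop_prediction(cr$origin, 8))
  dg <- aggregate_crops(preds, 8)
  dg$probs[1, 2, ] <- rep(0.1, 10)
  dg$probs[3, 4, ] <- c(rep(0, 9), 1)
  dg$probs[5, 6, ] <- c(0, 0, 1, rep(0, 7))
  P <- contact_probability(dg)
  expect_equal(P[1, 2], 0.3)
  expect_equal(P[3, 4], 0)
  expect_equal(P[5, 6], 1)
})

test_that("full-length prediction tiles, aggregates and ensembles", {
  aln <- random_msa(20, 10, 0.3, seed = 7)
  feats <- assemble_input(aln)
  cfg <- distnet_config(in_channels = 547, n_blocks = 2, wide_blocks = 1,
                        wide_channels = 8, narrow_channels = 4,
                        crop_size = 16, dropout = 0)
  m1 <- build_model(cfg, seed = 1)
  m2 <- build_model(cfg, seed = 2)
  dg <- predict_distogram(list(m1, m2), feats, n_offsets = 2)
  expect_equal(dim(dg$probs), c(20L, 20L, 10L))
  expect_equal(apply(dg$probs, c(1, 2), sum), matrix(1, 20, 20),
               tolerance = 1e-5)
  expect_equal(dg$probs[4, 11, ], dg$probs[11, 4, ], tolerance = 1e-12)
  expect_true(all(dg$coverage >= 4))  # 2 models x 2 offsets
})
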