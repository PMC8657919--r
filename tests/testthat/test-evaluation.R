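test_that("contacts use the strict 8-Angstrom C-beta rule", {
  mk_res <- function(x, resid = "ALA") {
    m <- rbind(N = x + c(-0.7, 0.5, 0), CA = x, C = x + c(0.7, 0.5, 0),
               CB = x + c(0, 0, 0.5))
    if (resid == "GLY") m <- m[c("N", "CA", "C"), ]
    m
  }
  # residues 1 and 2: CB distance 7.9 -> contact; 1 and 3: exactly 8 -> not
  ch <- structure_chain(
    c("ALA", "ALA", "ALA"),
    list(mk_res(c(0, 0, 0)), mk_res(c(7.9, 0, 0)), mk_res(c(-8, 0, 0))))
  tc <- true_contacts(ch)
  expect_true(any(tc[, 1] == 1 & tc[, 2] == 2))
  expect_false(any(tc[, 1] == 1 & tc[, 2] == 3))
  expect_true(all(tc[, 1] < tc[, 2]))  # no self-contacts

  # glycine falls back to CA
  chg <- structure_chain(
    c("GLY", "ALA"),
    list(mk_res(c(0, 0, 0), "GLY"), mk_res(c(7.5, 0, 0))))
  expect_equal(nrow(true_contacts(chg)), 1)
})

test_that("separation ranges partition pairs at the printed boundaries", {
  expect_equal(range_of(1, 7), "short")    # sep 6
  expect_equal(range_of(1, 12), "short")   # sep 11
  expect_equal(range_of(1, 13), "mid")     # sep 12
  expect_equal(range_of(1, 24), "mid")     # sep 23
  expect_equal(range_of(1, 25), "long")    # sep 24
  expect_equal(range_of(1, 6), "none")     # sep 5
  # the three ranges plus "none" partition all off-diagonal pairs
  seps <- expand.grid(i = 1:40, j = 1:40)
  seps <- seps[seps$i != seps$j, ]
  r <- range_of(seps$i, seps$j)
  expect_true(all(r %in% c("short", "mid", "long", "none")))
  expect_equal(sum(table(r)), nrow(seps))
})

test_that("top-L normalized accuracy matches exhaustive enumeration", {
  # toy: 6x6 map, L = 5, mid-range impossible; plant 3 short-range contacts
  set.seed(21)
  n <- 14; L <- 5
  truth <- rbind(c(1, 7), c(2, 9), c(3, 12))   # separations 6, 7, 9
  P <- matrix(0, n, n)
  P[truth] <- c(0.9, 0.8, 0.7)
  P[cbind(1, 8:10)] <- c(0.6, 0.5, 0.4)        # decoys, also short range
  P <- P + t(P)
  # top-5 short-range picks include all 3 true contacts; denom = min(5, 3)
  expect_equal(topL_accuracy(P, truth, L, "short"), 1.0)

  # brute-force oracle under the documented lexicographic tie-break
  Pu <- matrix(0.5, n, n)
  ut <- which(upper.tri(Pu), arr.ind = TRUE)
  keep <- abs(ut[, 1] - ut[, 2]) >= 6 & abs(ut[, 1] - ut[, 2]) <= 11
  pairs <- ut[keep, , drop = FALSE]
  ord <- order(pairs[, 1], pairs[, 2])  # equal probs -> pure lexicographic
  top <- pairs[ord[seq_len(min(L, nrow(pairs)))], , drop = FALSE]
  tp <- sum(paste(top[, 1], top[, 2]) %in% paste(truth[, 1], truth[, 2]))
  expect_equal(topL_accuracy(Pu, truth, L, "short"),
               tp / min(L, nrow(truth)))

  # no true contacts in range -> undefined
  expect_true(is.na(topL_accuracy(P, truth, L, "long")))
})

test_that("a perfect predictor scores 1.0 in every defined range", {
  ch <- lattice_chain(64)
  tc <- true_contacts(ch)
  P <- matrix(0, 64, 64); P[tc] <- 1; P <- P + t(P)
  sc <- evaluate_contacts(P, ch)
  expect_equal(unname(sc[c("short", "mid", "long")]), c(1, 1, 1))
  # scores never exceed 1 and are monotone-transform invariant
  sc2 <- evaluate_contacts(P * 0.3 + 0.1, ch)  # monotone rescale
  expect_equal(sc2, sc)
})

test_that("depth correlations recover planted relationships", {
  rep_lin <- eval_report(data.frame(
    target = paste0("T", 1:8),
    short = seq(0.1, 0.8, by = 0.1), mid = seq(0.1, 0.8, by = 0.1),
    long = seq(0.1, 0.8, by = 0.1),
    msa_depth = seq(40, 390, by = 50), length = 100))
  r <- suppressWarnings(accuracy_depth_correlation(rep_lin))
  expect_equal(unname(r["r_shallow"]), 1.0)  # deep stratum is empty -> NA

  # constant accuracies: zero variance -> NA
  rep_const <- eval_report(data.frame(
    target = paste0("T", 1:6), short = 0.5, mid = 0.5, long = 0.5,
    msa_depth = c(10, 20, 30, 500, 600, 700), length = 1:6 * 30))
  r <- suppressWarnings(accuracy_depth_correlation(rep_const))
  expect_true(is.na(r["r_shallow"]))

  # planted slope + noise vs the closed-form Pearson formula
  set.seed(33)
  depth <- seq(20, 380, length.out = 12)
  acc <- 0.2 + 0.001 * depth + rnorm(12, sd = 0.03)
  repl <- eval_report(data.frame(
    target = paste0("T", 1:12), short = acc, mid = acc, long = acc,
    msa_depth = depth, length = 80))
  r <- suppressWarnings(accuracy_depth_correlation(repl))  # deep stratum empty
  closed <- sum((depth - mean(depth)) * (acc - mean(acc))) /
    sqrt(sum((depth - mean(depth))^2) * sum((acc - mean(acc))^2))
  expect_equal(unname(r["r_shallow"]), closed, tolerance = 1e-12)

  # under 3 targets in a stratum -> warning + NA (one per tiny stratum)
  w <- testthat::capture_warnings(
    r2 <- accuracy_depth_correlation(eval_report(data.frame(
      target = c("a", "b"), short = c(0.1, 0.2), mid = c(0.1, 0.2),
      long = c(0.1, 0.2), msa_depth = c(10, 20), length = c(30, 40)))))
  expect_true(all(grepl("fewer than 3", w)))
  expect_true(is.na(r2["r_shallow"]))
})

test_that("report set averages skip undefined ranges", {
  repd <- eval_report(data.frame(
    target = c("A", "B", "C"),
    short = c(0.5, NA, 1), mid = c(0.2, 0.4, 0.6), long = c(NA, NA, 0.9),
    msa_depth = c(10, 100, 1000), length = c(50, 60, 70)))
  avg <- attr(repd, "set_average")
  expect_equal(unname(avg["short"]), 0.75)
  expect_equal(unname(avg["long"]), 0.9)
})
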