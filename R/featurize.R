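#' Identity-based sequence weights
#'
#' The standard reweighting used ahead of direct-coupling analysis: the
#' weight of row r is 1 / (number of rows, including itself, whose fractional
#' identity to r is at least \code{identity_threshold}). The effective depth
#' Neff is the sum of weights.
#'
#' @param aln an \code{\link{msa}}.
#' @param identity_threshold fraction in (0, 1); default 0.8.
#' @return An object of class \code{"sequence_weights"}: list with
#'   \code{weights} (one per row, each in (0, 1]) and \code{neff}.
#' @export
sequence_weights <- function(aln, identity_threshold = 0.8) {
  stopifnot(inherits(aln, "msa"),
            identity_threshold > 0, identity_threshold < 1)
  X <- msa_matrix(aln)
  n <- nrow(X); L <- ncol(X)
  matches <- matrix(0L, n, n)
  for (j in seq_len(L)) {
    matches <- matches + outer(X[, j], X[, j], "==")
  }
  counts <- rowSums(matches / L >= identity_threshold)
  w <- 1 / counts
  structure(list(weights = w, neff = sum(w),
                 identity_threshold = identity_threshold),
            class = "sequence_weights")
}

#' Weighted single-site and pairwise state frequencies
#'
#' With \code{pseudocount = 0} the pair table marginalizes exactly to the
#' site table. Frequencies are over the full 21-state alphabet. The pair
#' table is dense (L x L x 21 x 21); use small L, or the covariance path
#' inside \code{\link{compute_dca}} which never materializes it.
#'
#' @param aln an \code{\link{msa}}.
#' @param w a \code{\link{sequence_weights}} result.
#' @param pseudocount nonnegative uniform pseudocount mass.
#' @return list with \code{site} (L x 21) and \code{pair} (L x L x 21 x 21).
#' @export
weighted_frequencies <- function(aln, w = sequence_weights(aln),
                                 pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  X <- msa_matrix(aln)
  n <- nrow(X); L <- ncol(X)
  wt <- w$weights; tot <- sum(wt)
  site <- matrix(0, L, 21)
  for (a in 1:21) site[, a] <- colSums(wt * (X == a))
  site <- (site + pseudocount / 21) / (tot + pseudocount)
  pair <- array(0, c(L, L, 21, 21))
  for (a in 1:21) {
    Ia <- wt * (X == a)
    for (b in 1:21) {
      pair[, , a, b] <- t(Ia) %*% (X == b)
    }
  }
  pair <- (pair + pseudocount / 441) / (tot + pseudocount)
  list(site = site, pair = pair)
}

#' Average-product correction of a coupling-strength matrix
#'
#' Removes background row/column effects: output(i, j) =
#' F(i, j) - rowmean(i) * rowmean(j) / grandmean, with all means computed
#' excluding the diagonal. A zero grand mean returns an all-zero matrix.
#'
#' @param F square symmetric nonnegative matrix.
#' @return matrix of the same shape.
#' @export
apc_correct <- function(F) {
  stopifnot(is.matrix(F), nrow(F) == ncol(F))
  n <- nrow(F)
  if (n < 2) return(F * 0)
  Fo <- F; diag(Fo) <- 0
  rm <- rowSums(Fo) / (n - 1)
  gm <- sum(Fo) / (n * (n - 1))
  if (gm == 0) return(F * 0)
  F - outer(rm, rm) / gm
}

#' Direct-coupling analysis by regularized inverse covariance
#'
#' Columns are one-hot encoded over the 20 amino-acid states (the gap state
#' is excluded from the inverted system and re-inserted as zeros to fill the
#' 21 x 21 per-pair blocks). The sequence-weighted covariance of the 20L
#' one-hot columns gets \code{shrinkage} added to its diagonal and is
#' inverted; the coupling block for pair (i, j) is the corresponding 20 x 20
#' sub-block of the precision matrix. The pair coupling strength is the
#' Frobenius norm of that block, and \code{apc_score} is its
#' average-product-corrected version with a zero diagonal.
#'
#' @param aln an \code{\link{msa}}.
#' @param identity_threshold reweighting threshold, see
#'   \code{\link{sequence_weights}}.
#' @param shrinkage diagonal regularization; \code{NULL} selects the default
#'   4.5 / sqrt(Neff * L).
#' @return An object of class \code{"dca_features"}: list with
#'   \code{couplings} (L x L x 441), \code{apc_score} (L x L),
#'   \code{n_channels} (442) and \code{neff}.
#' @export
compute_dca <- function(aln, identity_threshold = 0.8, shrinkage = NULL) {
  stopifnot(inherits(aln, "msa"))
  w <- sequence_weights(aln, identity_threshold)
  X <- msa_matrix(aln)
  n <- nrow(X); L <- ncol(X)
  if (is.null(shrinkage)) shrinkage <- 4.5 / sqrt(w$neff * L)
  # one-hot over the 20 residue states; gaps encode as all-zero
  Z <- matrix(0, n, 20L * L)
  for (a in 1:20) {
    hit <- X == a
    cols <- (seq_len(L) - 1L) * 20L + a
    Z[, cols] <- hit
  }
  wt <- w$weights / w$neff
  f <- colSums(Z * wt)
  C <- crossprod(Z, Z * wt) - tcrossprod(f)
  diag(C) <- diag(C) + shrinkage
  J <- tryCatch(solve(C), error = function(e) {
    stop("covariance inversion failed despite shrinkage ",
         signif(shrinkage, 3),
         "; supply a larger `shrinkage` (alignment too shallow?)")
  })
  # reshape 20L x 20L precision into (21,21,L,L) blocks, gap state zero
  J4 <- aperm(array(J, c(20L, L, 20L, L)), c(1, 3, 2, 4))  # [a,b,i,j]
  A <- array(0, c(21L, 21L, L, L))
  A[1:20, 1:20, , ] <- J4
  couplings <- aperm(A, c(3, 4, 1, 2))
  dim(couplings) <- c(L, L, 441L)
  Fn <- sqrt(apply(J4^2, c(3, 4), sum))
  diag(Fn) <- 0
  apc <- apc_correct(Fn)
  diag(apc) <- 0
  structure(list(couplings = couplings, apc_score = apc,
                 n_channels = 442L, neff = w$neff, shrinkage = shrinkage),
            class = "dca_features")
}

#' @export
print.dca_features <- function(x, ...) {
  L <- nrow(x$apc_score)
  cat(sprintf("dca_features: L = %d, %d channels, Neff = %.1f\n",
              L, x$n_channels, x$neff))
  invisible(x)
}

#' Channel budget of the pairwise input tensor
#'
#' Named channel offsets into the depth-547 axis: 21 one-hot values for each
#' of residues i and j, the two integer residue-index channels, two 30-value
#' HMM profile blocks, 441 coupling channels plus the APC score (442 DCA
#' channels in total), and one validity-mask channel.
#' @export
INPUT_CHANNELS <- list(onehot_i = 1:21, onehot_j = 22:42,
                       index_i = 43L, index_j = 44L,
                       hmm_i = 45:74, hmm_j = 75:104,
                       dca_couplings = 105:545, dca_apc = 546L,
                       mask = 547L)

#' Assemble the L x L x 547 pairwise input tensor
#'
#' Cell (i, j) stacks the one-hot encodings of query residues i and j, their
#' 0-based integer positions, the two 30-value HMM profile rows, the 441
#' inter-column coupling values and the APC coupling score for the pair, and
#' a validity mask (1 on real residues; cropping sets it to 0 on padding).
#'
#' @param aln an \code{\link{msa}} (row 1 is the query).
#' @param profile an \code{\link{hmm_profile}} for the query, from
#'   \code{\link{read_hhm}} or \code{\link{profile_from_msa}}.
#' @param dca a \code{\link{dca_features}} result for the same alignment.
#' @return An object of class \code{"pairwise_input"}: list with
#'   \code{tensor} (L x L x 547 array) and \code{L}.
#' @export
assemble_input <- function(aln, profile = profile_from_msa(aln),
                           dca = compute_dca(aln)) {
  stopifnot(inherits(aln, "msa"), inherits(profile, "hmm_profile"),
            inherits(dca, "dca_features"))
  L <- aln$length
  if (profile$length != L || nrow(dca$apc_score) != L) {
    stop(sprintf(
      "length mismatch: alignment L=%d, profile L=%d, dca L=%d",
      L, profile$length, nrow(dca$apc_score)))
  }
  q <- encode_sequence(aln$sequences[1])
  onehot <- diag(21)[q, , drop = FALSE]            # L x 21
  x <- array(0, c(L, L, 547L))
  ones <- matrix(1, L, L)
  for (a in 1:21) {
    x[, , a]       <- onehot[, a] * ones           # varies with i (rows)
    x[, , 21L + a] <- t(onehot[, a] * ones)        # varies with j (cols)
  }
  idx0 <- seq_len(L) - 1
  x[, , 43L] <- idx0 * ones
  x[, , 44L] <- t(idx0 * ones)
  for (k in 1:30) {
    x[, , 44L + k]  <- profile$profile[, k] * ones
    x[, , 74L + k]  <- t(profile$profile[, k] * ones)
  }
  x[, , 105:545] <- dca$couplings
  x[, , 546L] <- dca$apc_score
  x[, , 547L] <- 1
  structure(list(tensor = x, L = L), class = "pairwise_input")
}

#' @export
print.pairwise_input <- function(x, ...) {
  cat(sprintf("pairwise_input: %d x %d x %d tensor\n",
              x$L, x$L, dim(x$tensor)[3]))
  invisible(x)
}
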