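#' True contacts of a structure
#'
#' Unordered residue pairs (i < j, 1-based) whose C-beta distance (C-alpha
#' for glycine) is strictly less than 8 Angstroms; pairs involving
#' unresolved residues are excluded.
#'
#' @param chain a \code{\link{structure_chain}}.
#' @return 2-column integer matrix of contacting pairs.
#' @export
true_contacts <- function(chain) {
  L <- chain$length
  cb <- lapply(seq_len(L), function(i)
    cb_coordinate(chain$atoms[[i]], chain$resid[i]))
  have <- which(!vapply(cb, is.null, TRUE))
  if (length(have) < 2) return(matrix(integer(0), 0, 2))
  M <- do.call(rbind, cb[have])
  D <- as.matrix(stats::dist(M))
  hit <- which(D < 8 & upper.tri(D), arr.ind = TRUE)
  cbind(have[hit[, 1]], have[hit[, 2]])
}

#' Sequence-separation range of residue pairs
#'
#' Short = separation 6 to 11, mid = 12 to 23, long = 24 or more; pairs
#' closer than 6 are excluded ("none").
#'
#' @param i,j residue indices (any common base; only |i - j| matters).
#' @return character vector: "short", "mid", "long" or "none".
#' @export
range_of <- function(i, j) {
  sep <- abs(i - j)
  out <- rep("none", length(sep))
  out[sep >= 6 & sep <= 11] <- "short"
  out[sep >= 12 & sep <= 23] <- "mid"
  out[sep >= 24] <- "long"
  out
}

#' Normalized top-L contact precision in one separation range
#'
#' Pairs in the range are ranked by predicted probability (ties broken by
#' ascending (i, j) order) and the top min(L, number of in-range pairs) are
#' called contacts. The precision TP / (TP + FP) is normalized by
#' min(L, number of true in-range contacts) so that 100 percent is always
#' achievable; with no true contacts in the range the score is undefined
#' (NA).
#'
#' @param P L x L contact probability matrix.
#' @param truth 2-column matrix of true contact pairs (1-based, i < j).
#' @param L sequence length (the "L" of top-L).
#' @param range "short", "mid" or "long".
#' @return fraction in [0, 1], or NA when undefined.
#' @export
topL_accuracy <- function(P, truth, L, range = c("long", "mid", "short")) {
  range <- match.arg(range)
  n <- nrow(P)
  ut <- which(upper.tri(P), arr.ind = TRUE)
  keep <- range_of(ut[, 1], ut[, 2]) == range
  pairs <- ut[keep, , drop = FALSE]
  if (!nrow(pairs)) return(NA_real_)
  truth_keys <- if (nrow(truth)) {
    tr <- cbind(pmin(truth[, 1], truth[, 2]), pmax(truth[, 1], truth[, 2]))
    tr <- tr[range_of(tr[, 1], tr[, 2]) == range, , drop = FALSE]
    paste(tr[, 1], tr[, 2])
  } else character(0)
  n_true <- length(truth_keys)
  if (n_true == 0) return(NA_real_)
  prob <- P[pairs]
  ord <- order(-prob, pairs[, 1], pairs[, 2])
  k <- min(L, nrow(pairs))
  top <- pairs[ord[seq_len(k)], , drop = FALSE]
  tp <- sum(paste(top[, 1], top[, 2]) %in% truth_keys)
  tp / min(L, n_true)
}

#' Evaluate one target in all three ranges
#'
#' @param P contact probability map (e.g. from
#'   \code{\link{contact_probability}}).
#' @param chain reference \code{\link{structure_chain}} (or a precomputed
#'   2-column truth matrix).
#' @param L sequence length; defaults to \code{nrow(P)}.
#' @return named numeric: short, mid, long, average (mean over defined
#'   ranges).
#' @export
evaluate_contacts <- function(P, chain, L = nrow(P)) {
  truth <- if (inherits(chain, "structure_chain")) true_contacts(chain)
           else chain
  sc <- c(short = topL_accuracy(P, truth, L, "short"),
          mid = topL_accuracy(P, truth, L, "mid"),
          long = topL_accuracy(P, truth, L, "long"))
  c(sc, average = mean(sc, na.rm = TRUE))
}

#' Build a multi-target evaluation report
#'
#' @param targets data.frame with columns \code{target}, \code{short},
#'   \code{mid}, \code{long}, \code{msa_depth}, \code{length}.
#' @return data.frame of class \code{"eval_report"} with an added
#'   \code{average} column; set-level averages are attached as the
#'   \code{"set_average"} attribute (mean over targets with a defined score
#'   in each range).
#' @export
eval_report <- function(targets) {
  stopifnot(all(c("target", "short", "mid", "long", "msa_depth",
                  "length") %in% names(targets)))
  targets$average <- rowMeans(targets[, c("short", "mid", "long")],
                              na.rm = TRUE)
  attr(targets, "set_average") <-
    colMeans(targets[, c("short", "mid", "long", "average")], na.rm = TRUE)
  class(targets) <- c("eval_report", "data.frame")
  targets
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d targets\n", nrow(x)))
  print.data.frame(x, row.names = FALSE)
  cat("set averages:\n")
  print(round(attr(x, "set_average"), 4))
  invisible(x)
}

#' Accuracy vs MSA depth and length correlations
#'
#' Splits targets at \code{depth_threshold} (the published analysis uses
#' 400) and reports the Pearson correlation of (MSA depth, average accuracy)
#' within each stratum, plus the correlation of (sequence length, average
#' accuracy) over all targets. Strata with fewer than 3 targets, or with
#' zero variance, yield NA with a warning.
#'
#' @param report an \code{\link{eval_report}}.
#' @param depth_threshold depth split point.
#' @return named numeric: \code{r_shallow}, \code{r_deep}, \code{r_length}.
#' @export
accuracy_depth_correlation <- function(report, depth_threshold = 400) {
  safe_cor <- function(x, y) {
    if (length(x) < 3) {
      warning("fewer than 3 targets in stratum; correlation undefined")
      return(NA_real_)
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  shallow <- report$msa_depth < depth_threshold
  c(r_shallow = safe_cor(report$msa_depth[shallow],
                         report$average[shallow]),
    r_deep = safe_cor(report$msa_depth[!shallow],
                      report$average[!shallow]),
    r_length = safe_cor(report$length, report$average))
}
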