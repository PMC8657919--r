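#' Aggregate crop predictions into a full-length distogram
#'
#' Each cell's 10-class distribution is the arithmetic mean over all crops
#' covering it (zero-padded crop cells outside the sequence are excluded),
#' so cells covered by more crops are corrected for through averaging. The
#' distogram is then symmetrized by averaging cell (i, j) with (j, i).
#' Per-residue auxiliary predictions are averaged the same way over the
#' row-axis and column-axis heads of all covering crops.
#'
#' @param crop_preds list of \code{"crop_prediction"} objects whose crops
#'   collectively cover [0, L)^2.
#' @param L full sequence length.
#' @return An object of class \code{"distogram"}: \code{probs}
#'   (L x L x 10, each cell summing to 1), \code{coverage} (L x L crop
#'   counts), and \code{aux} (list of per-residue class-probability
#'   matrices ss, phi, psi, asa).
#' @export
aggregate_crops <- function(crop_preds, L) {
  sums <- array(0, c(L, L, 10L))
  cnt <- matrix(0L, L, L)
  aux_sums <- list(ss = matrix(0, L, 9), phi = matrix(0, L, 37),
                   psi = matrix(0, L, 37), asa = matrix(0, L, 11))
  aux_cnt <- rep(0L, L)
  for (pred in crop_preds) {
    stopifnot(inherits(pred, "crop_prediction"))
    cs <- pred$size
    r <- pred$origin[1]; cc <- pred$origin[2]
    ri <- intersect(seq(r, r + cs - 1), 0:(L - 1))
    ci <- intersect(seq(cc, cc + cs - 1), 0:(L - 1))
    if (!length(ri) || !length(ci)) next
    sums[ri + 1, ci + 1, ] <- sums[ri + 1, ci + 1, , drop = FALSE] +
      pred$dist[ri - r + 1, ci - cc + 1, , drop = FALSE]
    cnt[ri + 1, ci + 1] <- cnt[ri + 1, ci + 1] + 1L
    for (nm in names(aux_sums)) {
      seg <- .AUX_SEGMENTS[[nm]]
      aux_sums[[nm]][ri + 1, ] <-
        aux_sums[[nm]][ri + 1, , drop = FALSE] +
        pred$aux_i[ri - r + 1, seg, drop = FALSE]
      aux_sums[[nm]][ci + 1, ] <-
        aux_sums[[nm]][ci + 1, , drop = FALSE] +
        pred$aux_j[ci - cc + 1, seg, drop = FALSE]
    }
    aux_cnt[ri + 1] <- aux_cnt[ri + 1] + 1L
    aux_cnt[ci + 1] <- aux_cnt[ci + 1] + 1L
  }
  if (any(cnt == 0)) {
    miss <- which(cnt == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("cell (%d, %d) not covered by any crop (0-based)",
                 miss[1] - 1L, miss[2] - 1L))
  }
  probs <- sums / as.vector(cnt)
  probs <- (probs + aperm(probs, c(2, 1, 3))) / 2
  aux <- lapply(aux_sums, function(a) a / aux_cnt)
  structure(list(probs = probs, coverage = cnt, aux = aux, L = L),
            class = "distogram")
}

#' @export
print.distogram <- function(x, ...) {
  cat(sprintf(
    "distogram: %d x %d x 10 (crop coverage %d-%d per cell)\n",
    x$L, x$L, min(x$coverage), max(x$coverage)))
  invisible(x)
}

#' Ensemble several distograms
#'
#' Per-cell arithmetic mean of the class distributions, renormalized
#' (averaging normalized vectors already lies on the simplex, so the
#' renormalization is a numerical no-op). Auxiliary tables are averaged the
#' same way.
#'
#' @param distograms list of \code{"distogram"} objects on the same L.
#' @return A \code{"distogram"}.
#' @export
ensemble_distograms <- function(distograms) {
  stopifnot(length(distograms) >= 1)
  L <- distograms[[1]]$L
  for (d in distograms) {
    if (d$L != L) stop(sprintf("length mismatch in ensemble: %d vs %d",
                               d$L, L))
  }
  probs <- Reduce(`+`, lapply(distograms, `[[`, "probs")) / length(distograms)
  norm <- apply(probs, c(1, 2), sum)
  probs <- probs / as.vector(norm)
  aux <- distograms[[1]]$aux
  if (!is.null(aux)) {
    for (nm in names(aux)) {
      aux[[nm]] <- Reduce(`+`, lapply(distograms, function(d) d$aux[[nm]])) /
        length(distograms)
      aux[[nm]] <- aux[[nm]] / rowSums(aux[[nm]])
    }
  }
  cov <- Reduce(`+`, lapply(distograms, `[[`, "coverage"))
  structure(list(probs = probs, coverage = cov, aux = aux, L = L),
            class = "distogram")
}

#' Contact probability map from a distogram
#'
#' Sums the first three distance classes, whose bins cover all distances
#' below the 8 Angstrom contact threshold.
#'
#' @param dg a \code{"distogram"}.
#' @return L x L matrix of contact probabilities in [0, 1].
#' @export
contact_probability <- function(dg) {
  stopifnot(inherits(dg, "distogram"))
  dg$probs[, , 1] + dg$probs[, , 2] + dg$probs[, , 3]
}

#' Full-length prediction with crop tiling and optional ensembling
#'
#' Tiles the L x L input with \code{\link{coverage_crops}}, runs the forward
#' pass on every crop of every model (softmax per crop, probability-space
#' averaging), aggregates per model, and ensembles across models.
#'
#' @param models a \code{"distnet"} or list of them (e.g. the three
#'   published training runs A/B/C).
#' @param features a \code{\link{pairwise_input}}.
#' @param n_offsets overlapping offset grids (1 = fast, 10 = the published
#'   high-accuracy setting).
#' @param seed optional seed for random instead of evenly spaced offsets.
#' @return A \code{"distogram"}.
#' @export
predict_distogram <- function(models, features, n_offsets = 1, seed = NULL) {
  stopifnot(inherits(features, "pairwise_input"))
  if (inherits(models, "distnet")) models <- list(models)
  L <- features$L
  per_model <- lapply(models, function(m) {
    crops <- coverage_crops(L, m$cfg$crop_size, n_offsets, seed)
    preds <- lapply(crops, function(cr)
      forward(m, crop_features(features, cr), origin = cr$origin))
    aggregate_crops(preds, L)
  })
  if (length(per_model) == 1) per_model[[1]] else
    ensemble_distograms(per_model)
}
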