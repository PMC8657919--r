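#' Save feature/label/prediction tensors
#'
#' Single-file container with three named groups — \code{features} (a
#' \code{pairwise_input}), \code{labels} (a \code{label_set}) and
#' \code{predictions} (a \code{distogram}) — any of which may be absent.
#' Stored as RDS; writing the same objects twice produces byte-identical
#' files.
#'
#' @param path output file path.
#' @param features,labels,predictions optional components.
#' @return \code{path}, invisibly.
#' @export
save_tensors <- function(path, features = NULL, labels = NULL,
                         predictions = NULL) {
  saveRDS(list(features = features, labels = labels,
               predictions = predictions, format_version = 1L), path)
  invisible(path)
}

#' Load a tensor container written by \code{\link{save_tensors}}
#'
#' @param path file path.
#' @return list with \code{features}, \code{labels}, \code{predictions}.
#' @export
load_tensors <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  if (is.null(obj$format_version)) stop("not a tensor container: ", path)
  obj
}

#' Save a model checkpoint (configuration embedded)
#'
#' @param model a \code{"distnet"}, or a \code{"distnet_fit"} (its
#'   best-validation checkpoint parameters are substituted into the model).
#' @param path output path.
#' @param seed training seed to record, if any.
#' @return \code{path}, invisibly.
#' @export
save_checkpoint <- function(model, path, seed = NULL) {
  if (inherits(model, "distnet_fit")) {
    fit <- model
    model <- fit$model
    if (length(fit$checkpoints)) {
      model$params <- fit$checkpoints[[1]]$params
      model$state <- fit$checkpoints[[1]]$state
    }
    if (is.null(seed)) seed <- fit$seed
  }
  stopifnot(inherits(model, "distnet"))
  saveRDS(list(cfg = model$cfg, params = model$params, state = model$state,
               seed = seed, format_version = 1L), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint path.
#' @return A \code{"distnet"}.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  if (is.null(obj$cfg)) stop("not a checkpoint: ", path)
  structure(list(cfg = obj$cfg, params = obj$params, state = obj$state,
                 plan = .block_plan(obj$cfg)),
            class = "distnet")
}

#' Export a contact map as CASP RR-style text
#'
#' One line per pair: \code{i j 0 8 probability}, ranked by probability.
#'
#' @param P L x L contact probability matrix.
#' @param path output path.
#' @param top how many pairs to write (default: all with separation >= 6).
#' @return \code{path}, invisibly.
#' @export
write_rr <- function(P, path, top = Inf) {
  ut <- which(upper.tri(P), arr.ind = TRUE)
  keep <- range_of(ut[, 1], ut[, 2]) != "none"
  pairs <- ut[keep, , drop = FALSE]
  prob <- P[pairs]
  ord <- order(-prob, pairs[, 1], pairs[, 2])
  n <- min(top, length(ord))
  lines <- sprintf("%d %d 0 8 %.6f", pairs[ord[1:n], 1],
                   pairs[ord[1:n], 2], prob[ord[1:n]])
  writeLines(c("PFRMAT RR", lines, "END"), path)
  invisible(path)
}
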