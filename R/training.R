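#' Default loss weights
#'
#' Component weights of the multicomponent cross-entropy: 15 for distances,
#' 0.5 secondary structure, 0.25 phi, 0.25 psi, 0.5 ASA.
#' @export
LOSS_WEIGHTS <- c(dist = 15, ss = 0.5, phi = 0.25, psi = 0.25, asa = 0.5)

#' Non-overlapping crop grid over an L x L map
#'
#' The grid is anchored at (-dr, -dc) and steps by the crop size, so the
#' union of crops covers every cell of [0, L)^2 exactly once; crops
#' extending past the sequence are zero-padded (features) / ignore-labeled.
#'
#' @param L sequence length.
#' @param c crop size (> 0).
#' @param offset integer (dr, dc), each in [0, c).
#' @param seed when given, the offset is drawn uniformly instead.
#' @return list of crop specs: \code{origin} (0-based, possibly negative),
#'   \code{size}.
#' @export
crop_grid <- function(L, c, offset = c(0L, 0L), seed = NULL) {
  if (c <= 0) stop("crop size must be positive")
  if (!is.null(seed)) {
    offset <- .with_seed(seed, sample.int(c, 2, replace = TRUE) - 1L)
  }
  stopifnot(all(offset >= 0), all(offset < c))
  r0 <- seq(-offset[1], L - 1, by = c)
  c0 <- seq(-offset[2], L - 1, by = c)
  crops <- list()
  for (r in r0) for (cc in c0) {
    crops[[length(crops) + 1L]] <- list(origin = c(r, cc), size = c)
  }
  crops
}

#' Inference crop set with overlapping offset grids
#'
#' Offset 1 is the (0, 0) base grid; further offsets are distinct diagonal
#' shifts (deterministic, evenly spaced over the crop size) or random when a
#' seed is supplied, covering the boundaries between base-grid crops. Every
#' grid covers all of [0, L)^2, so with n offsets every cell is covered at
#' least n times.
#'
#' @param L sequence length.
#' @param c crop size.
#' @param n_offsets number of overlapping grids (>= 1); the published
#'   high-accuracy setting uses 10.
#' @param seed optional seed for random (instead of evenly spaced) shifts.
#' @return list of crop specs as in \code{\link{crop_grid}}.
#' @export
coverage_crops <- function(L, c, n_offsets = 1, seed = NULL) {
  stopifnot(n_offsets >= 1)
  shifts <- if (n_offsets == 1) 0L else if (is.null(seed)) {
    unique(c(0L, as.integer(floor((seq_len(n_offsets - 1)) * c / n_offsets))))
  } else {
    c(0L, .with_seed(seed, sample.int(c - 1L, min(n_offsets - 1L, c - 1L))))
  }
  out <- list()
  for (s in shifts) out <- c(out, crop_grid(L, c, offset = c(s, s)))
  out
}

#' Subsample alignment rows for training-time augmentation
#'
#' The query row is always retained; of the remaining rows,
#' \code{round(fraction * (depth - 1))} are sampled without replacement.
#'
#' @param aln an \code{\link{msa}}.
#' @param fraction fraction in (0, 1]; the published training recipe uses
#'   0.5 per domain per epoch.
#' @param seed RNG seed.
#' @return An \code{\link{msa}}.
#' @export
subsample_msa <- function(aln, fraction = 0.5, seed = 1) {
  stopifnot(inherits(aln, "msa"), fraction > 0, fraction <= 1)
  if (aln$depth == 1) return(aln)
  keep <- .with_seed(seed, {
    k <- round(fraction * (aln$depth - 1))
    if (k == 0) integer(0) else sort(sample(2:aln$depth, k))
  })
  msa(aln$sequences[c(1L, keep)], aln$ids[c(1L, keep)])
}

#' Learning-rate schedule
#'
#' The three published schedules share an initial Adam learning rate of
#' 0.001 and decay to 0.0005 and then 0.0001 at model-specific epochs:
#' A at epochs 5/15, B at 10/25, C at 8/20.
#'
#' @param model_id "A", "B" or "C", or a custom list with \code{initial}
#'   and \code{decay} (named numeric: epoch -> LR).
#' @return list of class \code{"lr_schedule"}.
#' @export
lr_schedule <- function(model_id = "A") {
  decays <- list(A = c("5" = 5e-4, "15" = 1e-4),
                 B = c("10" = 5e-4, "25" = 1e-4),
                 C = c("8" = 5e-4, "20" = 1e-4))
  if (is.character(model_id)) {
    if (!model_id %in% names(decays)) stop("unknown schedule: ", model_id)
    sch <- list(model_id = model_id, initial = 1e-3,
                decay = decays[[model_id]])
  } else sch <- model_id
  structure(sch, class = "lr_schedule")
}

#' Learning rate at a given epoch
#'
#' Piecewise constant: each decay applies from its stated epoch onward.
#'
#' @param epoch epoch number (>= 0).
#' @param s an \code{\link{lr_schedule}}.
#' @return learning rate.
#' @export
lr_at <- function(epoch, s = lr_schedule("A")) {
  stopifnot(epoch >= 0)
  lr <- s$initial
  at <- as.numeric(names(s$decay))
  for (k in seq_along(at)) if (epoch >= at[k]) lr <- s$decay[[k]]
  lr
}

# --- crop extraction -------------------------------------------------------

#' Extract a zero-padded feature crop
#'
#' Cells outside the sequence get zero features, including a zero validity
#' mask channel.
#'
#' @param x a \code{\link{pairwise_input}}.
#' @param crop a crop spec from \code{\link{crop_grid}}.
#' @return crop_size x crop_size x channels array.
#' @export
crop_features <- function(x, crop) {
  stopifnot(inherits(x, "pairwise_input"))
  cs <- crop$size; L <- x$L
  out <- array(0, c(cs, cs, dim(x$tensor)[3]))
  r <- crop$origin[1]; cc <- crop$origin[2]
  ri <- intersect(seq(r, r + cs - 1), 0:(L - 1))
  ci <- intersect(seq(cc, cc + cs - 1), 0:(L - 1))
  if (length(ri) && length(ci)) {
    out[ri - r + 1, ci - cc + 1, ] <- x$tensor[ri + 1, ci + 1, ]
  }
  out
}

#' Extract crop-aligned labels
#'
#' Positions outside the sequence (padding) carry NA and are excluded from
#' every loss component.
#'
#' @param labels a \code{\link{make_labels}} result.
#' @param crop a crop spec.
#' @return list: \code{dist} (c x c integer/NA), per-residue vectors
#'   \code{ss_i}, \code{phi_i}, \code{psi_i}, \code{asa_i} for the crop rows
#'   and \code{*_j} for the crop columns.
#' @export
crop_labels <- function(labels, crop) {
  stopifnot(inherits(labels, "label_set"))
  cs <- crop$size; L <- labels$length
  r <- crop$origin[1]; cc <- crop$origin[2]
  dist <- matrix(NA_integer_, cs, cs)
  ri <- intersect(seq(r, r + cs - 1), 0:(L - 1))
  ci <- intersect(seq(cc, cc + cs - 1), 0:(L - 1))
  if (length(ri) && length(ci)) {
    dist[ri - r + 1, ci - cc + 1] <- labels$dist_bins[ri + 1, ci + 1]
  }
  vec <- function(v, o) {
    out <- rep(NA_integer_, cs)
    ii <- intersect(seq(o, o + cs - 1), 0:(L - 1))
    out[ii - o + 1] <- v[ii + 1]
    out
  }
  list(dist = dist,
       ss_i = vec(labels$ss, r), phi_i = vec(labels$phi, r),
       psi_i = vec(labels$psi, r), asa_i = vec(labels$asa, r),
       ss_j = vec(labels$ss, cc), phi_j = vec(labels$phi, cc),
       psi_j = vec(labels$psi, cc), asa_j = vec(labels$asa, cc))
}

# mean cross-entropy of probability rows P against 0-based integer labels y
# (NA = ignore); returns loss and d(logits) already divided by valid count
.ce_component <- function(P, y, weight) {
  ok <- !is.na(y)
  n <- sum(ok)
  dZ <- matrix(0, nrow(P), ncol(P))
  if (n == 0) return(list(loss = 0, dZ = dZ))
  idx <- cbind(which(ok), y[ok] + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  Y <- matrix(0, nrow(P), ncol(P))
  Y[idx] <- 1
  dZ[ok, ] <- (P[ok, , drop = FALSE] - Y[ok, , drop = FALSE]) * (weight / n)
  list(loss = loss, dZ = dZ)
}

#' Weighted multicomponent cross-entropy loss
#'
#' loss = 15 CE(dist) + 0.5 CE(ss) + 0.25 CE(phi) + 0.25 CE(psi)
#' + 0.5 CE(asa); each CE is a mean over non-ignored positions (a component
#' with no valid positions contributes 0). Per-residue components average
#' the contributions of the row-axis and column-axis auxiliary heads.
#'
#' @param pred a \code{"crop_prediction"}.
#' @param labels a \code{\link{crop_labels}} result.
#' @param w named loss weights (default \code{\link{LOSS_WEIGHTS}}).
#' @param with_grad also return head logit gradients for
#'   \code{\link{backward}}.
#' @return scalar loss, or (with \code{with_grad}) a list with \code{loss},
#'   \code{components}, \code{d_dist}, \code{d_auxi}, \code{d_auxj}.
#' @export
multicomponent_loss <- function(pred, labels, w = LOSS_WEIGHTS,
                                with_grad = FALSE) {
  stopifnot(inherits(pred, "crop_prediction"), all(w >= 0))
  cs <- pred$size
  P <- matrix(pred$dist, cs * cs, 10L)
  dist <- .ce_component(P, as.vector(labels$dist), w[["dist"]])
  comp <- c(dist = dist$loss)
  d_auxi <- matrix(0, cs, 94L)
  d_auxj <- matrix(0, cs, 94L)
  for (nm in c("ss", "phi", "psi", "asa")) {
    seg <- .AUX_SEGMENTS[[nm]]
    ci <- .ce_component(pred$aux_i[, seg, drop = FALSE],
                        labels[[paste0(nm, "_i")]], w[[nm]] / 2)
    cj <- .ce_component(pred$aux_j[, seg, drop = FALSE],
                        labels[[paste0(nm, "_j")]], w[[nm]] / 2)
    comp[nm] <- (ci$loss + cj$loss) / 2
    d_auxi[, seg] <- ci$dZ
    d_auxj[, seg] <- cj$dZ
  }
  loss <- sum(w[names(comp)] * comp)
  if (!with_grad) return(loss)
  list(loss = loss, components = comp,
       d_dist = dist$dZ, d_auxi = d_auxi, d_auxj = d_auxj)
}

# --- optimizer -------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# --- training loop ---------------------------------------------------------

.domain_features <- function(domain, epoch_seed, subsample_fraction) {
  if (!is.null(domain$aln)) {
    aln <- if (subsample_fraction < 1) {
      subsample_msa(domain$aln, subsample_fraction, seed = epoch_seed)
    } else domain$aln
    prof <- if (!is.null(domain$hhm)) domain$hhm else profile_from_msa(aln)
    assemble_input(aln, prof, compute_dca(aln))
  } else domain$features
}

#' Train a model on labeled domains
#'
#' Per epoch: a fresh random crop grid per domain, a fresh 50 percent MSA
#' subsample per domain (features recomputed online when the domain carries
#' its alignment; precomputed features are reused as-is), Adam updates every
#' \code{batch_size} crops under the given learning-rate schedule, and a
#' validation pass on static offset-(0,0) grids. The three checkpoints with
#' the lowest validation loss (training loss when no validation set is
#' given) are retained, sorted ascending.
#'
#' @param model a \code{"distnet"} from \code{\link{build_model}}.
#' @param dataset list of domains; each a list with either \code{features}
#'   (a \code{\link{pairwise_input}}) or \code{aln} (an \code{\link{msa}},
#'   plus optional \code{hhm}), and \code{labels} (a \code{label_set}).
#' @param epochs number of epochs.
#' @param batch_size crops per optimizer step (published setting: 8).
#' @param schedule an \code{\link{lr_schedule}}.
#' @param seed master seed; all per-epoch randomness derives from it.
#' @param subsample_fraction MSA subsample fraction per epoch (default 0.5).
#' @param validation optional held-out domain list for early-stopping
#'   selection.
#' @param max_steps optional cap on total optimizer steps.
#' @return list of class \code{"distnet_fit"}: final \code{model},
#'   \code{checkpoints} (up to 3, ascending validation loss), and \code{log}
#'   (data.frame of per-step training loss and per-epoch validation loss).
#' @export
train_model <- function(model, dataset, epochs = 1, batch_size = 8,
                        schedule = lr_schedule("A"), seed = 1,
                        subsample_fraction = 0.5, validation = NULL,
                        max_steps = Inf) {
  stopifnot(inherits(model, "distnet"), length(dataset) >= 1)
  cs <- model$cfg$crop_size
  opt <- .adam_init(model$params)
  log <- data.frame(epoch = integer(0), step = integer(0),
                    loss = numeric(0))
  val_log <- data.frame(epoch = integer(0), val_loss = numeric(0))
  checkpoints <- list()
  step <- 0L

  eval_loss <- function(domains) {
    tot <- 0; nc <- 0L
    for (dom in domains) {
      feats <- if (!is.null(dom$features)) dom$features else
        .domain_features(dom, 0L, 1)
      for (cr in crop_grid(feats$L, cs)) {
        pred <- forward(model, crop_features(feats, cr))
        tot <- tot + multicomponent_loss(pred, crop_labels(dom$labels, cr))
        nc <- nc + 1L
      }
    }
    tot / nc
  }

  .with_seed((seed * 2654435761) %% .Machine$integer.max, {
  for (ep in seq_len(epochs)) {
    if (step >= max_steps) break
    ep_seed <- (seed * 1000003L + ep) %% .Machine$integer.max
    batch_grads <- NULL; batch_n <- 0L; batch_loss <- 0
    dom_i <- 0L
    for (dom in dataset) {
      dom_i <- dom_i + 1L
      feats <- .domain_features(dom, ep_seed + dom_i, subsample_fraction)
      crops <- crop_grid(feats$L, cs, seed = ep_seed * 31L + dom_i)
      for (cr in crops) {
        if (step >= max_steps) break
        x <- crop_features(feats, cr)
        fw <- forward(model, x, training = TRUE, origin = cr$origin)
        model <- fw$model
        lg <- multicomponent_loss(fw$pred, crop_labels(dom$labels, cr),
                                  with_grad = TRUE)
        if (!is.finite(lg$loss)) {
          stop(sprintf(
            "non-finite loss at epoch %d step %d (domain %d crop %d,%d)",
            ep, step + 1L, dom_i, cr$origin[1], cr$origin[2]))
        }
        gr <- backward(model, fw$cache, lg$d_dist, lg$d_auxi, lg$d_auxj)
        gr$dX <- NULL
        batch_grads <- if (is.null(batch_grads)) gr else
          mapply(`+`, batch_grads, gr, SIMPLIFY = FALSE)
        batch_n <- batch_n + 1L; batch_loss <- batch_loss + lg$loss
        if (batch_n == batch_size) {
          step <- step + 1L
          sg <- lapply(batch_grads, function(g) g / batch_n)
          upd <- .adam_step(model$params, sg, opt, lr_at(ep - 1, schedule))
          model$params <- upd$params; opt <- upd$opt
          log <- rbind(log, data.frame(epoch = ep, step = step,
                                       loss = batch_loss / batch_n))
          batch_grads <- NULL; batch_n <- 0L; batch_loss <- 0
        }
      }
    }
    if (batch_n > 0) {  # flush the trailing partial batch
      step <- step + 1L
      sg <- lapply(batch_grads, function(g) g / batch_n)
      upd <- .adam_step(model$params, sg, opt, lr_at(ep - 1, schedule))
      model$params <- upd$params; opt <- upd$opt
      log <- rbind(log, data.frame(epoch = ep, step = step,
                                   loss = batch_loss / batch_n))
    }
    vl <- eval_loss(if (!is.null(validation)) validation else dataset)
    val_log <- rbind(val_log, data.frame(epoch = ep, val_loss = vl))
    checkpoints[[length(checkpoints) + 1L]] <-
      list(params = model$params, state = model$state,
           val_loss = vl, epoch = ep)
    checkpoints <- checkpoints[order(vapply(checkpoints,
                                            `[[`, 0, "val_loss"))]
    if (length(checkpoints) > 3) checkpoints <- checkpoints[1:3]
  }
  })
  structure(list(model = model, checkpoints = checkpoints,
                 log = log, val_log = val_log, schedule = schedule,
                 seed = seed),
            class = "distnet_fit")
}

#' @export
print.distnet_fit <- function(x, ...) {
  cat(sprintf(
    "distnet_fit: %d steps, final training loss %.4f, best val loss %.4f\n",
    nrow(x$log), x$log$loss[nrow(x$log)],
    if (length(x$checkpoints)) x$checkpoints[[1]]$val_loss else NA))
  invisible(x)
}
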