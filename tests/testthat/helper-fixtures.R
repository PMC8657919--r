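# shared tiny objects, built once per test run

tiny_cfg <- function(in_channels = 7, crop = 6, dropout = 0) {
  distnet_config(in_channels = in_channels, n_blocks = 4, wide_blocks = 2,
                 wide_channels = 8, narrow_channels = 4, crop_size = crop,
                 dropout = dropout)
}

# a normalized random crop prediction for aggregation tests
random_crop_prediction <- function(origin, cs = 8) {
  d <- array(stats::runif(cs * cs * 10), c(cs, cs, 10))
  d <- d / as.vector(apply(d, c(1, 2), sum))
  segs <- list(ss = 1:9, phi = 10:46, psi = 47:83, asa = 84:94)
  norm_aux <- function() {
    a <- matrix(stats::runif(cs * 94), cs, 94)
    for (seg in segs) a[, seg] <- a[, seg] / rowSums(a[, seg, drop = FALSE])
    a
  }
  structure(list(dist = d, aux_i = norm_aux(), aux_j = norm_aux(),
                 origin = as.integer(origin), size = cs),
            class = "crop_prediction")
}

# crop-shaped random labels with some ignored positions
random_crop_labels <- function(cs, seed = 4) {
  set.seed(seed)
  list(dist = matrix(sample(c(0:9, NA), cs * cs, TRUE), cs, cs),
       ss_i = sample(c(0:8, NA), cs, TRUE), phi_i = sample(0:36, cs, TRUE),
       psi_i = sample(0:36, cs, TRUE), asa_i = sample(0:10, cs, TRUE),
       ss_j = sample(0:8, cs, TRUE), phi_j = sample(0:36, cs, TRUE),
       psi_j = sample(0:36, cs, TRUE), asa_j = sample(c(0:10, NA), cs, TRUE))
}
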