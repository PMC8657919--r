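# run expr under a fixed RNG seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ideal backbone stereochemistry, frozen in one place
.GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  helix_phi = -57, helix_psi = -47, omega = 180
)

# NeRF atom placement: D bonded to C with bond length `bond`, bond angle
# B-C-D `angle` (deg) and torsion A-B-C-D `torsion` (deg)
.nerf <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# C-beta from backbone N, CA, C (tetrahedral construction)
.place_cb <- function(n, ca, c) {
  b <- ca - n; cc <- c - ca
  a <- .cross3(b, cc)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

#' Ideal poly-alanine alpha helix
#'
#' Builds a backbone from fixed ideal internal coordinates
#' (phi = -57, psi = -47, omega = 180 degrees; standard bond lengths and
#' angles) with C-beta placed by tetrahedral geometry and carbonyl O in the
#' peptide plane. Serves as a geometry oracle: recomputing phi/psi from the
#' coordinates returns the constants the helix was built from.
#'
#' @param n number of residues (>= 4).
#' @param phi,psi backbone torsions in degrees (defaults: ideal alpha helix).
#' @return A \code{\link{structure_chain}} of n alanines.
#' @export
ideal_helix <- function(n, phi = .GEOM$helix_phi, psi = .GEOM$helix_psi) {
  stopifnot(n >= 4)
  g <- .GEOM
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ]  <- .nerf(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n, psi)
    CA[i + 1, ] <- .nerf(CA[i, ], C[i, ], N[i + 1, ],
                         g$b_n_ca, g$a_c_n_ca, g$omega)
    C[i + 1, ]  <- .nerf(C[i, ], N[i + 1, ], CA[i + 1, ],
                         g$b_ca_c, g$a_n_ca_c, phi)
  }
  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    O <- if (i < n) {
      .nerf(N[i + 1, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, 180)
    } else {
      .nerf(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, psi + 180)
    }
    CB <- .place_cb(N[i, ], CA[i, ], C[i, ])
    m <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O, CB = CB)
    atoms[[i]] <- m
  }
  structure_chain(rep("ALA", n), atoms, chain_id = "A")
}

#' Specification for a Potts-model alignment with planted couplings
#'
#' @param L sequence length.
#' @param n_seq number of sequences to sample.
#' @param n_pairs number of planted coupled column pairs (each with
#'   sequence separation >= 5).
#' @param beta coupling strength (dimensionless energy favoring matching
#'   states at a planted pair).
#' @param field_sd standard deviation of the random single-site fields.
#' @param seed RNG seed; the sample is a pure function of the spec.
#' @param planted_pairs optional 2-column matrix of pairs overriding the
#'   random draw.
#' @return list of class \code{"potts_spec"}.
#' @export
potts_spec <- function(L = 40, n_seq = 2000, n_pairs = 8, beta = 2.5,
                       field_sd = 0.5, seed = 1, planted_pairs = NULL) {
  if (is.null(planted_pairs)) {
    planted_pairs <- .with_seed(seed * 7919 + 13, {
      pairs <- matrix(NA_integer_, 0, 2)
      while (nrow(pairs) < n_pairs) {
        i <- sample.int(L - 5, 1)
        cand <- (i + 5):L
        j <- cand[sample.int(length(cand), 1)]
        if (!any(pairs[, 1] == i & pairs[, 2] == j)) {
          pairs <- rbind(pairs, c(i, j))
        }
      }
      pairs
    })
  }
  stopifnot(all(abs(planted_pairs[, 1] - planted_pairs[, 2]) >= 5),
            beta >= 0)
  structure(list(L = L, n_seq = n_seq, beta = beta, field_sd = field_sd,
                 seed = seed, planted_pairs = planted_pairs),
            class = "potts_spec")
}

#' Sample an alignment from a pairwise Potts model with planted couplings
#'
#' Gibbs sampling over 20 amino-acid states: each of \code{n_seq}
#' independent chains runs \code{burnin} full sweeps (default 50) of
#' site-wise conditional resampling under random single-site fields plus
#' couplings of strength \code{beta} that favor matching states at the
#' planted pairs only. The planted pairs are the recovery oracle for
#' direct-coupling analysis.
#'
#' @param spec a \code{\link{potts_spec}}.
#' @param burnin Gibbs sweeps before the state is taken as the sample.
#' @return An \code{\link{msa}} of depth \code{n_seq}.
#' @export
potts_sample <- function(spec, burnin = 50) {
  stopifnot(inherits(spec, "potts_spec"))
  L <- spec$L; n <- spec$n_seq
  .with_seed(spec$seed, {
    h <- matrix(stats::rnorm(L * 20, sd = spec$field_sd), L, 20)
    partners <- vector("list", L)
    for (k in seq_len(nrow(spec$planted_pairs))) {
      i <- spec$planted_pairs[k, 1]; j <- spec$planted_pairs[k, 2]
      partners[[i]] <- c(partners[[i]], j)
      partners[[j]] <- c(partners[[j]], i)
    }
    X <- matrix(sample.int(20, n * L, replace = TRUE), n, L)
    for (sweep in seq_len(burnin)) {
      for (s in seq_len(L)) {
        logits <- matrix(h[s, ], n, 20, byrow = TRUE)
        for (p in partners[[s]]) {
          logits[cbind(seq_len(n), X[, p])] <-
            logits[cbind(seq_len(n), X[, p])] + spec$beta
        }
        gumbel <- -log(-log(matrix(stats::runif(n * 20), n, 20)))
        X[, s] <- max.col(logits + gumbel, ties.method = "first")
      }
    }
    seqs <- apply(X, 1, function(r) paste(AA_ALPHABET[r], collapse = ""))
    msa(seqs, paste0("potts", seq_len(n)))
  })
}

#' Compact lattice-snake chain
#'
#' Residues laid out along a boustrophedon path through a cubic lattice, so
#' the chain is compact and has true contacts at short, mid and long
#' sequence separations — unlike a single straight helix. C-alpha sits on
#' the lattice point and C-beta is displaced by 0.5 Angstroms; N/C/O are
#' placed nearby only so the residues count as resolved.
#'
#' @param n number of residues.
#' @param spacing lattice spacing in Angstroms (default 5.5, putting lattice
#'   neighbors and face diagonals inside the 8 Angstrom contact threshold).
#' @return A \code{\link{structure_chain}}.
#' @export
lattice_chain <- function(n, spacing = 5.5) {
  side <- ceiling(n^(1 / 3))
  atoms <- vector("list", n)
  k <- 0L
  for (z in seq_len(side)) for (yy in seq_len(side)) for (xx in seq_len(side)) {
    if (k >= n) break
    k <- k + 1L
    # snake: reverse x on odd y rows, reverse y on odd z layers
    y2 <- if (z %% 2 == 0) side + 1 - yy else yy
    x2 <- if (y2 %% 2 == 0) side + 1 - xx else xx
    ca <- spacing * c(x2, y2, z)
    atoms[[k]] <- rbind(N = ca + c(-0.7, 0.5, 0), CA = ca,
                        C = ca + c(0.7, 0.5, 0), O = ca + c(0.9, 1.4, 0),
                        CB = ca + c(0, 0, 0.5))
  }
  structure_chain(rep("ALA", n), atoms, chain_id = "A")
}

#' Random mutated-copies alignment
#'
#' A random query plus rows that are query copies with i.i.d. substitutions
#' (uniform over the 20 amino acids, so a "mutation" can silently restore
#' the original letter) and occasional gaps.
#'
#' @param L query length.
#' @param n_seq alignment depth (row 1 is the unmutated query).
#' @param mutation_rate per-site substitution probability in [0, 1].
#' @param seed RNG seed.
#' @param gap_rate per-site gap probability for non-query rows.
#' @return An \code{\link{msa}}.
#' @export
random_msa <- function(L, n_seq, mutation_rate = 0.3, seed = 1,
                       gap_rate = 0.02) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1, n_seq >= 1)
  .with_seed(seed, {
    q <- sample.int(20, L, replace = TRUE)
    rows <- matrix(rep(q, each = n_seq), n_seq, L)
    if (n_seq > 1) {
      for (r in 2:n_seq) {
        mut <- stats::runif(L) < mutation_rate
        rows[r, mut] <- sample.int(20, sum(mut), replace = TRUE)
        gap <- stats::runif(L) < gap_rate
        rows[r, gap] <- 21L
      }
    }
    seqs <- apply(rows, 1, function(x) paste(AA_ALPHABET[x], collapse = ""))
    msa(seqs, c("query", if (n_seq > 1) paste0("hom", 2:n_seq)))
  })
}
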