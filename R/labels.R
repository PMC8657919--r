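#' Distance bin edges (Angstroms)
#'
#' 10 classes: < 4, then 2-Angstrom bins up to the final class holding all
#' distances >= 20.
#' @export
DIST_BIN_EDGES <- c(4, 6, 8, 10, 12, 14, 16, 18, 20)

#' Secondary-structure letter-to-class table
#'
#' The 8 DSSP codes plus blank (coil) give classes 0..7; class 8 is reserved
#' for gap/error.
#' @export
SS_CLASSES <- c(H = 0L, G = 1L, I = 2L, E = 3L, B = 4L,
                T = 5L, S = 6L, C = 7L)

#' Bin an inter-residue distance into one of 10 classes
#'
#' @param d distance(s) in Angstroms, >= 0.
#' @return integer class(es) in 0..9 (left-closed bins; >= 20 -> 9).
#' @export
bin_distance <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("negative distance")
  out <- findInterval(d, DIST_BIN_EDGES)
  out[is.na(d)] <- NA_integer_
  as.integer(out)
}

#' Bin a torsion angle into one of 37 classes
#'
#' 36 ten-degree bins spanning [-180, 180), plus class 36 for an undefined
#' (gap/error) angle.
#'
#' @param a angle(s) in degrees, or NA for undefined.
#' @return integer class(es) in 0..36.
#' @export
bin_angle <- function(a) {
  out <- pmin(floor((a + 180) / 10), 35)
  out[is.na(a)] <- 36
  as.integer(out)
}

#' Bin a relative accessible surface area into one of 11 classes
#'
#' 10 equal bins over [0, 1], plus class 10 for N/A or a gap.
#'
#' @param r fraction(s) in [0, 1], or NA.
#' @return integer class(es) in 0..10.
#' @export
bin_asa <- function(r) {
  out <- pmin(floor(10 * r), 9)
  out[is.na(r)] <- 10
  as.integer(out)
}

#' Representative C-beta coordinate of a residue
#'
#' Returns the CB coordinate; CA for glycine; CA with a warning for a
#' non-glycine residue lacking CB. \code{NULL} when CA is also absent (the
#' residue is then masked out of the labels).
#'
#' @param atoms residue atom matrix (rows named N/CA/C/O/CB) or \code{NULL}.
#' @param resid 3-letter residue name.
#' @return numeric length-3 vector or \code{NULL}.
#' @export
cb_coordinate <- function(atoms, resid = "ALA") {
  if (is.null(atoms) || !"CA" %in% rownames(atoms)) return(NULL)
  if (resid == "GLY") return(atoms["CA", ])
  if ("CB" %in% rownames(atoms)) return(atoms["CB", ])
  warning(sprintf("non-glycine residue %s lacks CB; using CA", resid))
  atoms["CA", ]
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' Standard atan2 construction, IUPAC sign convention (trans = +/-180,
#' mapped into [-180, 180) so trans reports as -180).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (Angstroms).
#' @return angle in degrees in [-180, 180), or NA for degenerate
#'   (collinear) input.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9 || nb2 < 1e-9)
    return(NA_real_)
  m1 <- .cross3(n1, b2 / nb2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang >= 180) ang <- ang - 360
  if (ang < -180) ang <- ang + 360
  if (ang == 180) ang <- -180
  ang
}

# van der Waals radii (Angstroms) by element, for ASA
.VDW_RADII <- c(N = 1.55, C = 1.70, O = 1.52, S = 1.80)

# Theoretical maximum ASA per residue (Tien et al. 2013), Angstroms^2
.MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# deterministic unit sphere points (golden-spiral / Fibonacci lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atom_element <- function(name) substr(name, 1, 1)

# flatten a chain's atoms into coordinate matrix + radii + residue index
.chain_atom_table <- function(chain) {
  xyz <- NULL; rad <- numeric(0); res <- integer(0)
  for (i in seq_len(chain$length)) {
    a <- chain$atoms[[i]]
    if (is.null(a)) next
    xyz <- rbind(xyz, a)
    rad <- c(rad, .VDW_RADII[.atom_element(rownames(a))])
    res <- c(res, rep(i, nrow(a)))
  }
  list(xyz = xyz, rad = rad, res = res)
}

#' Relative accessible surface area of one residue
#'
#' Shrake-Rupley accessible surface area (probe 1.4 Angstroms, fixed
#' deterministic 960-point sphere sampling, per-element van der Waals radii)
#' over the residue's atoms, divided by the residue's theoretical maximum
#' ASA and clamped to [0, 1].
#'
#' @param chain a \code{\link{structure_chain}}.
#' @param residue_index 1-based residue index.
#' @param probe probe radius in Angstroms.
#' @param n_points sphere sample points per atom.
#' @return fraction in [0, 1], or NA if the residue is absent.
#' @export
relative_asa <- function(chain, residue_index, probe = 1.4, n_points = 960) {
  tab <- .chain_atom_table(chain)
  if (is.null(tab$xyz) || !residue_index %in% tab$res) return(NA_real_)
  pts <- .sphere_points(n_points)
  idx <- which(tab$res == residue_index)
  area <- 0
  for (k in idx) {
    r <- tab$rad[k] + probe
    sph <- pts * r + rep(tab$xyz[k, ], each = n_points)
    free <- rep(TRUE, n_points)
    for (m in seq_along(tab$rad)) {
      if (m == k) next
      rm2 <- (tab$rad[m] + probe)^2
      d2 <- (sph[, 1] - tab$xyz[m, 1])^2 + (sph[, 2] - tab$xyz[m, 2])^2 +
            (sph[, 3] - tab$xyz[m, 3])^2
      free <- free & d2 > rm2
      if (!any(free)) break
    }
    area <- area + 4 * pi * r^2 * mean(free)
  }
  mx <- .MAX_ASA[chain$resid[residue_index]]
  if (is.na(mx)) mx <- mean(.MAX_ASA)
  min(area / mx, 1)
}

#' Secondary structure classes for a chain
#'
#' With a DSSP output file, parses its per-residue letter codes through the
#' exported \code{\link{SS_CLASSES}} table (blank -> coil class 7, gap/error
#' -> 8). Without one, applies an internal fallback implementing the
#' published hydrogen-bond rules: a backbone N-H...O=C electrostatic energy
#' below -0.5 kcal/mol defines an H-bond; helices come from consecutive
#' n-turns (alpha 4-turn -> H, 3-10 -> G, pi -> I), strands/bridges from
#' parallel or antiparallel bridge patterns (E/B), remaining turn residues T
#' and high-curvature residues S. Bit-exact DSSP edge cases are out of scope.
#'
#' @param chain a \code{\link{structure_chain}}.
#' @param dssp_file optional path to classic DSSP text output.
#' @return integer vector of classes 0..8, length \code{chain$length}.
#' @export
secondary_structure <- function(chain, dssp_file = NULL) {
  L <- chain$length
  if (!is.null(dssp_file)) {
    lines <- readLines(dssp_file, warn = FALSE)
    start <- grep("^  #  RESIDUE", lines)
    if (!length(start)) stop("not a DSSP file: ", dssp_file)
    body <- lines[(start[1] + 1L):length(lines)]
    body <- body[nzchar(body)]
    body <- body[substr(body, 14, 14) != "!"]
    if (length(body) != sum(chain$mask)) {
      stop(sprintf("DSSP file has %d residues, chain has %d resolved",
                   length(body), sum(chain$mask)))
    }
    letters8 <- substr(body, 17, 17)
    cls <- SS_CLASSES[letters8]
    cls[letters8 == " " | is.na(cls)] <- 7L
    out <- rep(8L, L)
    out[chain$mask] <- as.integer(cls)
    return(out)
  }
  .dssp_fallback(chain)
}

# hydrogen-bond energy (kcal/mol) between donor NH(i) and acceptor CO(j)
.dssp_fallback <- function(chain) {
  L <- chain$length
  get <- function(i, nm) {
    a <- chain$atoms[[i]]
    if (is.null(a) || !nm %in% rownames(a)) return(NULL)
    a[nm, ]
  }
  # amide H approximated opposite the preceding carbonyl (DSSP convention)
  Hpos <- vector("list", L)
  for (i in 2:L) {
    n <- get(i, "N"); cp <- get(i - 1, "C"); op <- get(i - 1, "O")
    if (is.null(n) || is.null(cp) || is.null(op)) next
    d <- cp - op; d <- d / sqrt(sum(d^2))
    Hpos[[i]] <- n + d
  }
  hbond <- matrix(FALSE, L, L)  # hbond[i, j]: N-H of i donates to C=O of j
  for (i in 2:L) {
    n <- get(i, "N"); h <- Hpos[[i]]
    if (is.null(n) || is.null(h)) next
    for (j in seq_len(L)) {
      if (abs(i - j) < 2) next
      cO <- get(j, "O"); cC <- get(j, "C")
      if (is.null(cO) || is.null(cC)) next
      dd <- function(a, b) sqrt(sum((a - b)^2))
      e <- 0.084 * 332 * (1 / dd(cO, n) + 1 / dd(cC, h) -
                          1 / dd(cO, h) - 1 / dd(cC, n))
      if (e < -0.5) hbond[i, j] <- TRUE
    }
  }
  turn <- function(k) vapply(seq_len(L), function(i) {
    i + k <= L && hbond[i + k, i]
  }, TRUE)
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  out <- rep(7L, L)
  mark <- function(flags, k, code) {
    for (i in seq_len(L - 1)) {
      if (flags[i] && i + 1 <= L && flags[i + 1]) {
        span <- (i + 1):min(i + k, L)
        out[span][out[span] == 7L] <<- code
      }
    }
  }
  mark(t4, 4, SS_CLASSES[["H"]])
  mark(t3, 3, SS_CLASSES[["G"]])
  mark(t5, 5, SS_CLASSES[["I"]])
  # bridges
  bridge <- rep(FALSE, L)
  for (i in 2:(L - 1)) for (j in 2:(L - 1)) {
    if (abs(i - j) < 3) next
    par <- (hbond[j, i - 1] && hbond[i + 1, j]) ||
           (hbond[i, j - 1] && hbond[j + 1, i])
    anti <- (hbond[i, j] && hbond[j, i]) ||
            (hbond[j + 1, i - 1] && hbond[i + 1, j - 1])
    if (par || anti) bridge[i] <- TRUE
  }
  for (i in which(bridge)) {
    if (out[i] != 7L) next
    ladder <- (i > 1 && bridge[i - 1]) || (i < L && bridge[i + 1])
    out[i] <- if (ladder) SS_CLASSES[["E"]] else SS_CLASSES[["B"]]
  }
  # turns, then bends
  for (i in seq_len(L)) {
    if (out[i] == 7L && ((i >= 4 && (t3[i - 3] || t4[min(i, L)])) ||
                         t3[i] || t4[i] || t5[i]))
      out[i] <- SS_CLASSES[["T"]]
  }
  for (i in 3:(L - 2)) {
    if (out[i] != 7L) next
    a <- get(i - 2, "CA"); b <- get(i, "CA"); cc <- get(i + 2, "CA")
    if (is.null(a) || is.null(b) || is.null(cc)) next
    u <- b - a; v <- cc - b
    ang <- acos(min(1, max(-1, sum(u * v) /
                             (sqrt(sum(u^2)) * sqrt(sum(v^2)))))) * 180 / pi
    if (ang > 70) out[i] <- SS_CLASSES[["S"]]
  }
  out[!chain$mask] <- 8L
  out
}

#' Derive the full label set from a structure chain
#'
#' Produces the training targets: the 10-class binned C-beta distance map
#' (NA where either residue is unresolved; excluded from the loss), 9-class
#' secondary structure, 37-class phi/psi torsion bins (class 36 = undefined:
#' chain termini, gaps), 11-class relative-ASA bins (class 10 = N/A), and
#' the residue presence mask.
#'
#' @param chain a \code{\link{structure_chain}}.
#' @param dssp_file optional DSSP output to use instead of the internal
#'   secondary-structure fallback.
#' @param compute_asa set FALSE to skip the (relatively slow) ASA step and
#'   label every residue's ASA as N/A.
#' @return An object of class \code{"label_set"}: list with \code{dist_bins}
#'   (L x L), \code{ss}, \code{phi}, \code{psi}, \code{asa}, \code{mask},
#'   \code{length}.
#' @export
make_labels <- function(chain, dssp_file = NULL, compute_asa = TRUE) {
  L <- chain$length
  cb <- lapply(seq_len(L), function(i)
    cb_coordinate(chain$atoms[[i]], chain$resid[i]))
  have <- !vapply(cb, is.null, TRUE)
  dist_bins <- matrix(NA_integer_, L, L)
  if (any(have)) {
    M <- do.call(rbind, cb[have])
    D <- as.matrix(stats::dist(M))
    dist_bins[have, have] <- bin_distance(D)
  }
  phi <- rep(NA_real_, L); psi <- rep(NA_real_, L)
  get <- function(i, nm) {
    a <- chain$atoms[[i]]
    if (is.null(a) || !nm %in% rownames(a)) return(NULL)
    a[nm, ]
  }
  for (i in seq_len(L)) {
    if (i > 1) {
      p <- list(get(i - 1, "C"), get(i, "N"), get(i, "CA"), get(i, "C"))
      if (!any(vapply(p, is.null, TRUE)))
        phi[i] <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    }
    if (i < L) {
      p <- list(get(i, "N"), get(i, "CA"), get(i, "C"), get(i + 1, "N"))
      if (!any(vapply(p, is.null, TRUE)))
        psi[i] <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    }
  }
  asa <- rep(NA_real_, L)
  if (compute_asa) {
    for (i in which(chain$mask)) asa[i] <- relative_asa(chain, i)
  }
  ss <- secondary_structure(chain, dssp_file)
  phi_c <- bin_angle(phi); psi_c <- bin_angle(psi)
  phi_c[!chain$mask] <- 36L; psi_c[!chain$mask] <- 36L
  asa_c <- bin_asa(asa); asa_c[!chain$mask] <- 10L
  ss[!chain$mask] <- 8L
  structure(list(dist_bins = dist_bins, ss = ss, phi = phi_c, psi = psi_c,
                 asa = asa_c, mask = chain$mask, length = L),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: L = %d (%d resolved residues)\n",
              x$length, sum(x$mask)))
  invisible(x)
}
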