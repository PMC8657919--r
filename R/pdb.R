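#' Construct a structure chain object
#'
#' An ordered list of residues with backbone (and C-beta) coordinates in
#' Angstroms. Residues missing from the structure are kept as explicit gaps
#' (\code{mask = FALSE}) so downstream label shapes always match the chain
#' length; internal indexing is 0-based with the original PDB numbering
#' retained in \code{resno}.
#'
#' @param resid character vector of 3-letter residue names ("UNK" for gaps).
#' @param atoms list (one element per residue) of numeric matrices with
#'   rownames among N, CA, C, O, CB and 3 columns (x, y, z); \code{NULL} for
#'   missing residues.
#' @param chain_id chain identifier.
#' @param resno original residue numbering (integer), for reports.
#' @return An object of class \code{"structure_chain"}.
#' @export
structure_chain <- function(resid, atoms, chain_id = "A",
                            resno = seq_along(resid)) {
  stopifnot(length(resid) == length(atoms))
  for (a in atoms) {
    if (!is.null(a) && (!is.numeric(a) || ncol(a) != 3 || any(!is.finite(a))))
      stop("atom coordinates must be finite n x 3 matrices")
  }
  mask <- vapply(atoms, function(a) !is.null(a) && "CA" %in% rownames(a), TRUE)
  structure(list(resid = resid, atoms = atoms, chain_id = chain_id,
                 resno = resno, mask = mask, length = length(resid)),
            class = "structure_chain")
}

#' @export
print.structure_chain <- function(x, ...) {
  cat(sprintf("structure_chain %s: %d residues (%d resolved)\n",
              x$chain_id, x$length, sum(x$mask)))
  invisible(x)
}

#' Read one chain from a PDB file
#'
#' Parses ATOM records via \code{bio3d::read.pdb} (first model only).
#' Alternate locations are resolved by highest occupancy, then first-seen.
#' Gaps in the numeric residue numbering become explicit missing residues;
#' insertion-coded residues are ordered lexicographically after their base
#' number (upstream files are assumed well-ordered; this is a convention, not
#' a guarantee about arbitrary PDB archives).
#'
#' @param path PDB file path.
#' @param chain chain identifier (single character).
#' @return A \code{\link{structure_chain}}.
#' @export
read_pdb_chain <- function(path, chain = "A") {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (!chain %in% chains) {
    stop(sprintf("chain '%s' not in %s; available chains: %s",
                 chain, path, paste(chains, collapse = ", ")))
  }
  at <- at[at$chain == chain, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  # altloc: highest occupancy then first-seen, per (residue, atom name)
  key <- paste(at$resno, at$insert, at$elety)
  at$o[is.na(at$o)] <- 1
  ord <- order(match(key, unique(key)), -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety)), , drop = FALSE]

  rkey <- unique(paste(at$resno, at$insert, sep = "_"))
  rtab <- at[!duplicated(paste(at$resno, at$insert, sep = "_")), ]
  ord <- order(rtab$resno, rtab$insert)
  rkey <- paste(rtab$resno, rtab$insert, sep = "_")[ord]
  rtab <- rtab[ord, ]

  resid <- character(0); atoms <- list(); resno <- integer(0)
  prev_no <- NA_integer_
  for (k in seq_along(rkey)) {
    this_no <- rtab$resno[k]
    if (!is.na(prev_no) && rtab$insert[k] == "" && this_no > prev_no + 1L) {
      for (g in (prev_no + 1L):(this_no - 1L)) {     # explicit gap residues
        resid <- c(resid, "UNK"); atoms <- c(atoms, list(NULL))
        resno <- c(resno, g)
      }
    }
    rows <- at$resno == rtab$resno[k] & at$insert == rtab$insert[k]
    sel <- at[rows & at$elety %in% c("N", "CA", "C", "O", "CB"), ]
    m <- as.matrix(sel[, c("x", "y", "z")])
    dimnames(m) <- list(sel$elety, NULL)
    resid <- c(resid, rtab$resid[k]); atoms <- c(atoms, list(m))
    resno <- c(resno, this_no)
    prev_no <- this_no
  }
  structure_chain(resid, atoms, chain_id = chain, resno = resno)
}

#' Write a structure chain as PDB text
#'
#' Emits plain ATOM records (backbone + CB); used mainly to serialize
#' synthetic fixtures for the command-line pipeline.
#'
#' @param chain a \code{\link{structure_chain}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pdb_chain <- function(chain, path) {
  stopifnot(inherits(chain, "structure_chain"))
  lines <- character(0); serial <- 0L
  elem <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  for (i in seq_len(chain$length)) {
    a <- chain$atoms[[i]]
    if (is.null(a)) next
    for (nm in intersect(c("N", "CA", "C", "O", "CB"), rownames(a))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, ifelse(nchar(nm) < 4, paste0(" ", nm), nm), chain$resid[i],
        chain$chain_id, chain$resno[i], a[nm, 1], a[nm, 2], a[nm, 3],
        1.00, 0.00, elem[[nm]]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' One-letter sequence of a structure chain
#'
#' @param chain a \code{\link{structure_chain}}.
#' @return character scalar; gaps/unknowns as \code{"-"}.
#' @export
chain_sequence <- function(chain) {
  one <- suppressWarnings(bio3d::aa321(chain$resid))
  one[is.na(one) | one == "X" | !chain$mask] <- "-"
  paste(one, collapse = "")
}
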