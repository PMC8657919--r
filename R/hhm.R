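#' Column layout of an HMM profile
#'
#' 20 match-emission probabilities (alphabetical amino-acid order), 7
#' transition probabilities and 3 per-column diversity (effective sequence
#' count) values, matching the HHsuite hhm text format.
#' @export
HHM_COLUMNS <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y",
                 "M_M","M_I","M_D","I_M","I_I","D_M","D_D",
                 "Neff","Neff_I","Neff_D")

#' Construct an HMM profile object
#'
#' @param mat L x 30 numeric matrix; columns per \code{\link{HHM_COLUMNS}}.
#'   Emission and transition entries are probabilities in [0, 1]; the three
#'   diversity columns are effective counts.
#' @return An object of class \code{"hmm_profile"}.
#' @export
hmm_profile <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 30, all(is.finite(mat)))
  colnames(mat) <- HHM_COLUMNS
  structure(list(profile = mat, length = nrow(mat)), class = "hmm_profile")
}

#' @export
print.hmm_profile <- function(x, ...) {
  cat(sprintf("hmm_profile: %d match states x 30 values\n", x$length))
  invisible(x)
}

# hhm integer score <-> probability: score = -1000 * log2(p); '*' <-> p = 0
.hhm_score_to_p <- function(tok) {
  p <- ifelse(tok == "*", 0, 2^(-suppressWarnings(as.numeric(tok)) / 1000))
  if (any(is.na(p))) stop("malformed hhm score token: ",
                          tok[which(is.na(p))[1]])
  p
}
.hhm_p_to_score <- function(p) {
  ifelse(p <= 0, "*", as.character(round(-1000 * log2(p))))
}

#' Read an HHsuite hhm profile file
#'
#' Integer scores (\code{-1000 * log2(p)}) are converted to probabilities;
#' the null score \code{"*"} maps to probability 0. Diversity columns are
#' converted from their x1000 integer representation to effective counts.
#'
#' @param path hhm file path.
#' @return An \code{\link{hmm_profile}}.
#' @export
read_hhm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hmm_at <- grep("^HMM\\s", lines)
  if (!length(hmm_at)) stop("no HMM block found in ", path)
  i <- hmm_at[1] + 3L  # skip column-header pair and the begin-state line
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "//") break
    if (ln == "") { i <- i + 1L; next }
    em_tok <- strsplit(ln, "\\s+")[[1]]
    if (length(em_tok) < 22)
      stop(sprintf("truncated emission line at line %d of %s", i, path))
    if (i + 1L > length(lines) || trimws(lines[i + 1L]) == "//")
      stop(sprintf("truncated profile block at line %d of %s", i, path))
    tr_tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(tr_tok) < 10)
      stop(sprintf("truncated transition line at line %d of %s", i + 1L, path))
    em <- .hhm_score_to_p(em_tok[3:22])
    tr <- .hhm_score_to_p(tr_tok[1:7])
    dv <- ifelse(tr_tok[8:10] == "*", 0,
                 suppressWarnings(as.numeric(tr_tok[8:10])) / 1000)
    rows[[length(rows) + 1L]] <- c(em, tr, dv)
    i <- i + 2L
  }
  if (!length(rows)) stop("no match states parsed from ", path)
  hmm_profile(do.call(rbind, rows))
}

#' Write an HMM profile in HHsuite hhm format
#'
#' @param prof an \code{\link{hmm_profile}}.
#' @param path output path.
#' @param name profile name for the header.
#' @param seq optional query sequence (defaults to argmax emissions).
#' @return \code{path}, invisibly.
#' @export
write_hhm <- function(prof, path, name = "profile", seq = NULL) {
  stopifnot(inherits(prof, "hmm_profile"))
  m <- prof$profile
  L <- prof$length
  if (is.null(seq)) {
    seq <- paste(HHM_COLUMNS[max.col(m[, 1:20, drop = FALSE],
                                     ties.method = "first")], collapse = "")
  }
  out <- c(sprintf("HHsearch 1.5"), sprintf("NAME  %s", name),
           sprintf("LENG  %d match states", L), "#",
           paste(c("HMM   ", HHM_COLUMNS[1:20]), collapse = "\t"),
           paste(c("      ", HHM_COLUMNS[21:30]), collapse = "\t"),
           paste(c("      ", "0", "*", "*", "0", "*", "0", "*",
                   "*", "*", "*"), collapse = "\t"))
  sq <- strsplit(seq, "")[[1]]
  for (i in seq_len(L)) {
    em <- .hhm_p_to_score(m[i, 1:20])
    tr <- .hhm_p_to_score(m[i, 21:27])
    dv <- as.character(round(m[i, 28:30] * 1000))
    out <- c(out,
             paste(c(sq[i], i, em, i), collapse = "\t"),
             paste(c("", tr, dv), collapse = "\t"),
             "")
  }
  writeLines(c(out, "//"), path)
  invisible(path)
}

#' Build an HMM profile directly from an alignment
#'
#' Internal fallback for when no hhm file from an external HMM builder is
#' available. Emission columns are weighted residue frequencies per site
#' (gap mass excluded, so each row of the 20 emission columns sums to at most
#' 1). The 7 transition columns are approximated from weighted match/gap
#' transitions between adjacent columns (insertion states do not occur in a
#' gap-free encoding, so I-state transitions are 0). Diversity columns carry
#' the effective sequence count. The layout matches \code{\link{read_hhm}}
#' output, so the two sources are interchangeable as network features.
#'
#' @param aln an \code{\link{msa}}.
#' @param w optional \code{\link{sequence_weights}} result; computed with the
#'   default identity threshold when missing.
#' @return An \code{\link{hmm_profile}}.
#' @export
profile_from_msa <- function(aln, w = NULL) {
  stopifnot(inherits(aln, "msa"))
  if (is.null(w)) w <- sequence_weights(aln)
  X <- msa_matrix(aln)
  L <- aln$length
  wt <- w$weights
  tot <- sum(wt)
  mat <- matrix(0, L, 30)
  for (j in seq_len(L)) {
    f <- vapply(1:20, function(a) sum(wt[X[, j] == a]), 0) / tot
    mat[j, 1:20] <- f
  }
  # transition estimates between columns j and j+1 (M = residue, D = gap)
  for (j in seq_len(L)) {
    if (j < L) {
      m_here <- X[, j] != 21L; m_next <- X[, j + 1L] != 21L
      wm <- sum(wt[m_here]); wd <- sum(wt[!m_here])
      mm <- if (wm > 0) sum(wt[m_here & m_next]) / wm else 1
      dd <- if (wd > 0) sum(wt[!m_here & !m_next]) / wd else 0
      mat[j, 21] <- mm              # M->M
      mat[j, 23] <- 1 - mm          # M->D
      mat[j, 26] <- 1 - dd          # D->M
      mat[j, 27] <- dd              # D->D
    } else {
      mat[j, 21] <- 1
    }
    mat[j, 24] <- 1                 # I->M (vacuous: no insert states)
  }
  mat[, 28] <- w$neff
  mat[, 30] <- vapply(seq_len(L), function(j) sum(wt[X[, j] == 21L]), 0)
  hmm_profile(mat)
}
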