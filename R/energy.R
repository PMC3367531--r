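# Fixed-backbone contact energetics: E(S, X) = sum over contacts (i,j) of X
# of eps[s_i, s_j], plus the structure's sequence-independent hydrogen-bond
# term E_HB. All energies in reduced units with k_B = 1.

#' Amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes, in the fixed order used by interaction
#' matrices and by the Monte Carlo kernels.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy indices, the published scale behind the default
# interaction matrix.
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

#' Default residue-residue interaction matrix
#'
#' A symmetric 20 x 20 contact-energy matrix in reduced units built from the
#' Kyte-Doolittle hydropathy scale as `eps[a, b] = -scale * (h_a + h_b)`:
#' the additive, hydrophobicity-dominated form that knowledge-based contact
#' potentials are well approximated by. Hydrophobic pairs are favourable
#' (negative), polar pairs unfavourable. Any user matrix in the same layout
#' can be supplied wherever an interaction matrix is accepted.
#'
#' @param scale Energy scale per unit hydropathy sum (default 0.1, giving
#'   contact energies in roughly `[-0.9, 0.9]`).
#' @return A named symmetric 20 x 20 matrix over [AA_ALPHABET].
#' @export
default_interaction_matrix <- function(scale = 0.1) {
  h <- KD_HYDROPATHY[AA_ALPHABET]
  m <- -scale * outer(h, h, `+`)
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}

check_interaction_matrix <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop("interaction matrix must be square", call. = FALSE)
  if (any(!is.finite(M))) stop("interaction matrix has non-finite entries", call. = FALSE)
  if (max(abs(M - t(M))) > 1e-12)
    stop("interaction matrix must be symmetric", call. = FALSE)
  if (is.null(rownames(M))) stop("interaction matrix needs letter dimnames", call. = FALSE)
  M
}

#' Read or write an interaction matrix as whitespace-delimited text
#'
#' Layout: a header row of one-letter codes, then one labelled row per
#' residue type.
#'
#' @param path File path.
#' @param M Matrix to write.
#' @return `read_interaction_matrix` returns the checked matrix.
#' @export
read_interaction_matrix <- function(path) {
  m <- as.matrix(read.table(path, header = TRUE, check.names = FALSE))
  check_interaction_matrix(m)
}

#' @rdname read_interaction_matrix
#' @export
write_interaction_matrix <- function(M, path) {
  write.table(format(M, digits = 10), path, quote = FALSE, sep = "\t")
  invisible(path)
}

seq_to_idx <- function(seq, letters = AA_ALPHABET) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(ch, letters)
  if (anyNA(idx)) {
    stop("unknown letter '", ch[which(is.na(idx))[1]], "' at position ",
         which(is.na(idx))[1], call. = FALSE)
  }
  idx
}

#' Total energy of a sequence threaded on a structure
#'
#' `E(S, X) = sum_{(i,j) in contacts(X)} eps[s_i, s_j] + E_HB(X)`. The
#' hydrogen-bond term is a property of the structure and does not depend on
#' the sequence.
#'
#' @param seq Amino-acid string (length must match the structure).
#' @param X An [ss_structure()].
#' @param M Interaction matrix (default [default_interaction_matrix()]).
#' @return Energy in reduced units.
#' @export
total_energy <- function(seq, X, M = default_interaction_matrix()) {
  M <- check_interaction_matrix(M)
  idx <- seq_to_idx(seq, rownames(M))
  if (length(idx) != X$length) stop("sequence/structure length mismatch", call. = FALSE)
  e <- X$e_hb
  if (X$n_contacts > 0L) {
    e <- e + sum(M[cbind(idx[X$contacts[, 1] + 1L], idx[X$contacts[, 2] + 1L])])
  }
  e
}

#' Energy change of a single point mutation
#'
#' Computes `total_energy(after) - total_energy(before)` touching only the
#' contacts incident to the mutated site.
#'
#' @param seq Amino-acid string.
#' @param site 1-based position of the mutation.
#' @param new_letter Replacement residue type.
#' @inheritParams total_energy
#' @return Energy difference in reduced units.
#' @export
mutation_delta <- function(seq, site, new_letter, X,
                           M = default_interaction_matrix()) {
  M <- check_interaction_matrix(M)
  letters <- rownames(M)
  idx <- seq_to_idx(seq, letters)
  if (length(idx) != X$length) stop("sequence/structure length mismatch", call. = FALSE)
  if (site < 1L || site > length(idx)) stop("site out of range", call. = FALSE)
  new <- match(new_letter, letters)
  if (is.na(new)) stop("unknown letter '", new_letter, "'", call. = FALSE)
  old <- idx[site]
  if (new == old) return(0)
  s0 <- site - 1L  # contacts are 0-based
  inc <- X$contacts[X$contacts[, 1] == s0 | X$contacts[, 2] == s0, , drop = FALSE]
  if (nrow(inc) == 0L) return(0)
  partner <- ifelse(inc[, 1] == s0, inc[, 2], inc[, 1]) + 1L
  sum(M[cbind(new, idx[partner])]) - sum(M[cbind(old, idx[partner])])
}

#' Log multinomial permutation count of a sequence composition
#'
#' `ln N_perm = ln [ N! / (n_1! ... n_20!) ]`, the sequence-entropy term that
#' the design acceptance rule maximizes to avoid homopolymer collapse.
#' Computed via log-gamma.
#'
#' @param seq Amino-acid string, or a named/unnamed integer composition
#'   vector of per-type counts.
#' @return Natural log of the number of distinct letter permutations.
#' @export
log_n_perm <- function(seq) {
  counts <- if (is.character(seq)) {
    tabulate(seq_to_idx(seq), nbins = length(AA_ALPHABET))
  } else {
    as.integer(seq)
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
}

#' Incremental change in the log permutation count under one substitution
#'
#' Moving one residue from type `old` to type `new` changes `ln N_perm` by
#' `ln(n_old) - ln(n_new + 1)`, where the counts are those *before* the move.
#'
#' @param n_old Pre-move count of the disappearing type (must be >= 1).
#' @param n_new Pre-move count of the appearing type.
#' @return The increment in natural-log units.
#' @export
d_log_n_perm <- function(n_old, n_new) {
  if (n_old < 1) stop("n_old must be >= 1", call. = FALSE)
  log(n_old) - log(n_new + 1)
}
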