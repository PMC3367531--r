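# Stepping-stone structures as contact maps with hydrogen-bond bookkeeping.
# A structure is fully described, for every downstream computation, by its
# contact set, its hydrogen-bond count (through E_HB = -eps_hb * n_hbonds)
# and its provenance secondary-structure string.

#' Construct a stepping-stone structure object
#'
#' @param id Structure identifier.
#' @param length Chain length (number of residues).
#' @param contacts Two-column integer matrix of 0-based residue pairs `(i, j)`
#'   with `i < j` and `j - i >= 3`; may have zero rows.
#' @param n_hbonds Non-negative hydrogen-bond count.
#' @param ss Optional provenance secondary-structure string.
#' @param eps_hb Energy per hydrogen bond (reduced units); `E_HB = -eps_hb *
#'   n_hbonds`.
#' @return An object of class `ss_structure` with fields `id`, `length`,
#'   `contacts`, `n_contacts`, `n_hbonds`, `e_hb`, `ss`.
#' @export
ss_structure <- function(id, length, contacts, n_hbonds = 0L, ss = NULL,
                         eps_hb = 1) {
  contacts <- normalize_contacts(contacts, length)
  stopifnot(n_hbonds >= 0, eps_hb >= 0)
  structure(
    list(id = as.character(id), length = as.integer(length),
         contacts = contacts, n_contacts = nrow(contacts),
         n_hbonds = as.integer(n_hbonds),
         e_hb = -eps_hb * as.integer(n_hbonds), ss = ss),
    class = "ss_structure")
}

#' @export
print.ss_structure <- function(x, ...) {
  cat(sprintf("stepping stone '%s': %d residues, N_c = %d, n_hbonds = %d (E_HB = %g)\n",
              x$id, x$length, x$n_contacts, x$n_hbonds, x$e_hb))
  invisible(x)
}

normalize_contacts <- function(contacts, length) {
  if (is.null(contacts) || (is.matrix(contacts) && nrow(contacts) == 0L)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  contacts <- as.matrix(contacts)
  if (ncol(contacts) != 2L) stop("contacts must be a two-column matrix", call. = FALSE)
  storage.mode(contacts) <- "integer"
  swap <- contacts[, 1] > contacts[, 2]
  if (any(swap)) contacts[swap, ] <- contacts[swap, 2:1]
  if (any(contacts[, 1] < 0L) || any(contacts[, 2] >= length))
    stop("contact indices out of range [0, length)", call. = FALSE)
  if (any(contacts[, 2] - contacts[, 1] < 3L))
    stop("contacts require sequence separation j - i >= 3", call. = FALSE)
  key <- contacts[, 1] * length + contacts[, 2]
  if (anyDuplicated(key)) contacts <- contacts[!duplicated(key), , drop = FALSE]
  contacts <- contacts[order(contacts[, 1], contacts[, 2]), , drop = FALSE]
  dimnames(contacts) <- list(NULL, c("i", "j"))
  contacts
}

# Deterministic secondary-structure scaffold: local helix contacts and
# antiparallel sheet pairings, with the hydrogen-bond counts they imply.
ss_scaffold <- function(ss) {
  el <- ss_elements(ss)
  contacts <- matrix(integer(0), ncol = 2)
  n_hb <- 0L
  if (nrow(el)) {
    for (k in seq_len(nrow(el))) {
      if (el$kind[k] == "H") {
        s <- el$start[k]; e <- el$end[k]  # 0-based [s, e)
        len <- e - s
        n_hb <- n_hb + max(0L, len - 4L)
        i <- s:(e - 1L)
        for (off in 3:4) {
          ii <- i[i + off <= e - 1L]
          if (length(ii)) contacts <- rbind(contacts, cbind(ii, ii + off))
        }
      }
    }
    strands <- el[el$kind == "E", , drop = FALSE]
    if (nrow(strands) >= 2L) {
      for (k in seq_len(nrow(strands) - 1L)) {
        a <- strands[k, ]; b <- strands[k + 1L, ]
        npair <- min(a$length, b$length)
        # antiparallel in chain order: residue a.end-1-t pairs b.start+t
        for (t in 0:(npair - 1L)) {
          i <- a$end - 1L - t; j <- b$start + t
          if (j - i >= 3L) {
            contacts <- rbind(contacts, c(i, j))
            n_hb <- n_hb + 1L
          }
        }
      }
    }
  }
  list(contacts = contacts, n_hbonds = n_hb)
}

#' Generate a synthetic stepping-stone structure from a secondary-structure string
#'
#' Builds a contact map deterministically from the secondary structure --
#' helices of length l contribute their (i, i+3) and (i, i+4) local contacts
#' and l - 4 hydrogen bonds; consecutive strands pair antiparallel in chain
#' order, each aligned pair contributing one cross contact and one hydrogen
#' bond -- then pads with long-range contacts drawn uniformly at random
#' (seeded, respecting `j - i >= 3`, no duplicates) until the requested
#' compactness `N_c = target_contacts` is reached.
#'
#' @param ss A valid secondary-structure string.
#' @param target_contacts Desired total contact count; must lie between the
#'   scaffold floor implied by `ss` and the combinatorial ceiling.
#' @param id Identifier for the returned structure.
#' @param extra_hbonds Additional hydrogen bonds beyond the scaffold count
#'   (allows sweeping E_HB independently of topology).
#' @param eps_hb Energy per hydrogen bond (reduced units).
#' @param parent Optional [ss_structure()] whose long-range contacts are
#'   preferentially inherited, controlling the shared-contact fraction
#'   between related stepping stones.
#' @param share Fraction of the random contacts drawn from `parent` (when
#'   available) rather than uniformly.
#' @param seed Integer seed; the generator is deterministic given all inputs.
#' @return An [ss_structure()].
#' @export
synth_structure <- function(ss, target_contacts, id = "synthetic",
                            extra_hbonds = 0L, eps_hb = 1,
                            parent = NULL, share = 0.7, seed = 1L) {
  viol <- ss_validate(ss)
  if (length(viol) && !all(grepl("total structured residues", viol))) {
    stop("invalid secondary-structure string: ",
         paste(viol, collapse = "; "), call. = FALSE)
  }
  n <- nchar(ss)
  sc <- ss_scaffold(ss)
  base <- normalize_contacts(sc$contacts, n)
  floor_nc <- nrow(base)
  all_pairs <- which(outer(0:(n - 1), 0:(n - 1),
                           function(i, j) j - i >= 3), arr.ind = TRUE) - 1L
  ceiling_nc <- nrow(all_pairs)
  if (target_contacts < floor_nc || target_contacts > ceiling_nc) {
    stop(sprintf("target_contacts must lie in [%d, %d] for this string",
                 floor_nc, ceiling_nc), call. = FALSE)
  }
  extra_needed <- target_contacts - floor_nc
  if (extra_needed > 0L) {
    rng <- local_rng(seed)
    key_base <- base[, 1] * n + base[, 2]
    key_pool <- all_pairs[, 1] * n + all_pairs[, 2]
    avail <- all_pairs[!(key_pool %in% key_base), , drop = FALSE]
    if (!is.null(parent) && parent$n_contacts > 0L && share > 0) {
      key_avail <- avail[, 1] * n + avail[, 2]
      from_parent <- avail[key_avail %in% contact_keys(parent), , drop = FALSE]
      n_inherit <- min(round(share * extra_needed), nrow(from_parent))
      if (n_inherit > 0L) {
        pick <- rng$sample_int(nrow(from_parent), size = n_inherit)
        base <- rbind(base, from_parent[pick, , drop = FALSE])
        key_base <- base[, 1] * n + base[, 2]
        avail <- avail[!(key_avail %in% key_base), , drop = FALSE]
        extra_needed <- extra_needed - n_inherit
      }
    }
    if (extra_needed > 0L) {
      pick <- rng$sample_int(nrow(avail), size = extra_needed)
      base <- rbind(base, avail[pick, , drop = FALSE])
    }
  }
  ss_structure(id, n, base, n_hbonds = sc$n_hbonds + as.integer(extra_hbonds),
               ss = ss, eps_hb = eps_hb)
}

contact_keys <- function(x) x$contacts[, 1] * x$length + x$contacts[, 2]

#' Shared-contact overlap between two structures
#'
#' Counts the residue contacts common to two structures and the symmetric
#' shared-contact fraction `q = 2 Q / (N_c^A + N_c^B)` that enters the
#' common-contact rate factor. The per-endpoint display variant
#' (`Q / N_c` of each structure) is also returned.
#'
#' @param A,B Structures of equal length ([ss_structure()]).
#' @return List with `Q` (shared contact count), `q` (symmetric fraction in
#'   `[0, 1]`), `frac_A`, `frac_B`.
#' @export
common_contacts <- function(A, B) {
  if (A$length != B$length) stop("structures differ in length", call. = FALSE)
  Q <- length(intersect(contact_keys(A), contact_keys(B)))
  tot <- A$n_contacts + B$n_contacts
  list(Q = Q,
       q = if (tot == 0L) 0 else 2 * Q / tot,
       frac_A = if (A$n_contacts) Q / A$n_contacts else 0,
       frac_B = if (B$n_contacts) Q / B$n_contacts else 0)
}

#' Contact map from C-alpha coordinates
#'
#' @param coords Numeric matrix with one row per residue and three columns
#'   (Angstrom).
#' @param cutoff Distance cutoff in Angstrom; a contact is counted for any
#'   pair strictly below it with sequence separation `j - i >= 3`.
#' @return Two-column 0-based integer contact matrix.
#' @export
contacts_from_coords <- function(coords, cutoff = 8) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) < 4L || any(!is.finite(coords)))
    stop("coords must be a finite n x 3 matrix with n >= 4", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  d <- as.matrix(dist(coords))
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] >= 3L, , drop = FALSE]
  normalize_contacts(idx - 1L, nrow(coords))
}

#' Distance-matrix RMSD between two conformations
#'
#' Root mean square deviation over all intramolecular pairwise distances,
#' computed without superposition and therefore invariant under rigid motion.
#'
#' @param x,y Coordinate matrices (n x 3, Angstrom) of equal length `n >= 2`.
#' @return DRMSD in Angstrom.
#' @export
drmsd <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y) || nrow(x) < 2L)
    stop("coordinate sets must have equal length >= 2", call. = FALSE)
  dx <- dist(x); dy <- dist(y)
  sqrt(mean((dx - dy)^2))
}

#' Read and write structures as JSON
#'
#' Schema: `{id, length, ss, contacts: [[i, j], ...], n_hbonds}` with 0-based
#' indices and `i < j`.
#'
#' @param x An [ss_structure()].
#' @param path File path.
#' @param eps_hb Hydrogen-bond energy scale used when reading.
#' @return `read_structure_json` returns an [ss_structure()];
#'   `write_structure_json` returns `path` invisibly.
#' @export
write_structure_json <- function(x, path) {
  obj <- list(id = x$id, length = x$length, ss = x$ss,
              contacts = unname(x$contacts), n_hbonds = x$n_hbonds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_structure_json
#' @export
read_structure_json <- function(path, eps_hb = 1) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ss_structure(obj$id, obj$length, obj$contacts, obj$n_hbonds,
               ss = obj$ss, eps_hb = eps_hb)
}
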