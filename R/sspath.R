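#' @useDynLib stepstone, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef dist lm median optim quantile residuals runif sd setNames vcov
#' @importFrom graphics hist
#' @importFrom utils combn head read.table tail write.table
NULL

# Secondary-structure grammar: strings over {H, E, C} (helix, strand, coil),
# rule-based validation, elementary edit moves, and exhaustive enumeration of
# parsimonious element-correspondence pathways between two endpoint folds.

SS_ALPHABET <- c("H", "E", "C")
HELIX_MIN <- 4L
HELIX_MAX <- 15L
STRAND_MIN <- 2L
STRAND_MAX <- 8L
STRUCT_MIN <- 20L
STRUCT_MAX <- 45L

#' Default endpoint secondary-structure strings
#'
#' Two length-56 secondary-structure strings representing the endpoint folds of
#' the bundled evolutionary experiment: the B1 domain of protein G (PDB 1PGB;
#' elements E7 E7 H15 E5 E5) and chain X of a SecM-stalled ribosome complex
#' (PDB 2GYC; elements E5 H8 E4 H7 E2). Element types, lengths and order are
#' the defining data; the coil gaps place the 1PGB elements at approximately
#' their native positions and spread the 2GYC elements evenly.
#'
#' @param id `"1PGB"` or `"2GYC"`.
#' @return A single secondary-structure string over `{H, E, C}`.
#' @examples
#' ss_elements(ss_endpoint("1PGB"))
#' @export
ss_endpoint <- function(id = c("1PGB", "2GYC")) {
  id <- match.arg(id)
  switch(id,
    "1PGB" = paste0(
      "C", strrep("E", 7), "CCCC", strrep("E", 7), "CCC",
      strrep("H", 15), "CCCC", strrep("E", 5), "CCCC", strrep("E", 5), "C"
    ),
    "2GYC" = paste0(
      "CCCC", strrep("E", 5), "CCCCC", strrep("H", 8), "CCCCC",
      strrep("E", 4), "CCCCC", strrep("H", 7), "CCCCC", strrep("E", 2), "CCCCCC"
    )
  )
}

ss_chars <- function(ss) {
  stopifnot(is.character(ss), length(ss) == 1L)
  ch <- strsplit(ss, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% SS_ALPHABET)
  if (length(bad)) {
    stop("invalid secondary-structure character '", ch[bad[1]],
         "' at position ", bad[1], " (alphabet is H, E, C)", call. = FALSE)
  }
  ch
}

#' Parse a secondary-structure string into its elements
#'
#' Returns the maximal structured runs (helices and strands) of a
#' secondary-structure string in left-to-right order.
#'
#' @param ss Secondary-structure string over `{H, E, C}`.
#' @return A data frame with one row per element: `kind` (`"H"` or `"E"`),
#'   `start` (0-based inclusive), `end` (0-based exclusive), `length`.
#' @examples
#' ss_elements("CHHHHCCEEC")
#' @export
ss_elements <- function(ss) {
  ch <- ss_chars(ss)
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != "C"
  data.frame(
    kind = r$values[keep],
    start = as.integer(starts[keep]),
    end = as.integer(ends[keep]),
    length = as.integer(r$lengths[keep]),
    stringsAsFactors = FALSE
  )
}

#' Validate a secondary-structure string against the grammar rules
#'
#' Checks the element-length bounds (helices 4--15, strands 2--8), the
#' requirement of at least one coil between consecutive structured elements,
#' and the bound of 20--45 on the total number of structured residues.
#'
#' @param ss Secondary-structure string.
#' @return Character vector of violation messages; empty when the string is
#'   valid. Each message names the violated rule and the position involved.
#' @export
ss_validate <- function(ss) {
  ch <- ss_chars(ss)
  el <- ss_elements(ss)
  out <- character(0)
  if (nrow(el)) {
    for (k in seq_len(nrow(el))) {
      kind <- el$kind[k]; len <- el$length[k]; pos <- el$start[k]
      if (kind == "H" && (len < HELIX_MIN || len > HELIX_MAX)) {
        out <- c(out, sprintf(
          "helix length %d at position %d outside [%d, %d]",
          len, pos, HELIX_MIN, HELIX_MAX))
      }
      if (kind == "E" && (len < STRAND_MIN || len > STRAND_MAX)) {
        out <- c(out, sprintf(
          "strand length %d at position %d outside [%d, %d]",
          len, pos, STRAND_MIN, STRAND_MAX))
      }
    }
    if (nrow(el) > 1L) {
      gap0 <- which(el$start[-1L] == el$end[-nrow(el)])
      for (k in gap0) {
        out <- c(out, sprintf(
          "elements touching at position %d: no separating coil", el$end[k]))
      }
    }
  }
  nstruct <- sum(ch != "C")
  if (nstruct < STRUCT_MIN || nstruct > STRUCT_MAX) {
    out <- c(out, sprintf(
      "total structured residues %d outside [%d, %d]",
      nstruct, STRUCT_MIN, STRUCT_MAX))
  }
  out
}

ss_is_valid <- function(ss) length(ss_validate(ss)) == 0L

#' Distance between two secondary-structure strings
#'
#' The default `"conversion"` metric is the per-position single-character
#' conversion cost: 0 for identical states, 1 between coil and a structured
#' state, 2 between the two structured states (which can only interconvert
#' through coil). It equals the minimum number of single-character
#' conversions separating the strings and is the metric under which pathway
#' moves must approach the destination fold: plain `"hamming"` mismatch
#' counting is also available, but leaves the necessary structured-to-coil
#' steps distance-neutral wherever an element must change type in place, so
#' no strictly approaching path can exist there.
#'
#' @param a,b Secondary-structure strings of equal length.
#' @param method `"conversion"` (default) or `"hamming"`.
#' @return Integer distance.
#' @export
ss_distance <- function(a, b, method = c("conversion", "hamming")) {
  method <- match.arg(method)
  ca <- ss_chars(a); cb <- ss_chars(b)
  if (length(ca) != length(cb)) stop("strings differ in length", call. = FALSE)
  if (method == "hamming") return(sum(ca != cb))
  mism <- ca != cb
  sum(mism) + sum(mism & ca != "C" & cb != "C")
}

apply_chars <- function(ch) paste(ch, collapse = "")

#' Enumerate legal elementary moves from a secondary-structure string
#'
#' The move set comprises: lengthening an element by converting an adjacent
#' coil, shortening an element by converting a terminal residue to coil,
#' inserting a minimal helix (`CHHHHC`) or strand (`CEEC`) into an all-coil
#' window, and deleting a whole minimal-length element. Every returned string
#' re-validates clean; moves that would break any rule are not offered. With a
#' `target`, only moves that strictly decrease the Hamming distance to it are
#' returned.
#'
#' @param ss A valid secondary-structure string.
#' @param target Optional destination string of the same length.
#' @return A data frame with columns `move` (human-readable descriptor) and
#'   `ss` (resulting string), zero rows when no legal move exists.
#' @export
ss_moves <- function(ss, target = NULL) {
  viol <- ss_validate(ss)
  if (length(viol)) {
    stop("invalid secondary-structure string: ",
         paste(viol, collapse = "; "), call. = FALSE)
  }
  ch <- ss_chars(ss)
  n <- length(ch)
  el <- ss_elements(ss)
  cand_move <- character(0)
  cand_ss <- character(0)
  add <- function(move, chars) {
    cand_move <<- c(cand_move, move)
    cand_ss <<- c(cand_ss, apply_chars(chars))
  }

  if (nrow(el)) {
    for (k in seq_len(nrow(el))) {
      kind <- el$kind[k]; s <- el$start[k]; e <- el$end[k]
      # lengthen left / right (rule ii)
      if (s > 0 && ch[s] == "C") {
        new <- ch; new[s] <- kind
        add(sprintf("lengthen %s@%d left", kind, s), new)
      }
      if (e < n && ch[e + 1L] == "C") {
        new <- ch; new[e + 1L] <- kind
        add(sprintf("lengthen %s@%d right", kind, s), new)
      }
      # shorten left / right (rule iii)
      new <- ch; new[s + 1L] <- "C"
      add(sprintf("shorten %s@%d left", kind, s), new)
      if (e - s > 1L) {
        new <- ch; new[e] <- "C"
        add(sprintf("shorten %s@%d right", kind, s), new)
      }
      # delete a minimal element (rule vi)
      min_len <- if (kind == "H") HELIX_MIN else STRAND_MIN
      if (e - s == min_len) {
        new <- ch; new[(s + 1L):e] <- "C"
        add(sprintf("delete %s@%d", kind, s), new)
      }
    }
  }

  # insertions into all-coil windows (rule v): C + core + C must fit
  coil <- ch == "C"
  for (spec in list(c("H", HELIX_MIN), c("E", STRAND_MIN))) {
    kind <- spec[1]; core <- as.integer(spec[2])
    w <- core + 2L
    if (n >= w) {
      for (s in 0:(n - w)) {
        idx <- (s + 1L):(s + w)
        if (all(coil[idx])) {
          new <- ch; new[(s + 2L):(s + 1L + core)] <- kind
          add(sprintf("insert %s@%d", kind, s + 1L), new)
        }
      }
    }
  }

  keep <- vapply(cand_ss, ss_is_valid, logical(1), USE.NAMES = FALSE)
  cand_move <- cand_move[keep]; cand_ss <- cand_ss[keep]
  dup <- duplicated(cand_ss)
  cand_move <- cand_move[!dup]; cand_ss <- cand_ss[!dup]

  if (!is.null(target)) {
    d0 <- ss_distance(ss, target)
    d <- vapply(cand_ss, ss_distance, integer(1), b = target, USE.NAMES = FALSE)
    keep <- d < d0
    cand_move <- cand_move[keep]; cand_ss <- cand_ss[keep]
  }
  data.frame(move = cand_move, ss = cand_ss, stringsAsFactors = FALSE)
}

match_internal <- function(src_kinds, dst_kinds) {
  # all injective, order- and type-preserving partial matchings
  res <- list()
  recurse <- function(i, j_min, pairs) {
    if (i > length(src_kinds)) {
      res[[length(res) + 1L]] <<- pairs
      return(invisible())
    }
    # source element i unmatched (disappears)
    recurse(i + 1L, j_min, pairs)
    if (j_min <= length(dst_kinds)) {
      for (j in j_min:length(dst_kinds)) {
        if (dst_kinds[j] == src_kinds[i]) {
          recurse(i + 1L, j + 1L, rbind(pairs, c(i, j)))
        }
      }
    }
  }
  recurse(1L, 1L, matrix(integer(0), ncol = 2))
  res
}

#' Enumerate parsimonious element-correspondence pathways
#'
#' Enumerates every injective, type-preserving, order-preserving partial
#' matching between the internal secondary-structure elements of two endpoint
#' folds, with the terminal strands held fixed. Each matching defines one
#' pathway class: matched elements persist ("move"), unmatched source elements
#' disappear, unmatched destination elements are created.
#'
#' @param src,dst Valid secondary-structure strings whose first and last
#'   elements are strands.
#' @return A list of pathway mappings. Each mapping is a two-column integer
#'   matrix of (source element index, destination element index) pairs over the
#'   *internal* elements (1-based, terminals excluded), with attributes
#'   `src_kinds` and `dst_kinds`, and a `description` attribute listing kept,
#'   lost and created elements.
#' @examples
#' length(ss_pathways(ss_endpoint("1PGB"), ss_endpoint("2GYC")))  # 7
#' @export
ss_pathways <- function(src, dst) {
  for (nm in c("src", "dst")) {
    ss <- get(nm)
    viol <- ss_validate(ss)
    if (length(viol)) {
      stop(nm, " is not a valid secondary-structure string: ",
           paste(viol, collapse = "; "), call. = FALSE)
    }
  }
  es <- ss_elements(src); ed <- ss_elements(dst)
  if (nrow(es) < 2L || nrow(ed) < 2L ||
      es$kind[1] != "E" || es$kind[nrow(es)] != "E" ||
      ed$kind[1] != "E" || ed$kind[nrow(ed)] != "E") {
    stop("both endpoints must begin and end with a terminal strand",
         call. = FALSE)
  }
  sk <- es$kind[-c(1L, nrow(es))]
  dk <- ed$kind[-c(1L, nrow(ed))]
  maps <- match_internal(sk, dk)
  lapply(maps, function(m) {
    colnames(m) <- c("src", "dst")
    attr(m, "src_kinds") <- sk
    attr(m, "dst_kinds") <- dk
    lost <- setdiff(seq_along(sk), m[, 1])
    new <- setdiff(seq_along(dk), m[, 2])
    attr(m, "description") <- sprintf(
      "kept: %s | lost: %s | created: %s",
      if (nrow(m)) paste(sprintf("%s%d>%s%d", sk[m[, 1]], m[, 1],
                                 dk[m[, 2]], m[, 2]), collapse = ",") else "-",
      if (length(lost)) paste0(sk[lost], lost, collapse = ",") else "-",
      if (length(new)) paste0(dk[new], new, collapse = ",") else "-")
    m
  })
}

#' Build a move-by-move pathway between two folds
#'
#' Realizes one pathway as a sequence of elementary edit moves from `src` to
#' `dst`. At every step one move is drawn uniformly (seeded) from the legal
#' moves that strictly decrease the Hamming distance to `dst`, so the path
#' terminates in at most `ss_distance(src, dst)` steps. The element mapping
#' labels the pathway class and is carried as metadata; element "movement" is
#' realized by shorten/lengthen (and delete/insert) composites of the
#' elementary moves.
#'
#' @param src,dst Valid secondary-structure strings of equal length.
#' @param mapping One mapping from [ss_pathways()] (metadata only; optional).
#' @param seed Integer seed controlling tie-breaks among eligible moves.
#' @return An object of class `ss_path`: list with `steps` (character vector
#'   of strings from `src` to `dst` inclusive), `moves` (descriptors),
#'   `distance` (distance-to-target after each step) and `mapping`.
#'   If the greedy walk reaches a dead end, an error of class
#'   `stepstone_path_error` carrying the stuck string is thrown; retry with
#'   another seed.
#' @export
ss_build_path <- function(src, dst, mapping = NULL, seed = 1L) {
  if (nchar(src) != nchar(dst)) stop("endpoint strings differ in length", call. = FALSE)
  rng <- local_rng(seed)
  steps <- src
  moves <- character(0)
  dist <- ss_distance(src, dst)
  cur <- src
  while (cur != dst) {
    mv <- ss_moves(cur, target = dst)
    if (nrow(mv) == 0L) {
      cond <- structure(
        class = c("stepstone_path_error", "error", "condition"),
        list(message = paste0("pathway dead end at distance ",
                              ss_distance(cur, dst), "; stuck string: ", cur),
             call = sys.call(-1), stuck = cur))
      stop(cond)
    }
    k <- if (nrow(mv) == 1L) 1L else rng$sample_int(nrow(mv))
    cur <- mv$ss[k]
    steps <- c(steps, cur)
    moves <- c(moves, mv$move[k])
    dist <- c(dist, ss_distance(cur, dst))
  }
  structure(
    list(steps = steps, moves = moves, distance = dist, mapping = mapping),
    class = "ss_path")
}

#' @export
print.ss_path <- function(x, ...) {
  cat("secondary-structure pathway:", length(x$steps) - 1L, "moves,",
      nchar(x$steps[1]), "residues\n")
  if (!is.null(x$mapping)) cat(" ", attr(x$mapping, "description"), "\n")
  invisible(x)
}

# Deterministic local RNG that does not disturb the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    sample_int = function(n, size = 1L, replace = FALSE)
      with_state(function() sample.int(n, size = size, replace = replace)),
    runif = function(n) with_state(function() runif(n)),
    derive_seed = function()
      with_state(function() sample.int(.Machine$integer.max, 1L))
  )
}
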