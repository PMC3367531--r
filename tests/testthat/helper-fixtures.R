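# Shared toy fixtures: small structures and exhaustive-enumeration helpers.

toy_structure_pair <- function() {
  list(
    A = ss_structure("A", 8L, rbind(c(0L, 4L), c(1L, 5L), c(2L, 7L)), n_hbonds = 2L),
    B = ss_structure("B", 8L, rbind(c(0L, 5L), c(3L, 7L), c(1L, 6L), c(0L, 7L)),
                     n_hbonds = 2L))
}

# all sequences over `letters` of length L, as a character vector
all_sequences <- function(letters, L) {
  do.call(paste0, expand.grid(rep(list(letters), L),
                              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
}

# exact Boltzmann distribution of the generalized design energy on a structure
exact_design_distribution <- function(X, M, letters, T, E_R) {
  sq <- all_sequences(letters, X$length)
  g <- vapply(sq, function(s)
    total_energy(s, X, M) - E_R * log_n_perm(s), numeric(1))
  w <- exp(-(g - min(g)) / T)
  setNames(w / sum(w), sq)
}

random_valid_ss <- function(seed) {
  # a pool of valid strings assembled from legal element lengths
  set.seed(seed)
  repeat {
    n_el <- sample(3:5, 1)
    kinds <- sample(c("H", "E"), n_el, replace = TRUE)
    lens <- ifelse(kinds == "H", sample(4:9, n_el, replace = TRUE),
                   sample(2:6, n_el, replace = TRUE))
    if (sum(lens) < 20 || sum(lens) > 45) next
    gaps <- sample(1:3, n_el + 1L, replace = TRUE)
    s <- paste0(strrep("C", gaps[1]),
                paste0(vapply(seq_len(n_el), function(i)
                  paste0(strrep(kinds[i], lens[i]), strrep("C", gaps[i + 1L])),
                  character(1)), collapse = ""))
    if (nchar(s) <= 56) {
      s <- paste0(s, strrep("C", 56 - nchar(s)))
      if (length(ss_validate(s)) == 0L) return(s)
    }
  }
}
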