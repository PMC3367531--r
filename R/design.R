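# Sequence design: entropy-regularized Monte Carlo on a fixed target
# structure. The acceptance rule minimizes the target energy while
# maximizing the multinomial permutation count of the composition, which
# keeps the designed population heterogeneous instead of collapsing to
# low-energy homopolymers.

#' Design configuration
#'
#' @param T_design Design temperature (dimensionless; must be a member of
#'   `ladder`). The island returned by [run_design()] is the population
#'   sampled at this temperature.
#' @param E_R Energy scaling factor multiplying the permutation term in the
#'   acceptance rule (non-negative).
#' @param n_sweeps Number of Monte Carlo sweeps (one sweep = one proposed
#'   substitution per site).
#' @param ladder Strictly increasing replica-exchange temperature ladder.
#' @param exchange_interval Sweeps between neighbour-swap attempts.
#' @param burn_in Sweeps discarded before recording (default 10% of
#'   `n_sweeps`).
#' @param record_every Thinning: record one sequence per this many sweeps.
#' @param rng_seed Integer seed; the run is deterministic given the seed.
#' @return A validated `design_config` list.
#' @export
design_config <- function(T_design = 1, E_R = 3, n_sweeps = 2000L,
                          ladder = NULL, exchange_interval = 10L,
                          burn_in = NULL, record_every = 1L, rng_seed = 1L) {
  if (is.null(ladder)) ladder <- T_design
  ladder <- sort(unique(c(ladder, T_design)))
  if (any(ladder <= 0)) stop("temperatures must be positive", call. = FALSE)
  if (T_design <= 0) stop("T_design must be positive", call. = FALSE)
  if (E_R < 0) stop("E_R must be non-negative", call. = FALSE)
  n_sweeps <- as.integer(n_sweeps)
  if (n_sweeps < 1L) stop("n_sweeps must be >= 1", call. = FALSE)
  if (is.null(burn_in)) burn_in <- as.integer(ceiling(0.1 * n_sweeps))
  structure(list(T_design = T_design, E_R = E_R, n_sweeps = n_sweeps,
                 ladder = ladder, exchange_interval = as.integer(exchange_interval),
                 burn_in = as.integer(burn_in),
                 record_every = as.integer(record_every),
                 rng_seed = as.integer(rng_seed)),
            class = "design_config")
}

#' Acceptance probability of a design move
#'
#' `p = min(1, exp(-(dE - E_R * d_log_nperm) / T))`: a Metropolis rule on the
#' generalized energy `E - E_R ln N_perm`, so moves are favoured both for
#' lowering the target energy and for increasing compositional heterogeneity.
#'
#' @param dE Energy change of the proposed substitution.
#' @param d_log_nperm Change in `ln N_perm` of the composition.
#' @param cfg A [design_config()] (its `T_design` and `E_R` are used).
#' @return Acceptance probability in `[0, 1]`.
#' @export
design_acceptance <- function(dE, d_log_nperm, cfg = design_config()) {
  if (cfg$T_design <= 0) stop("T_design must be positive", call. = FALSE)
  stopifnot(is.finite(dE), is.finite(d_log_nperm))
  pmin(1, exp(-(dE - cfg$E_R * d_log_nperm) / cfg$T_design))
}

mc_letters_to_seqs <- function(mat, letters) {
  apply(mat, 1L, function(r) paste(letters[r + 1L], collapse = ""))
}

#' Design a sequence island on a target structure
#'
#' Runs the replica-exchange design Monte Carlo (single-site substitution
#' proposals, acceptance per [design_acceptance()], neighbour swaps on the
#' generalized energy) and returns the sequence population recorded at the
#' design temperature, with all other ladder populations attached.
#'
#' @param X Target [ss_structure()].
#' @param M Interaction matrix.
#' @param cfg A [design_config()].
#' @param alphabet Letter set (default the 20 amino acids); the mutation move
#'   set proposes every type in this set.
#' @return An object of class `island`: list with `structure_id`, `sequences`
#'   (character vector), `energies` (total energies on `X`, including
#'   `E_HB`), `log_n_perm`, `temperature`, `acceptance`, `swap_acceptance`,
#'   and `ladder` (one record set per ladder temperature).
#' @export
run_design <- function(X, M = default_interaction_matrix(),
                       cfg = design_config(), alphabet = AA_ALPHABET) {
  M <- check_interaction_matrix(M)
  letters <- intersect(rownames(M), alphabet)
  if (length(letters) < 2L) stop("alphabet needs at least two letters", call. = FALSE)
  eps <- M[letters, letters, drop = FALSE]
  out <- mc_sample_cpp(
    L = X$length, n_letters = length(letters),
    contact_list = list(X$contacts), eps = unname(eps),
    temps = cfg$ladder, E_R = cfg$E_R, n_sweeps = cfg$n_sweeps,
    burn_in = cfg$burn_in, exchange_interval = cfg$exchange_interval,
    record_every = cfg$record_every, seed = cfg$rng_seed,
    init_seqs = matrix(integer(0), nrow = 0, ncol = X$length))
  ladder <- lapply(out$replicas, function(r) {
    list(temperature = r$temperature,
         sequences = mc_letters_to_seqs(r$seqs, letters),
         energies = as.numeric(r$E[, 1]) + X$e_hb,
         log_n_perm = as.numeric(r$log_n_perm),
         acceptance = r$acceptance)
  })
  k <- which.min(abs(vapply(ladder, `[[`, numeric(1), "temperature") - cfg$T_design))
  main <- ladder[[k]]
  structure(list(structure_id = X$id, sequences = main$sequences,
                 energies = main$energies, log_n_perm = main$log_n_perm,
                 temperature = main$temperature, acceptance = main$acceptance,
                 swap_acceptance = out$swap_acceptance, ladder = ladder,
                 alphabet = letters),
            class = "island")
}

#' @export
print.island <- function(x, ...) {
  cat(sprintf("island on '%s': %d sequences at T = %g, mean E = %.3f\n",
              x$structure_id, length(x$sequences), x$temperature,
              mean(x$energies)))
  invisible(x)
}

#' Per-site Shannon entropy of an island
#'
#' `S_i = -sum_a p_i(a) ln p_i(a)` in nats, with `p_i(a)` the frequency of
#' letter `a` at site `i` across the island's sequences.
#'
#' @param island An `island` from [run_design()], or a character vector of
#'   equal-length sequences.
#' @return Numeric vector of per-site entropies in `[0, ln 20]`.
#' @export
site_entropy <- function(island) {
  seqs <- if (inherits(island, "island")) island$sequences else island
  if (length(seqs) == 0L) stop("empty island", call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  apply(mat, 2L, function(col) {
    p <- table(col) / length(col)
    -sum(p * log(p))
  })
}

#' Distance between two site-entropy distributions
#'
#' Histograms both entropy profiles on a shared binning over `[0, ln 20]` and
#' returns the integrated absolute difference of the normalized histograms
#' (total-variation style; 0 for identical histograms, at most 2 for
#' disjointly supported ones). Used to pick the design temperature whose
#' sequence variability best matches a reference population.
#'
#' @param profile,reference Numeric entropy profiles (any lengths).
#' @param n_bins Number of shared histogram bins.
#' @return Non-negative divergence score.
#' @export
compare_entropy_distributions <- function(profile, reference, n_bins = 24L) {
  if (!length(profile) || !length(reference)) stop("empty profile", call. = FALSE)
  breaks <- seq(0, log(20) + 1e-9, length.out = n_bins + 1L)
  h1 <- hist(pmin(profile, log(20)), breaks = breaks, plot = FALSE)$counts
  h2 <- hist(pmin(reference, log(20)), breaks = breaks, plot = FALSE)$counts
  sum(abs(h1 / sum(h1) - h2 / sum(h2)))
}

#' Select the ladder temperature matching a reference entropy distribution
#'
#' Convenience wrapper: computes the site-entropy divergence of every ladder
#' population of a designed island against a reference profile and returns
#' the temperature minimizing it.
#'
#' @param island An `island` from [run_design()] (with its `ladder`).
#' @param reference Reference entropy profile.
#' @param n_bins Histogram bins for [compare_entropy_distributions()].
#' @return List with `temperature`, `divergences` (named by temperature).
#' @export
select_design_temperature <- function(island, reference, n_bins = 24L) {
  divs <- vapply(island$ladder, function(l) {
    compare_entropy_distributions(site_entropy(l$sequences), reference, n_bins)
  }, numeric(1))
  temps <- vapply(island$ladder, `[[`, numeric(1), "temperature")
  names(divs) <- temps
  list(temperature = temps[which.min(divs)], divergences = divs)
}

#' Free energy from a histogram of an order parameter
#'
#' `F(Q) = -T ln H(Q)`, shifted so the minimum over populated bins is zero.
#' Empty bins are undefined (`NA`).
#'
#' @param hist Non-negative bin counts.
#' @param T Temperature (reduced units).
#' @return Numeric vector of per-bin free energies (`NA` for empty bins).
#' @export
free_energy_from_histogram <- function(hist, T = 1) {
  if (any(hist < 0)) stop("negative counts", call. = FALSE)
  if (all(hist == 0)) stop("all-zero histogram", call. = FALSE)
  f <- ifelse(hist > 0, -T * log(hist), NA_real_)
  f - min(f, na.rm = TRUE)
}
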