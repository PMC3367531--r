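# Inter-island transition rates. The committor of a sequence for a pair of
# structures flips when its energy on the destination drops below its energy
# on the source; the rate constant k_AB is the source-ensemble average of
# that indicator, estimated by reweighting samples drawn from the biased
# joint ensemble with weight exp(-(E_A + E_B - E_R ln N_perm)/T), which
# concentrates sampling near the committor surface where both distributions
# overlap.

#' Rate-sampling configuration
#'
#' @param T Sampling temperature (dimensionless, > 0).
#' @param E_R Permutation-term scale, as in [design_config()]; keeps
#'   homopolymers out of the rate averages.
#' @param mu Mutation-rate prefactor multiplying all rates uniformly when
#'   absolute time units are requested (reduced inverse time).
#' @param n_samples Recorded joint-ensemble samples.
#' @param burn_in Discarded initial sweeps.
#' @param record_every Sweeps between records.
#' @param rng_seed Integer seed.
#' @return A validated `rate_config` list.
#' @export
rate_config <- function(T = 1, E_R = 3, mu = 1, n_samples = 5000L,
                        burn_in = NULL, record_every = 1L, rng_seed = 1L) {
  if (T <= 0) stop("T must be positive", call. = FALSE)
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  if (E_R < 0) stop("E_R must be non-negative", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (is.null(burn_in)) burn_in <- as.integer(ceiling(0.1 * n_samples))
  structure(list(T = T, E_R = E_R, mu = mu, n_samples = n_samples,
                 burn_in = as.integer(burn_in),
                 record_every = as.integer(record_every),
                 rng_seed = as.integer(rng_seed)),
            class = "rate_config")
}

#' Committor indicators of a sequence for a structure pair
#'
#' `Lambda_AB = 1` iff the sequence has strictly lower total energy on `B`
#' than on `A` (it is committed to evolve towards `B`); symmetrically for
#' `Lambda_BA`. Ties commit to neither direction.
#'
#' @param seq Amino-acid string.
#' @param A,B Structures of equal length.
#' @param M Interaction matrix.
#' @return Named integer vector `c(lambda_AB, lambda_BA)`.
#' @export
committor <- function(seq, A, B, M = default_interaction_matrix()) {
  eA <- total_energy(seq, A, M)
  eB <- total_energy(seq, B, M)
  c(lambda_AB = as.integer(eB < eA), lambda_BA = as.integer(eA < eB))
}

#' Acceptance probability in the biased joint ensemble
#'
#' `p = min(1, exp(-(dE_A + dE_B - E_R * d_log_nperm) / T))`: Metropolis for
#' the effective system `E_A + E_B` with the permutation term, symmetric
#' under swapping the roles of the two structures.
#'
#' @param dE_A,dE_B Energy changes on the two structures.
#' @param d_log_nperm Change in `ln N_perm`.
#' @param cfg A [rate_config()].
#' @return Acceptance probability in `[0, 1]`.
#' @export
joint_acceptance <- function(dE_A, dE_B, d_log_nperm, cfg = rate_config()) {
  if (cfg$T <= 0) stop("T must be positive", call. = FALSE)
  stopifnot(is.finite(dE_A), is.finite(dE_B), is.finite(d_log_nperm))
  pmin(1, exp(-(dE_A + dE_B - cfg$E_R * d_log_nperm) / cfg$T))
}

#' Sample the biased joint ensemble of a structure pair
#'
#' Markov chain over sequences with stationary weight proportional to
#' `exp(-(E_A + E_B - E_R ln N_perm) / T)`, via single-site substitutions.
#'
#' @param A,B Structures of equal length.
#' @param M Interaction matrix.
#' @param cfg A [rate_config()].
#' @param alphabet Letter set for proposals.
#' @return Object of class `joint_samples`: data frame with columns `seq`,
#'   `E_A`, `E_B` (total energies, including each structure's `E_HB`),
#'   `log_n_perm`, `committed_AB`, `committed_BA`; attributes carry the
#'   config and acceptance rate.
#' @export
sample_joint <- function(A, B, M = default_interaction_matrix(),
                         cfg = rate_config(), alphabet = AA_ALPHABET) {
  if (A$length != B$length) stop("structures differ in length", call. = FALSE)
  M <- check_interaction_matrix(M)
  letters <- intersect(rownames(M), alphabet)
  eps <- M[letters, letters, drop = FALSE]
  n_sweeps <- cfg$burn_in + cfg$n_samples * cfg$record_every
  out <- mc_sample_cpp(
    L = A$length, n_letters = length(letters),
    contact_list = list(A$contacts, B$contacts), eps = unname(eps),
    temps = cfg$T, E_R = cfg$E_R, n_sweeps = n_sweeps,
    burn_in = cfg$burn_in, exchange_interval = 0L,
    record_every = cfg$record_every, seed = cfg$rng_seed,
    init_seqs = matrix(integer(0), nrow = 0, ncol = A$length))
  r <- out$replicas[[1]]
  eA <- as.numeric(r$E[, 1]) + A$e_hb
  eB <- as.numeric(r$E[, 2]) + B$e_hb
  df <- data.frame(
    seq = mc_letters_to_seqs(r$seqs, letters),
    E_A = eA, E_B = eB, log_n_perm = as.numeric(r$log_n_perm),
    committed_AB = as.integer(eB < eA),
    committed_BA = as.integer(eA < eB),
    stringsAsFactors = FALSE)
  attr(df, "cfg") <- cfg
  attr(df, "acceptance") <- r$acceptance
  attr(df, "pair") <- c(A = A$id, B = B$id)
  class(df) <- c("joint_samples", class(df))
  df
}

logmeanexp_w <- function(logw, x = NULL) {
  m <- max(logw)
  w <- exp(logw - m)
  if (is.null(x)) mean(w) else sum(w * x) / sum(w)
}

#' Estimate rate constants from joint-ensemble samples
#'
#' Reweights the biased joint samples back to each single-structure
#' ensemble: `k_AB = <Lambda_AB w_B> / <w_B>` with `w_B = exp(+E_B / T)`
#' (log-space, max-shifted), which equals the ensemble-A average of the
#' committor. Standard errors by block bootstrap; an effective-sample-size
#' warning flag is set when the reweighting is degenerate.
#'
#' @param samples A `joint_samples` data frame from [sample_joint()].
#' @param cfg A [rate_config()] (defaults to the one stored on `samples`).
#' @param n_blocks Blocks for the bootstrap.
#' @param n_boot Bootstrap replicates.
#' @param absolute If `TRUE`, multiply rates by `mu` (absolute time units);
#'   default reports rates per mutation attempt.
#' @param ess_threshold Effective-sample-size warning threshold.
#' @return Object of class `rate_estimate`: list with `k_AB`, `k_BA`,
#'   `se_AB`, `se_BA`, `n_effective` (per direction), `low_ess` flag,
#'   `n_samples`.
#' @export
estimate_rate_constants <- function(samples, cfg = attr(samples, "cfg"),
                                    n_blocks = 50L, n_boot = 200L,
                                    absolute = FALSE, ess_threshold = 100) {
  if (!nrow(samples)) stop("no samples", call. = FALSE)
  if (is.null(cfg)) cfg <- rate_config()
  T <- cfg$T
  one_dir <- function(lambda, e_target, idx) {
    logw <- e_target[idx] / T
    m <- max(logw)
    w <- exp(logw - m)
    list(k = sum(w * lambda[idx]) / sum(w),
         ess = sum(w)^2 / sum(w^2))
  }
  n <- nrow(samples)
  full_AB <- one_dir(samples$committed_AB, samples$E_B, seq_len(n))
  full_BA <- one_dir(samples$committed_BA, samples$E_A, seq_len(n))
  # block bootstrap
  n_blocks <- min(n_blocks, n)
  block_id <- cut(seq_len(n), breaks = n_blocks, labels = FALSE)
  blocks <- split(seq_len(n), block_id)
  rng <- local_rng(cfg$rng_seed + 7L)
  boot <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    pick <- rng$sample_int(n_blocks, size = n_blocks, replace = TRUE)
    idx <- unlist(blocks[pick], use.names = FALSE)
    boot[b, 1] <- one_dir(samples$committed_AB, samples$E_B, idx)$k
    boot[b, 2] <- one_dir(samples$committed_BA, samples$E_A, idx)$k
  }
  scale <- if (absolute) cfg$mu else 1
  structure(list(
    k_AB = scale * full_AB$k, k_BA = scale * full_BA$k,
    se_AB = scale * sd(boot[, 1]), se_BA = scale * sd(boot[, 2]),
    n_effective = c(AB = full_AB$ess, BA = full_BA$ess),
    low_ess = min(full_AB$ess, full_BA$ess) < ess_threshold,
    n_samples = n, pair = attr(samples, "pair")),
    class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("k_AB = %.4g (SE %.2g), k_BA = %.4g (SE %.2g), ESS = %.0f/%.0f%s\n",
              x$k_AB, x$se_AB, x$k_BA, x$se_BA,
              x$n_effective[1], x$n_effective[2],
              if (isTRUE(x$low_ess)) " [low ESS]" else ""))
  invisible(x)
}

enumerate_sequences <- function(letters, L) {
  do.call(expand.grid, c(rep(list(letters), L),
                         list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
}

#' Exact rate constants by exhaustive enumeration
#'
#' Computes the exact Boltzmann-weighted committor averages over the full
#' sequence space of a small alphabet, including the permutation term:
#' `k_AB = sum_S Lambda_AB(S) w_A(S) / sum_S w_A(S)` with
#' `w_A = exp(-(E_A - E_R ln N_perm)/T)`. Intended as a verification oracle
#' for the Monte Carlo estimator on toy systems.
#'
#' @param A,B Structures of equal length.
#' @param M Interaction matrix (restricted to `alphabet`).
#' @param cfg A [rate_config()] (`T` and `E_R` are used).
#' @param alphabet Letter subset; `length(alphabet)^L` must be at most 1e7.
#' @return List with exact `k_AB`, `k_BA`, and the tie fraction in each
#'   source ensemble.
#' @export
exact_rate_oracle <- function(A, B, M = default_interaction_matrix(),
                              cfg = rate_config(), alphabet = c("A", "G")) {
  L <- A$length
  if (length(alphabet)^L > 1e7) stop("state space too large to enumerate", call. = FALSE)
  M <- check_interaction_matrix(M)
  letters <- intersect(rownames(M), alphabet)
  grid <- enumerate_sequences(letters, L)
  seqs <- do.call(paste0, grid)
  idx_mat <- matrix(match(as.matrix(grid), letters), nrow = nrow(grid))
  eps <- M[letters, letters, drop = FALSE]
  contact_energy <- function(X) {
    if (X$n_contacts == 0L) return(rep(0, length(seqs)))
    e <- rep(0, length(seqs))
    for (r in seq_len(X$n_contacts)) {
      i <- X$contacts[r, 1] + 1L; j <- X$contacts[r, 2] + 1L
      e <- e + eps[cbind(idx_mat[, i], idx_mat[, j])]
    }
    e
  }
  eA <- contact_energy(A) + A$e_hb
  eB <- contact_energy(B) + B$e_hb
  lnp <- apply(idx_mat, 1L, function(r) {
    counts <- tabulate(r, nbins = length(letters))
    lgamma(L + 1) - sum(lgamma(counts + 1))
  })
  lam_AB <- as.integer(eB < eA)
  lam_BA <- as.integer(eA < eB)
  logw_A <- -(eA - cfg$E_R * lnp) / cfg$T
  logw_B <- -(eB - cfg$E_R * lnp) / cfg$T
  avg <- function(lam, logw) {
    m <- max(logw); w <- exp(logw - m)
    sum(w * lam) / sum(w)
  }
  list(k_AB = avg(lam_AB, logw_A), k_BA = avg(lam_BA, logw_B),
       tie_fraction_A = avg(1L - lam_AB - lam_BA, logw_A),
       tie_fraction_B = avg(1L - lam_AB - lam_BA, logw_B))
}

#' Relative equilibrium probabilities from a network of rate estimates
#'
#' Detailed balance fixes `P_B / P_A = k_AB / k_BA` for every measured pair;
#' anchoring the reference structure at `P = 1` and propagating the ratios
#' along a spanning tree yields every structure's probability relative to the
#' reference. Ratios implied by non-tree edges are reported as per-cycle
#' log-residuals (zero when the rates come exactly from the detailed-balance
#' family).
#'
#' @param pairs Data frame with columns `A`, `B`, `k_AB`, `k_BA` (one row per
#'   measured pair).
#' @param reference Structure id anchored at relative probability 1.
#' @return List with `P` (named relative probabilities), `cycle_residuals`
#'   (named by the non-tree edge closing each independent cycle).
#' @export
relative_probabilities <- function(pairs, reference) {
  stopifnot(all(c("A", "B", "k_AB", "k_BA") %in% names(pairs)))
  if (any(pairs$k_AB <= 0 | pairs$k_BA <= 0))
    stop("zero or negative rate on a measured pair; cannot take log-ratios",
         call. = FALSE)
  g <- igraph::graph_from_data_frame(
    pairs[, c("A", "B")], directed = FALSE)
  igraph::E(g)$log_ratio <- log(pairs$k_AB / pairs$k_BA)  # = log(P_B/P_A)
  if (!reference %in% igraph::V(g)$name)
    stop("reference structure not in the pair graph", call. = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    members <- split(igraph::V(g)$name, comp$membership)
    stop("pair graph is disconnected; components: ",
         paste(vapply(members, paste, character(1), collapse = ","),
               collapse = " | "), call. = FALSE)
  }
  tree <- igraph::mst(g, weights = rep(1, igraph::ecount(g)))
  logP <- setNames(rep(NA_real_, igraph::vcount(g)), igraph::V(g)$name)
  logP[reference] <- 0
  # BFS over the tree from the reference
  order <- igraph::bfs(tree, root = reference, father = TRUE)
  vs <- igraph::V(tree)$name[as.integer(order$order)]
  fathers <- igraph::V(tree)$name[as.integer(order$father)]
  for (k in seq_along(vs)) {
    v <- vs[k]
    if (v == reference) next
    f <- fathers[match(v, igraph::V(tree)$name)]
    eid <- igraph::get_edge_ids(g, c(f, v))
    lr <- igraph::E(g)$log_ratio[eid]
    ends <- igraph::ends(g, eid)
    # log_ratio is log(P_B/P_A) for the stored (A, B) orientation
    logP[v] <- if (ends[1] == f) logP[f] + lr else logP[f] - lr
  }
  # cycle residuals from non-tree edges
  tree_ids <- igraph::get_edge_ids(
    g, t(igraph::ends(tree, igraph::E(tree))))
  extra <- setdiff(seq_len(igraph::ecount(g)), tree_ids)
  res <- vapply(extra, function(eid) {
    ends <- igraph::ends(g, eid)
    igraph::E(g)$log_ratio[eid] - (logP[ends[2]] - logP[ends[1]])
  }, numeric(1))
  names(res) <- vapply(extra, function(eid)
    paste(igraph::ends(g, eid), collapse = "-"), character(1))
  list(P = exp(logP), cycle_residuals = res)
}
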