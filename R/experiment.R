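# End-to-end seeded experiment: endpoints -> pathway -> synthetic stepping
# stones -> designed islands -> pairwise rates -> surface fit -> Markov
# analysis. Desk-scale defaults; every depth is config-exposed.

#' Experiment configuration
#'
#' @param src,dst Endpoint secondary-structure strings.
#' @param n_structures Number of stepping stones sampled along the pathway
#'   (>= 2; endpoints included).
#' @param contact_range Length-2 range of target contact counts swept
#'   linearly across the stepping stones.
#' @param hbond_jitter Maximum +/- jitter on each stone's extra hydrogen
#'   bonds (spreads the `dE_HB` axis).
#' @param contact_share Fraction of each stone's random long-range contacts
#'   inherited from its predecessor along the path, so that nearby stones
#'   share most of their topology and the shared-contact fraction decays
#'   with path separation (as it does across related folds).
#' @param design DesignConfig for island generation ([design_config()]).
#' @param rates RateConfig for joint sampling ([rate_config()]).
#' @param pair_max_sep Only pairs within this path separation are measured
#'   (jumps between very dissimilar stones are vanishingly rare and their
#'   committor averages saturate).
#' @param max_pairs Cap on the number of structure pairs measured (pairs are
#'   chosen deterministically: consecutive pairs first, then seeded draws).
#' @param mapping_index Which pathway mapping (1-based) labels the path.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional directory for TSV/JSON/FASTA outputs.
#' @return A validated `experiment_config` list.
#' @export
experiment_config <- function(src = ss_endpoint("1PGB"),
                              dst = ss_endpoint("2GYC"),
                              n_structures = 12L,
                              contact_range = c(100L, 140L),
                              hbond_jitter = 3L,
                              contact_share = 0.8,
                              design = design_config(n_sweeps = 600L),
                              rates = rate_config(T = 2, n_samples = 20000L),
                              pair_max_sep = 2L,
                              max_pairs = 30L,
                              mapping_index = 1L,
                              seed = 1L,
                              out_dir = NULL) {
  stopifnot(n_structures >= 2L, length(contact_range) == 2L,
            contact_range[1] <= contact_range[2],
            contact_share >= 0, contact_share <= 1, pair_max_sep >= 1L)
  structure(list(src = src, dst = dst, n_structures = as.integer(n_structures),
                 contact_range = as.integer(contact_range),
                 hbond_jitter = as.integer(hbond_jitter),
                 contact_share = contact_share,
                 design = design, rates = rates,
                 pair_max_sep = as.integer(pair_max_sep),
                 max_pairs = as.integer(max_pairs),
                 mapping_index = as.integer(mapping_index),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Generate a family of synthetic stepping stones along a pathway
#'
#' Builds one move-by-move pathway between the endpoints, samples
#' `n_structures` evenly spaced steps (endpoints included), and realizes
#' each sampled secondary-structure string as a synthetic contact-map
#' structure with target contact counts swept across `contact_range` and a
#' seeded jitter on the hydrogen-bond count.
#'
#' @param cfg An [experiment_config()].
#' @return List of [ss_structure()] objects.
#' @export
make_stepping_stones <- function(cfg) {
  maps <- ss_pathways(cfg$src, cfg$dst)
  mapping <- maps[[cfg$mapping_index]]
  rng <- local_rng(cfg$seed)
  path <- NULL
  for (try in 1:20) {
    path <- tryCatch(
      ss_build_path(cfg$src, cfg$dst, mapping, seed = rng$derive_seed()),
      stepstone_path_error = function(e) NULL)
    if (!is.null(path)) break
  }
  if (is.null(path)) stop("could not realize a pathway in 20 attempts", call. = FALSE)
  n <- cfg$n_structures
  pick <- unique(round(seq(1L, length(path$steps), length.out = n)))
  # compactness varies across stones but not monotonically along the path:
  # neighbouring topologies are similar, but either member of a pair may be
  # the more compact one (descriptor differences span both signs)
  ncs <- round(seq(cfg$contact_range[1], cfg$contact_range[2],
                   length.out = length(pick)))
  ncs <- ncs[rng$sample_int(length(ncs), size = length(ncs))]
  stones <- vector("list", length(pick))
  for (k in seq_along(pick)) {
    ss <- path$steps[pick[k]]
    # extra H-bonds: baseline + symmetric jitter, kept non-negative by the
    # baseline shift so the pairwise dE_HB distribution is sign-symmetric
    jit <- if (cfg$hbond_jitter > 0)
      rng$sample_int(2L * cfg$hbond_jitter + 1L) - 1L else 0L
    sc <- ss_scaffold(ss)
    target <- max(nrow(normalize_contacts(sc$contacts, nchar(ss))), ncs[k])
    stones[[k]] <- synth_structure(
      ss, target_contacts = target, id = sprintf("stone_%02d", k - 1L),
      extra_hbonds = jit,
      parent = if (k > 1L) stones[[k - 1L]] else NULL,
      share = cfg$contact_share, seed = rng$derive_seed())
  }
  attr(stones, "path") <- path
  stones
}

experiment_pairs <- function(n, max_pairs, max_sep, rng) {
  all_pairs <- t(combn(n, 2L))
  sep <- all_pairs[, 2] - all_pairs[, 1]
  all_pairs <- all_pairs[sep <= max_sep, , drop = FALSE]
  sep <- sep[sep <= max_sep]
  consec <- all_pairs[sep == 1L, , drop = FALSE]
  rest <- all_pairs[sep > 1L, , drop = FALSE]
  if (nrow(consec) >= max_pairs) return(consec[seq_len(max_pairs), , drop = FALSE])
  extra <- min(max_pairs - nrow(consec), nrow(rest))
  if (extra > 0L) {
    pick <- rng$sample_int(nrow(rest), size = extra)
    rbind(consec, rest[pick, , drop = FALSE])
  } else consec
}

#' Run the full stepping-stone experiment
#'
#' Pipeline: stepping stones ([make_stepping_stones()]), designed islands
#' ([run_design()]), pairwise rate estimation in the biased joint ensemble
#' ([sample_joint()] + [estimate_rate_constants()]), analytic surface fit
#' ([fit_rate_surface()]) with the detailed-balance plane check, equilibrium
#' probabilities, and master-equation propagation from the source endpoint.
#' Deterministic given the config seed. With `out_dir` set, all tables are
#' written (structures JSON, islands FASTA/TSV, rate table TSV, parameters
#' JSON, trajectory TSV).
#'
#' @param cfg An [experiment_config()].
#' @param M Interaction matrix.
#' @param design_islands If `FALSE`, skip island design (the rate pipeline
#'   does not require it).
#' @param quiet Suppress per-stage progress messages.
#' @return List with `structures`, `islands`, `rates` (rate table),
#'   `surface` (fit), `plane` (consistency fit), `equilibrium`, `network`,
#'   `trajectory`, `R_ratio` (per-pair total-rate ratios), `config`.
#' @export
run_experiment <- function(cfg = experiment_config(),
                           M = default_interaction_matrix(),
                           design_islands = TRUE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  rng <- local_rng(cfg$seed + 1L)
  t0 <- proc.time()[3]
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("experiment stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("stage %-12s done (%.1f s)", name, proc.time()[3] - t0)
    out
  }

  stones <- stage("structures", make_stepping_stones(cfg))
  n <- length(stones)

  islands <- NULL
  if (design_islands) {
    islands <- stage("islands", lapply(stones, function(X) {
      dc <- cfg$design
      dc$rng_seed <- rng$derive_seed()
      run_design(X, M, dc)
    }))
  }

  pairs <- experiment_pairs(n, cfg$max_pairs, cfg$pair_max_sep, rng)
  rates <- stage("rates", {
    rows <- vector("list", nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      A <- stones[[pairs[r, 1]]]; B <- stones[[pairs[r, 2]]]
      rc <- cfg$rates
      rc$rng_seed <- rng$derive_seed()
      est <- estimate_rate_constants(sample_joint(A, B, M, rc), rc)
      ov <- common_contacts(A, B)
      rows[[r]] <- data.frame(
        A = A$id, B = B$id,
        k_AB = est$k_AB, k_BA = est$k_BA,
        se_AB = est$se_AB, se_BA = est$se_BA,
        dE_HB = B$e_hb - A$e_hb, dN_c = B$n_contacts - A$n_contacts,
        Q = ov$Q, q = ov$q,
        n_eff = min(est$n_effective), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  fit_q <- diff(range(rates$q[rates$k_AB > 0 | rates$k_BA > 0])) >= 0.05
  surface <- stage("fit", fit_rate_surface(rates, fit_q = fit_q))
  plane <- plane_fit_log_ratio(rates)
  equilibrium <- equilibrium_probabilities(stones, surface$params)

  # per-pair total-rate ratio R_AB/R_BA = (k_AB/k_BA) * (P_A/P_B)
  ok <- rates$k_AB > 0 & rates$k_BA > 0
  R_ratio <- (rates$k_AB[ok] / rates$k_BA[ok]) *
    (equilibrium[rates$A[ok]] / equilibrium[rates$B[ok]])

  network <- stage("markov", build_rate_matrix(stones, surface$params))
  tmax <- 10 / max(abs(diag(network$K)))
  times <- c(0, tmax * c(0.01, 0.1, 1, 10, 100))
  trajectory <- propagate(network, stones[[1]]$id, times)

  out <- list(structures = stones, islands = islands, rates = rates,
              surface = surface, plane = plane, equilibrium = equilibrium,
              network = network, trajectory = trajectory,
              R_ratio = unname(R_ratio), config = cfg)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (X in stones)
      write_structure_json(X, file.path(cfg$out_dir, paste0(X$id, ".json")))
    if (!is.null(islands)) {
      for (isl in islands)
        write_island(isl,
                     file.path(cfg$out_dir, paste0(isl$structure_id, ".fasta")),
                     file.path(cfg$out_dir, paste0(isl$structure_id, "_energies.tsv")))
    }
    write_rate_table(rates, file.path(cfg$out_dir, "rates.tsv"))
    jsonlite::write_json(
      list(params = unclass(surface$params), se = as.list(surface$se),
           residual_rms = surface$residual_rms,
           plane = plane[c("c_HB", "c_c", "r_squared")]),
      file.path(cfg$out_dir, "params.json"), auto_unbox = TRUE, digits = NA)
    write.table(data.frame(time = times, trajectory),
                file.path(cfg$out_dir, "trajectory.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Construct the bundled toy fixtures used by the test-suite oracles
#'
#' Three deterministic fixture sets, small enough for exhaustive
#' enumeration: `dominated` (a pair in which structure B is lower in energy
#' for every sequence, so the committor is constant and `k_AB = 1`,
#' `k_BA = 0`), `symmetric` (two structures that are mirror images in
#' descriptor space, so the two rates agree), and `network6` (six structures
#' whose fitted-family rates have the closed-form stationary distribution).
#'
#' @param seed Integer seed for the synthetic contact maps.
#' @return List with `dominated` (list of two structures), `symmetric`
#'   (list of two structures), `network6` (list: `structures`, `params`).
#' @export
make_fixtures <- function(seed = 1L) {
  L <- 8L
  dominated <- list(
    A = ss_structure("dom_A", L, NULL, n_hbonds = 0L),
    B = ss_structure("dom_B", L, NULL, n_hbonds = 3L))
  # mirror pair: contact (0,4) vs (3,7) -- same separation, same counts
  symmetric <- list(
    A = ss_structure("sym_A", L, matrix(c(0L, 4L), 1), n_hbonds = 1L),
    B = ss_structure("sym_B", L, matrix(c(3L, 7L), 1), n_hbonds = 1L))
  rng <- local_rng(seed)
  net_structs <- lapply(1:6, function(k) {
    nc <- 3L + k
    pool <- t(combn(0:(L - 1L), 2L))
    pool <- pool[pool[, 2] - pool[, 1] >= 3L, , drop = FALSE]
    pick <- rng$sample_int(nrow(pool), size = nc)
    ss_structure(sprintf("net_%d", k), L, pool[pick, , drop = FALSE],
                 n_hbonds = k)
  })
  params <- rate_surface_params(log_k_max = -0.5, alpha_HB = 0.8,
                                alpha_c = 0.3)
  list(dominated = dominated, symmetric = symmetric,
       network6 = list(structures = net_structs, params = params))
}
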