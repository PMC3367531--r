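---
title: "Markovian rates for protein structure evolution over stepping-stone networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markovian rates for protein structure evolution over stepping-stone networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepstone)
```

## The model

`stepstone` treats protein structural evolution as a continuous-time Markov
process over a finite set of protein-like structures ("stepping stones")
intermediate in topology between two endpoint folds. The package bundles the
two endpoints used throughout: the B1 domain of protein G (PDB 1PGB, a
four-stranded sheet packed against a single 15-residue helix) and chain X of
a SecM-stalled ribosome complex (PDB 2GYC, an alternating
strand--helix--strand--helix--strand topology), both represented at 56
residues.

Each structure carries a population ("island") of amino-acid sequences that
fold into it. The model's central assumption is a separation of time scales:
neutral drift *within* an island is fast, while jumps *between* islands are
rare events whose rate is controlled by how hard it is to find sequences
compatible with both structures at once. A jump's progress is summarized by
a committor: a sequence is committed to evolve from structure $A$ towards
structure $B$ as soon as its energy threaded on $B$ drops below its energy
threaded on $A$ (ties commit to neither side — the indicator is strictly
one-sided). This energetic committor stands in for an explicit
mutation-trajectory simulation, which the model deliberately avoids.

The rate constant is the source-ensemble average of the committor,
$k_{AB} = \langle \Lambda_{AB} \rangle_A$, where the $A$ ensemble weights
sequences by $\exp[-(E_A - E_R \ln N_\mathrm{perm})/T]$. Because sequences
committed to $B$ are exponentially rare in the $A$ ensemble, the package
samples a *biased joint ensemble* with weight
$\exp[-(E_A + E_B - E_R \ln N_\mathrm{perm})/T]$ — concentrated exactly on
the overlap region where the committor flips — and reweights back with
$w_B = e^{+E_B/T}$ (always in log space with a max shift):
$k_{AB} = \langle \Lambda_{AB}\, w_B \rangle / \langle w_B \rangle$.
An exhaustive enumeration oracle (`exact_rate_oracle()`) computes the same
averages exactly on toy alphabets and is the reference the Monte Carlo
estimator is tested against.

## Secondary-structure grammar and pathways

Stepping-stone topologies are generated at the level of secondary-structure
strings over `{H, E, C}` under a fixed grammar: helices of 4--15 residues,
strands of 2--8, at least one coil between elements, 20--45 structured
residues in total. Elementary edits lengthen or shorten an element by one
residue, insert a minimal element (`CHHHHC`, `CEEC`) into a coil window, or
delete a minimal element.

A *pathway* between two folds is labelled by an element correspondence:
an injective, type- and order-preserving partial matching between the
internal elements of the two endpoints, with the terminal strands keeping
their identities. Exhaustive enumeration for the bundled endpoints (internal
elements E,H,E against H,E,H) yields exactly 7 matchings; matched elements
persist and "move", unmatched source elements disappear, unmatched
destination elements are created.

`ss_build_path()` realizes a pathway as a move-by-move walk. Rule
"each move must bring the string closer to the destination" needs a metric;
we use the per-position *conversion cost* (coil to structured costs 1, H to
E costs 2, because the two structured states can only interconvert through
coil). Plain Hamming mismatch counting is provably unusable here: wherever
a strand must become a helix in place, the intermediate `E -> C` step leaves
the Hamming distance unchanged, so no strictly-decreasing path exists. Under
the conversion metric every legal move changes the distance by at least one,
greedy seeded walks terminate in at most the initial distance number of
steps, and the realized paths for the bundled endpoints take 43--48 moves.
Element "movement" is not a separate move type; it emerges as
shorten-on-one-side/lengthen-on-the-other composites. Ties among eligible
moves are broken uniformly at random under the caller's seed; a dead end
(possible, though rare, for adversarial intermediate states) raises a typed
error carrying the stuck string so the caller can retry with another seed.

## Structures, energies, and what the synthetic generator does and does not emulate

A stepping stone is a contact map plus a hydrogen-bond count: contacts are
residue pairs $(i, j)$ with $j - i \ge 3$ (Cα distance below 8 Å when
derived from coordinates, strict inequality), and the hydrogen-bond energy
is $E_{HB} = -\varepsilon_{HB} \cdot n_{HB}$ with $\varepsilon_{HB} = 1$ in
reduced units. The sequence--structure energy is a fixed-backbone contact
sum $E(S, X) = \sum_{(i,j)} \varepsilon[s_i, s_j] + E_{HB}(X)$ over a
pluggable symmetric 20×20 interaction matrix. The bundled default is built
from the published Kyte--Doolittle hydropathy scale as
$\varepsilon[a,b] = -0.1\,(h_a + h_b)$, the additive hydrophobicity-dominated
form that knowledge-based contact potentials are known to be well
approximated by; any matrix in the same text layout can be supplied.

`synth_structure()` realizes a secondary-structure string as a synthetic
contact map: helices of length $\ell$ contribute their $(i,i+3)$, $(i,i+4)$
local contacts and $\ell - 4$ hydrogen bonds; consecutive strands pair
antiparallel in chain order, one contact and one hydrogen bond per aligned
pair; remaining contacts up to the requested compactness $N_c$ are drawn
uniformly at random (seeded), optionally inherited from a parent structure
with probability `share` so that related stones share most of their
topology. The generator emulates the *descriptors* the rate theory consumes
— compactness, hydrogen-bond count, shared-contact fraction — and nothing
else: there is no backbone geometry, no torsions, no sheet-topology rules,
no refinement, and no refolding test of designed sequences. Consequently,
passing tests show that the rate theory behaves correctly *given*
structures with realistic descriptor statistics; they cannot show that any
particular real protein pair has a particular rate.

## Sequence design

`run_design()` samples sequences on a fixed target by single-site
substitutions over the full 20-letter alphabet with the acceptance rule
$\min\{1, \exp[-(\Delta E - E_R\,\Delta \ln N_\mathrm{perm})/T]\}$, where
$N_\mathrm{perm} = N!/(n_1! \cdots n_{20}!)$ is the multinomial permutation
count of the composition. The entropy term (scale $E_R$, default 3) opposes
the homopolymer collapse that pure energy minimization produces. Replica
exchange across a temperature ladder replaces the original
virtual-move parallel tempering scheme; both leave every replica's
stationary distribution unchanged, and standard replica exchange is far
simpler to verify — the test suite checks the sampled distribution against
exact Boltzmann enumeration on toy systems, both with and without exchange.
Defaults: 10% burn-in (the burn-in length is a free choice), one recorded
sequence per sweep, substitutions only (no indels). Per-site Shannon
entropies of an island, and a total-variation-style distance between
entropy histograms, support choosing the design temperature whose
variability matches a reference population; the reference is user-supplied
(for instance a natural-family alignment profile), since no external
alignment is bundled.

## The analytic rate surface

Measured rates are summarized by three descriptors per ordered pair:
$\Delta E_{HB} = E_{HB}^B - E_{HB}^A$, $\Delta N_c = N_c^B - N_c^A$, and the
symmetric shared-contact fraction $q = 2Q/(N_c^A + N_c^B)$. The fitted
family is a product of midpoint-0 logistic sigmoids,

$$\ln k_{AB} = \ln k_\mathrm{max}
  - \ln\!\left(1 + e^{\alpha_{HB} \Delta E_{HB}}\right)
  - \ln\!\left(1 + e^{-\alpha_c \Delta N_c}\right) + \ln G(q),$$

with $G(q) = g_s / (1 + e^{-\alpha_q (q - q_\mathrm{mid})})$ normalized so
$G(1) = 1$. The family is step-like and monotone — jumps towards structures
with more hydrogen bonds and more contacts are fast — and, because the
midpoints are pinned at zero and $G$ is symmetric in the pair, the log-ratio
factorizes *exactly*:
$\ln k_{AB} - \ln k_{BA} = -\alpha_{HB}\Delta E_{HB} + \alpha_c \Delta N_c$.
Detailed balance therefore holds identically with equilibrium probabilities
$P_X \propto \exp(-\alpha_{HB} E_{HB}^X + \alpha_c N_c^X)$ — the
designability statement: the probability of observing a structure grows
with its hydrogen-bond count and its compactness. Freeing the midpoints is
possible by fitting the `joint` method with modified code paths, but the
package deliberately keeps them pinned: the three properties above are the
point of the family.

Fitting (`fit_rate_surface()`) defaults to a *balance-first* two-stage
strategy: the alphas come from the weighted least-squares plane fit of the
paired log-ratios (for the family this difference is exactly linear, and
within-pair differencing cancels every pair-level nuisance factor,
including $G(q)$ and the identity of the differing contacts); the plateau
and $G(q)$ are then fit to the rate magnitudes with the alphas held fixed.
A one-stage `joint` fit is available and agrees on family-generated data,
but is less robust when pair-level scatter is large. Weights are inverse
variances on the log scale from the bootstrap errors, with a variance floor
of 0.01 so saturated estimates (standard error zero at $k = 0$ or $1$)
cannot dominate. The optimizer is box-constrained L-BFGS-B with a coarse
grid multi-start for $(\alpha_q, q_\mathrm{mid})$ and Hessian-based
standard errors; this replaced a Levenberg--Marquardt fit whose post-fit
model object fails when the logistic factor degenerates at a bound.

## Markov layer

`build_rate_matrix()` fills a generator matrix $K$ from the fitted family
($K_{AB}$ is the $A \to B$ rate in units of the mutation-rate prefactor
$\mu$, default 1, i.e. rates per mutation attempt; rows sum to zero).
The stationary distribution is a dense null-space solve and must agree with
the closed form above to $10^{-10}$ for family networks; the master
equation $p(t) = p_0 e^{Kt}$ is evaluated by `Matrix::expm()` (adequate to
a few thousand states; the bundled experiments use 6--12). Global-balance
and detailed-balance residuals of user-supplied rate tables are reported,
never silently repaired.

## The bundled experiment and its conditions

`run_experiment()` chains the whole pipeline at desk scale. The default
conditions are: 12 stepping stones sampled evenly along one realized
1PGB-to-2GYC pathway at 56 residues; compactness targets spread over
100--140 contacts and assigned to stones in seeded *shuffled* order, so
that either member of a pair may be the more compact one (descriptor
differences must span both signs for the sigmoids to be identifiable, and
real stepping-stone sets are not ordered by compactness); hydrogen-bond
counts jittered symmetrically by up to ±3 around a +3 baseline; 80% of
each stone's random contacts inherited from its predecessor, so the
shared-contact fraction decays smoothly with path separation (about 0.75
for neighbours) as it does across related folds; rates measured for all
pairs within path separation 2 (jumps between very dissimilar stones
saturate the committor and carry no information about the transition
region); 2×10⁴ recorded joint-ensemble samples per pair at selection
temperature $T = 2$ and $E_R = 3$. The selection temperature was chosen
once, on the grounds that the two-descriptor family should describe the
measured rates well under the study conditions (at $T = 1$ the committor
is nearly deterministic and log-rates sit in saturated tails dominated by
pair-level heterogeneity the descriptors do not see); it was not treated as
a tunable.

The test suite exercises this experiment at reduced depth (6 stones, 1500
samples per pair) for pipeline checks, and at the default depth pooled over
three replicates (≥ 60 measured pairs) for the total-rate-balance check,
where the median of $(k_{AB}/k_{BA}) (P_A/P_B)$ over pairs is required to
lie within [0.8, 1.25]. Toy oracle checks use 2-letter alphabets at chain
length 6--8, where exhaustive enumeration over at most $2^8$ sequences is
exact.

## Numerical choices and degenerate inputs

* Reduced units throughout, $k_B = 1$; natural logarithms everywhere.
* Committor ties ($E_A = E_B$) commit to neither direction.
* All reweighting in log space with max-shift; effective sample sizes below
  100 set a warning flag on the estimate rather than failing.
* Rate standard errors by block bootstrap (50 blocks, 200 replicates).
* The coil glyph is `'C'`; contact cutoff 8 Å with strict `<` and
  $j - i \ge 3$ (both configurable where coordinates are involved).
* Empty histogram bins have undefined free energy (`NA`), never infinities.
* A `--symmetrize`-style exchange-symmetric flux estimator is *not*
  provided: the total-rate equality is checked empirically (the ratio
  distribution above) rather than imposed, since the package does not
  re-derive the analytic equality proof.
* Degenerate fits fail loudly: sign-deficient descriptor spreads name the
  deficient axis; insufficient $q$ spread fixes $G \equiv 1$ with a
  warning; disconnected pair graphs list their components.

## Known limitations

The contact-energy surrogate preserves everything the rate theory uses
(energy differences driven by contact differences and the hydrogen-bond
term) but is not a transferable force field; absolute energies and
temperatures do not map onto experimental scales. Synthetic stepping stones
have no notion of sheet topology or chirality, so their contact maps are
optimistic about how freely compactness can vary at fixed secondary
structure. The committor is energetic only — it assumes equal native-state
entropy across stones. Rates are per mutation attempt; converting to real
time requires an external mutation rate. Fitted-parameter standard errors
treat pairs as independent, although pairs sharing a stone are correlated;
the total-rate-balance check absorbs this by pooling replicates.
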