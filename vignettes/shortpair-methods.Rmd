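---
title: "Paired-end mate rescue for short-read profile homology search: models and methods"
author: "shortpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-end mate rescue for short-read profile homology search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortpair)
```

## The problem

Profile HMM search assigns sequences to protein domain families with high
confidence when the query is a full-length gene. A 76-bp Illumina read
translates to roughly 25 amino acids; when that window falls on a poorly
conserved stretch of a domain, its bit score is marginal and the read is
dropped by any sensible reporting threshold. In paired-end data this failure
is asymmetric: very often one end of a pair aligns confidently while its
mate, sequenced from the same DNA fragment at most a few hundred bases away,
does not. `shortpair` exploits exactly that asymmetry.

The procedure has three steps:

1. **Scan.** Every read end is translated in all six frames and each frame
   is aligned locally to every family profile by Viterbi. Per end and
   family the best frame is kept; a hit is reported when its bit score is
   positive and its E-value is at most 10. The permissive cutoff is
   deliberate: it recruits as many candidate alignments as possible, and
   false families are removed later by the posterior.
2. **Rescue.** For every pair with exactly one aligned end, the missing
   mate is re-aligned by full (unfiltered) Viterbi against *only* the
   families hit by its anchor. Any positive-bit-score alignment is
   admitted, with no E-value gate. This mirrors running the search in its
   most sensitive mode, but against a handful of families instead of the
   whole database, so it stays cheap.
3. **Rank.** For each family $M$ with alignments $a_1, a_2$ on both ends of
   a pair, the candidate is scored by

   $$\Pr(a_1, a_2 \mid r_1, r_2) \;\propto\; e^{s_{a_1}/T}\, e^{s_{a_2}/T}\,
     \Pr(f_{r_1,r_2}),$$

   where $s_{a_1}, s_{a_2}$ are the two bit scores, $f_{r_1,r_2}$ is the
   fragment length implied by the two alignments, and $\Pr(f)$ its
   probability under a fragment-length distribution estimated from the data
   themselves. Posteriors are normalised over the pair's whole candidate
   set, and every candidate with posterior at least $\tau \cdot p_{\max}$
   is retained ($\tau = 0.40$ by default). Pairs are then classified:
   case 2 when at least one candidate survives, case 1 when only one end
   has alignments (or the ends share no family), case 3 when nothing
   aligned.

## The reference-free fragment-length distribution

Insert-size distributions are normally estimated by mapping pairs to a
reference genome. For metagenomes and non-model transcriptomes there is no
reference, so the package estimates the distribution from the profile
alignments alone. For every pair whose two ends each align to exactly one
family — the same family — the outer span of the two alignments in model
coordinates is mapped through the family's seed alignment onto *each* seed
sequence: model position → alignment column (via the profile's match-state
map) → residue position (counting that row's non-gap characters). The
per-seed span lengths are averaged, because it is unknown which seed is
closest to the gene the fragment came from. Pooling these per-pair
estimates at 1-amino-acid resolution, adding a pseudo-count mass
(`smoothing`, default 1, spread uniformly across the support) and
normalising gives the distribution; lengths never observed return the
empty-bin "floor" probability, never zero, so the posterior's product form
is always well defined.

Two conventions needed fixing where the construction is under-determined:

* **Outer span, not inner gap.** The "distance between the two alignments"
  is realised as the outer footprint (min start to max end, end − start + 1),
  i.e. the aligned extent of the fragment in protein space, which is the
  quantity whose distribution the read geometry actually induces. This
  choice is fixed; changing it would silently shift every estimate by
  roughly twice the read length.
* **Rounding.** Per-pair averages over seeds are rounded half-up
  (`floor(x + 0.5)`), so the two-seed example of distances 50 and 55
  yields 53. Histogram bins need integers and the rule must be
  deterministic and direction-stable.

Pairs whose estimate falls outside a user-supplied nucleotide fragment
range (divided by 3) are dropped as outliers before the histogram is built;
by default no clipping is applied. The distribution is built from step-1
unique pairs only — rescued alignments are exactly the lower-confidence
ones, so feeding them back into the estimator would contaminate it.

## Scoring conventions and numerical choices

* **Bit scores.** The aligner reports $\log_2$ likelihood ratios of the
  Viterbi path against an i.i.d. background null. Entry into the local
  alignment is uniform over the $L$ match states (cost $\log_2 1/L$); exit
  after any match state is free. Stop codons (`*`) emit with probability
  zero, so an alignment can never cross an in-frame stop — a read
  straddling a UTR or intergenic boundary aligns on one side only.
  Ambiguity translations (`X`) emit the background and score zero bits.
* **The scaling factor $T$.** The posterior uses $T = 1/\ln 2$, so
  $e^{s/T} = 2^{s}$: a bit score enters as exactly the model-vs-null odds
  it encodes, and a 1-bit score difference doubles a candidate's weight.
  $T$ is configurable for users who want a softer or sharper ranking.
* **Log-space normalisation.** Candidate weights are combined as
  $\log w = (s_1 + s_2)/T + \ln \Pr(f)$ and normalised by a shifted
  softmax, so 5000-bit scores do not overflow.
* **E-values.** $E = Z e^{-\lambda (s - \mu)}$, clipped to $[0, Z]$, with
  Gumbel parameters taken from a profile's STATS line when one is present
  and otherwise fitted by maximum likelihood to the Viterbi scores of
  `calibrate_n` (default 500) background-sampled peptides of read-peptide
  length (default 25 aa). The search size $Z$ follows the usual
  profile-search convention — the number of targets scanned per model —
  which here is the six frame translations of both ends of every pair,
  $12 n_{\text{pairs}}$. (Defining $Z$ from the number of *models* instead
  would make $E \le 10$ vacuous for a small family panel: with five
  families it corresponds to a per-comparison p-value of $1/3$, and decoy
  hits would flood the scan.)
* **Retention rule.** "Above $p_{\max}\tau$" is implemented non-strictly
  ($\ge$), so the rule is stable under ties and the argmax is always
  retained. Retained candidates are sorted by posterior, ties broken by
  family id and then end-1 model start, which makes output files
  byte-reproducible.
* **Degenerate inputs.** Empty candidate sets, empty truth sets in the
  sensitivity denominator, universes with no true negatives, alignments
  with no anchoring seed residue, and empty read files all raise immediate
  errors (or, for the empty read file, an empty result with a warning)
  rather than propagating NaNs.

One modelling question the source material leaves open is whether the
scores feeding the posterior are Viterbi or Forward scores; this package
uses Viterbi bits, consistent with rescuing by "the full Viterbi
algorithm", and the difference only sharpens or softens the ranking, since
Forward scores dominate Viterbi scores monotonically in practice.

## Profile construction

Profiles are either read from HMMER3/f ASCII files (including MAP and
STATS lines) or built from seed alignments: match columns are those marked
in a `#=GC RF` line when present, otherwise columns with gap fraction
below 0.5; emissions are Laplace-smoothed counts ($+1$ per residue);
transition bundles are counted from each row's observed match/insert/delete
path and smoothed the same way. The background is uniform ($1/20$) unless
a profile file supplies a COMPO line. Laplace smoothing is intentionally
mild: with typical seed counts (tens of rows) it neither washes out
conserved columns nor zeroes unobserved residues. The match-state-to-column
map is retained on the object because fragment-length estimation needs it;
profiles built from files without their seed alignment fall back to
measuring fragments in model coordinates directly.

## What the simulator emulates — and what it does not

`simulate_scenario()` describes a family panel and a library;
`simulate_dataset()` realises it. An ancestor protein is drawn uniformly;
seeds diverge from it by i.i.d. substitutions (uniform over the 19
alternative residues) at `divergence`, with per-site deletions and private
insertion columns at `indel_rate`; a held-out member gene diverges at
`member_divergence` and is back-translated with uniform synonymous codon
choice. Fragments are drawn in amino acids from a truncated normal, placed
uniformly on the gene; end 1 reads the first `read_length_nt` bases, end 2
the reverse complement of the last, and both acquire substitution errors at
`error_rate`. Optionally a fraction `mate_divergence_rate` of pairs has the
protein under the end-2 window further mutated at `mate_divergence`,
emulating a mate on a poorly conserved stretch — the situation mate rescue
exists for. Everything is deterministic given `rng_seed`, and the truth
table records source family, true fragment length and the diverged flag
for every pair.

Defaults are chosen to mimic a short-read RNA-Seq library: 76-bp reads,
fragments of 66–267 amino acids (198–801 bp) with mean 150 aa and sd 15,
five families of length 300 aa trained from 10 seeds at 30% divergence,
1000 pairs. The uniform substitution model is deliberately simple: its mean
pairwise seed identity has the closed form $(1-p)^2 + p^2/19$, which the
test suite checks, and analytic expectations matter more here than
biological realism. The simulator does **not** model position-dependent
conservation, realistic codon usage, amino-acid exchangeability
(PAM/BLOSUM-like neighbourhoods), quality-score profiles, or indel
sequencing errors. Consequently, passing tests demonstrate that the
machinery is correct and that the method behaves as designed under its own
assumptions — not that its accuracy numbers transfer to real Pfam families,
whose conservation structure is far less homogeneous.

## Problem sizes used by the shipped studies

The test-suite and acceptance studies run at sizes chosen to give stable
statistics: the Viterbi aligner is verified exactly against exhaustive path
enumeration on 100 random instances with $L \le 6$ and peptides up to 6
residues; posterior arithmetic against a plain-product oracle on 1000
random candidate sets; fragment-length recovery on a 10,000-pair
single-family library (indel-free, truncated normal 150 ± 15 aa), where the
estimated distribution is required to track the sampled truth within 0.02
per length and 1 aa in the mean; mate rescue on 500 pairs with 30% of mates
at 40% residual identity; and end-to-end determinism on the standard
1000-pair scenario. `scripts/acceptance.R` re-runs the same three studies
from scratch and reports the measured quantities.

## Known limitations

* The aligner is a minimal Plan7-style local Viterbi: no Forward/posterior
  decoding, no multi-hit architecture, no bias filters, no
  Dirichlet-mixture priors. It is the method's hermetic stand-in for an
  external search engine, and per-end results from real HMMER runs can be
  substituted via `parse_domtblout()`.
* A single global fragment-length distribution is estimated, not
  per-family distributions; libraries with strongly family-dependent
  fragment sizes would violate the model.
* Pairs whose two ends align only to disjoint families are reported as
  case 1 (single-end evidence, E-value ranked); the posterior is defined
  only when both ends support one family.
* The fragment distribution is estimated once, before rescue, in a single
  pass; no iterative refinement is attempted.
* Frameshift (indel) sequencing errors are out of scope throughout — the
  target platform is substitution-dominated short-read data.
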