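---
title: "Codon-level selection analysis: model, methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-level selection analysis: model, methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felscan)
```

## The question and the quantities

For a family of protein-coding orthologs — the motivating case is vertebrate
small heat shock proteins (sHSPs), whose N-terminal region (NTR), central
region (CeR), α-crystallin domain (αCD) and C-terminal extension (CTE) are
expected to evolve under very different constraints — we want to know, codon
by codon and region by region, how strong purifying selection has been. The
standard currency is ω = β/α, the ratio of the nonsynonymous substitution
rate β to the synonymous rate α: ω < 1 indicates purifying selection, ω ≈ 1
neutral evolution, ω > 1 positive (diversifying) selection.

`felscan` implements the full path from candidate sequences to those
estimates:

1. **Curation** — pairwise global protein alignment against a reference
   (human) ortholog with identity/similarity thresholds, trimming of
   spurious N-terminal extensions back to the canonical start, and
   ortholog-group assignment by tree clustering against a paralog panel.
2. **Global model fit** — an MG94xREV codon model fit to the whole
   alignment (exchangeabilities, one alignment-wide ω, branch lengths).
3. **Site-level FEL scan** — per-codon (α, β) maximum likelihood with the
   global fit's nuisance parameters held fixed, a 1-df likelihood-ratio
   test against α = β, and profile-likelihood intervals for ω.
4. **Partition-level aggregates** — a single ω̄ per region/exon/full-length
   partition, pairwise 1-df LRT comparisons, and Hasse diagrams of the
   significant partial order.
5. **Simulation** — a forward codon simulator with site-specific (α, β)
   profiles, providing ground truth for every claim the tests make.

## The substitution model

The MG94xREV generator acts on the 61 sense codons. Codons differing at more
than one nucleotide position have rate 0. For a single-nucleotide change
x→y at codon position k,

    q_ij = r(x,y) · π_k(y) · (ω if the amino acid changes, else 1)

where r(x,y) are the six symmetric nucleotide exchangeabilities (GT fixed at
1 for identifiability) and π_k(y) is the equilibrium frequency of nucleotide
y at codon position k. Codon equilibrium frequencies are formed by the F3x4
product rule from empirical position-specific nucleotide counts (the
customary default for this model family; per-position frequencies are
floored at 1e-4 so no sense codon becomes unreachable). The generator is
normalized so one unit of branch length is one expected substitution per
codon site at the supplied parameters; branch lengths of input trees are
always *refit* under the codon model rather than rescaled, which removes
any dependence on the units of the upstream tree program.

Writing the generator as Q = S + ωN with S and N the synonymous and
nonsynonymous components, the per-site FEL generator is αS + βN. Since
αS + βN = α(S + ωN) with ω = β/α, one symmetric eigendecomposition of
S + ωN serves every α — the package's central computational trick. Because
the model is time-reversible, P(t) = exp(Qt) is computed exactly through the
similarity transform D^{1/2} Q D^{-1/2} (D = diag(π)); this is both faster
and more robust here than generic matrix exponentials and is cross-checked
against `Matrix::expm` in the test suite. Tiny negative entries from
round-off are clipped to zero. Likelihoods use Felsenstein pruning
(RcppArmadillo) with per-node rescaling; gap- or ambiguity-containing codons
are missing data and marginalize out; in-frame stops are an error unless
explicitly masked.

## Site-level FEL

For each codon with a homologous site in the reference row (columns where
the reference is gapped are dropped from all site reports), the alternative
model maximizes over (α, β); the null constrains α = β. The LRT statistic
2(logL_alt − logL_null) is referred to the asymptotic χ²₁ distribution —
deliberately *not* a boundary mixture, following the method as published.
Classes at the p ≤ 0.1 default: `purifying` (ω < 1), `diversifying`
(ω > 1), `neutral` otherwise. No multiple-testing correction is applied
across sites, again following the published method.

Boundary bookkeeping matters in real alignments: a strictly invariant
column (the initiator methionine, internal Met/Trp) yields α̂ = β̂ = 0 and an
*undefined* ω (0/0); a column with amino-acid variation but no synonymous
variation yields the *infinite* status (β/0). Rates below 1e-8 are treated
as 0 for status determination (optimizer boundary noise). Undefined sites
are excluded from every aggregate fit downstream, and the exclusion is
reconciled by count in the tests.

The 95% profile interval for ω contains every ω whose profile
log-likelihood (re-optimizing the overall site rate along the ω ray) is
within χ²₁(0.95)/2 of the maximum. The lower bound floors at 0; the upper
search is capped at ω = 10⁴ and reported as +∞ beyond it. The profile
direction — constrain ω, re-optimize the common scale α — is one of several
defensible readings of a profile CI for a ratio; it was chosen because it
makes a single-site "aggregate" fit collapse exactly onto the site's FEL
estimate, so site-level and partition-level machinery share one engine and
cannot drift apart.

## Partition-level aggregates and comparisons

A partition's aggregate ω̄ maximizes the summed profile likelihood of its
usable sites under one shared ω, with each site's synonymous rate profiled
out and all global nuisance parameters fixed. Comparisons between two
partitions (or two genes) are 1-df LRTs: the null enforces a single shared
ω̄, the alternative estimates them separately. Cross-gene comparisons
concatenate the two genes' site likelihoods, each with its own fixed tree
and frequencies, sharing only ω̄ under the null — the minimal common
parameter, since the genes have different taxa and trees. Identical site
sets are a supported degenerate case (LRT exactly 0); partially overlapping
partitions of one alignment are an input error.

Significant pairs (α = 0.05 by default — configurable, since the original
analysis never quantifies its confidence level) become directed edges
pointing toward the *larger* ω̄, i.e. toward less stringent purifying
selection; transitive reduction then yields the Hasse diagram. Because
every edge ascends in ω̄, the diagram is acyclic by construction; no
multiple-testing correction is applied across pairs (matching the source
method; a Holm adjustment can be applied externally to the comparison
table).

## Curation rules

Candidates are globally aligned to the reference with BLOSUM62, gap open
10, gap extend 0.5 per residue, end gaps penalized — the documented defaults
of the classical global aligner used for this screening step; the original
report names the tool but not its parameters, so these are recorded here as
the package's choice and are configurable. Percent identity counts
identical residue pairs over *all* alignment columns including gaps, and
percent similarity counts positive-scoring pairs over the same denominator,
matching that aligner's reporting convention. `X` scores 0 against
everything and never counts as identical. Inclusion requires identity ≥ 50
and similarity ≥ 60 (boundary inclusive; identity is checked first when
reporting the exclusion reason).

Ortholog-group assignment builds a neighbor-joining tree on
(1 − identity/100) distances over the paralog panel plus the query — a
deterministic, dependency-free stand-in for progressive-MSA guide trees
with the same clustering intent — and assigns the family of the query's
sister group if that group is family-pure; ties and mixed sister groups
exclude the candidate as `non_ortholog`, which is how ambiguous clustering
("discarded" in the source protocol) is interpreted here. N-terminal
residues aligned upstream of the reference's first residue are trimmed (the
canonical-start rule); a non-Met first retained residue warns but keeps the
sequence.

One caveat established by the tests: identity/similarity percentages are
exactly symmetric under swapping the two sequences for homologous pairs,
but for essentially unrelated sequences co-optimal alignments of different
lengths can change the gap-inclusive denominator. Curation decisions are
made in the homologous regime, where the convention is stable.

## The simulator, and what passing tests do and do not show

`simulate_codon_alignment` evolves root codons drawn from the equilibrium
distribution along a tree, sampling each branch endpoint directly from
P(t) — no event-level simulation, which is faster and exactly consistent
with the likelihood being tested. Site profiles are piecewise-constant ω
blocks with α = 1, optionally with a pinned invariant ATG at site 1 and
planted ω > 1 sites. Defaults chosen once as desk-scale stand-ins for the
study conditions: 64 taxa (large taxon counts are what give site-level
methods their power; the motivating datasets have 130–152 species), total
tree length 6 expected substitutions per codon site, transition-biased
exchangeabilities (AG = CT = 4, others 1), uniform position frequencies.
Several tests run smaller (12–24 taxa, 40–300 codons) to keep the default
suite fast; the acceptance script uses 24 taxa × 160 codons for the
end-to-end study, 12 × 200 for null calibration, and 16 × 100 for interval
coverage.

The simulator emulates site-specific selection intensity on a known tree.
It does **not** emulate indels (alignments are gapless; gap handling is
exercised by masking), alignment error, recombination, synonymous-rate
variation across sites, or lineage-specific (episodic) selection. Passing
tests therefore demonstrate the estimator's correctness and calibration
under its own model class at realistic scale — not robustness to the ways
real ortholog sets violate that model.

`make_curation_fixture` engineers mutants at requested identity/similarity
percentages using conservative (positive BLOSUM62 score) versus radical
(negative score) substitutions; cysteine, glycine and proline are excluded
from the random reference because BLOSUM62 offers them no positive-scoring
substitute, which would make exact similarity targets unreachable.

## Numerical choices

* Optimization: L-BFGS-B on log-scale parameters for the exchangeabilities
  and ω (bounds 1e-6..100), Brent for branch lengths (0..25) and for all
  one-dimensional profiles; global fit alternates rate and branch steps
  until |ΔlogL| < 1e-6 (the stage trace is retained and must be monotone).
  Branch sweeps use cached edge partials and fall back to sequential
  refits if a simultaneous sweep ever fails to improve the likelihood.
* FEL per site: the interior fit is a nested profile (outer Brent over
  log ω, inner Brent over log α), compared against the three boundary
  candidates ω = 0, ω = ∞, and the zero-rate corner; interval bounds by
  bisection on log ω, tolerance 1e-4.
* Boundary preference: when the zero-rate likelihood ties the interior
  optimum within 1e-9, the boundary wins, so invariant columns land exactly
  on the undefined status instead of drifting on optimizer noise.
* Serialization: rates at 6 significant digits, p-values in scientific
  notation with 3 digits, `inf` and `NA` spelled literally — reruns on
  identical inputs are byte-identical, which the tests assert.

## A worked example

```{r example, eval = FALSE}
prof <- make_site_profile(c("1-20" = 0.1, "21-40" = 0.8), 40,
                          invariant_start_met = TRUE)
sim <- simulate_codon_alignment(prof, n_taxa = 12, seed = 13, tree_length = 4)
fit <- fit_global_model(sim$alignment, sim$tree)
scan <- fel_scan(sim$alignment, fit)
summarize_classes(scan)
low  <- fit_aggregate_omega(sim$alignment, fit, partition("core", 2:20))
high <- fit_aggregate_omega(sim$alignment, fit, partition("tail", 21:40))
compare_aggregate(low, high)
```

## Known limitations

* Synonymous rate variation is profiled per site but not smoothed or
  shared; no episodic/branch-site models; no automatic inference of
  partition boundaries from the ω profile (boundaries are config input).
* The χ²₁ reference for boundary null hypotheses is conservative; the
  package follows the published method rather than a boundary mixture.
* The NJ fallback tree is a convenience, not a substitute for a proper
  maximum-likelihood tree when one is available.
* Aggregate ω̄ assumes the global branch lengths and frequencies fit the
  partition; per-partition branch-length refits are out of scope.
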