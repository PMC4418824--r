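---
title: "Methods: coevolution and phylogeny-trait association in a ligand-receptor system"
author: "oxtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coevolution and phylogeny-trait association in a ligand-receptor system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxtkit)
```

`oxtkit` studies genetic diversity in a neuropeptide hormone and its G
protein-coupled receptor across a clade, modelled on the oxytocin (OXT) /
oxytocin-receptor (OXTR) system in primates.  New World monkeys are unusual
among mammals in carrying several structurally distinct OXT nonapeptides
(the consensus mammalian Leu8 form plus Pro8, Ala8, Thr8 and Phe2
variants), and in expressing social monogamy at a high rate.  The package
asks two statistical questions about such a system: do the ligand and the
receptor coevolve, and does receptor phylogeny associate with a social
trait?  Around those two tests it provides the supporting machinery —
distance matrices, tree handling, peptide physicochemistry, substitution
classification — and a simulator that generates data with the same
statistical structure, so every stage is testable without downloads.

## Evolutionary distances

Pairwise distances between coding sequences are computed under the
standard nucleotide corrections:

* **p-distance**: the raw proportion of differing sites.
* **JC69**: $d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$.
* **K2P**: $d = -\tfrac{1}{2}\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$, separating
  transition ($P$) and transversion ($Q$) proportions.
* **Tamura 3-parameter (T92)**: $d = -h\ln(1-P/h-Q) -
  \tfrac12(1-h)\ln(1-2Q)$ with $h = 2\theta(1-\theta)$, $\theta$ the mean
  GC content of the pair over comparable sites.  With $\theta = 0.5$ it
  reduces exactly to K2P.

Each correction accepts an optional gamma shape parameter $\alpha$ for
rate heterogeneity across sites, replacing every $-\ln w$ by
$\alpha(w^{-1/\alpha}-1)$.  Gap and `N` positions are excluded per pair
(pairwise deletion, the common default of distance software), with
complete deletion available.  Two numerical policies matter downstream:

* **Saturated pairs are errors, not infinities.**  The matrix correlation
  stage requires finite values in every cell, so a pair with
  $p \ge 0.75$ (or the K2P/T92 analogues) aborts with a message naming the
  pair rather than propagating `NaN`.
* **Invariant-site mixtures are not supported.**  Likelihood analyses
  sometimes add a proportion-of-invariant-sites component to the model;
  there is no standard closed-form pairwise analogue, so the distance
  module offers gamma heterogeneity only.  This is a documented limitation.

The T92 GC fraction is computed over the pairwise-deleted sites of each
pair.  Other implementations use each sequence's own non-gap sites; the
conventions agree exactly on gap-free alignments and to about $10^{-3}$
under light gapping.

## Mirror-tree coevolution

Coevolution between ligand and receptor is quantified as the Pearson
correlation $r$ between the upper triangles of their two distance
matrices, paired over the shared taxa, together with the ordinary
least-squares slope and intercept.  Two significance measures are
reported:

* a **parametric p-value** from the $t$-distribution with
  $\binom{m}{2} - 2$ degrees of freedom, which treats the pairs as
  independent observations;
* a **Mantel permutation p-value**, in which each replicate jointly
  permutes the row and column labels of the second matrix and recomputes
  $r$, with the add-one convention $p = (1 + \#\{|r^\ast| \ge |r|\}) /
  (1 + B)$.

The off-diagonal entries of a distance matrix are not independent — each
taxon contributes to $m - 1$ of them — so the parametric p-value is
anticonservative and is reported only for comparability with analyses
that used it.  The permutation p-value is the headline number.  The
permutation must relabel taxa (rows and columns together), never
individual cells; cell-wise shuffling destroys the metric structure of
the matrix and produces a meaningless null.  The test is two-sided by
default, with one-sided options.

No correction is made for shared phylogenetic background (for example,
projecting a species-tree distance matrix out of both matrices before
correlating).  All primate genes share the species history, so part of
any observed correlation reflects that common signal; the test as
implemented matches the classical mirror-tree formulation, and the
extension is noted as future work.

## The MC phylogeny-trait statistic

For a rooted tree, a tip-to-state assignment, and a state $s$, the
monophyletic-clade statistic $\mathrm{MC}(s)$ is the size of the largest
clade — the descendant tip set of some node, leaves included — whose tips
all carry $s$.  Singleton leaves count as clades of size 1, so
$\mathrm{MC} \ge 1$ whenever the state is present, and branch lengths
never enter: it is a topology-only statistic.  Basal polytomies are
treated as hard; unrooted binary trees with branch lengths are
midpoint-rooted with a warning, since monophyly is undefined without a
root.

Phylogenetic uncertainty is handled by averaging over a tree sample
(Bayesian posterior, bootstrap sample, or the package's pseudo-posterior):
the observed statistic is the mean of $\mathrm{MC}$ across the sample,
with a central 95% quantile interval.  The null distribution is obtained
by shuffling the tip-to-state assignment uniformly (state counts
preserved); each replicate's shuffle is evaluated on the full tree sample
and summarised by its mean (an option evaluates each replicate on a
single tree drawn from the sample).  The test is one-sided — only a
higher-than-expected MC indicates phylogeny-trait association — and uses
the add-one convention, so $p$ is never exactly zero.  The expected MC is
the mean of the replicate means by default, with a median option, since
either summary is defensible.

Implementation note: MC for one trait vector is a single postorder
accumulation of per-clade state counts, and all null replicates for a
tree are evaluated together as one matrix accumulation over the edges,
which keeps 1,000 replicates over tens of trees fast.  An independent
brute-force implementation (naive reachability enumeration of every
node's tip set) ships in the package and is tested for exact agreement on
hundreds of random trees.

Only the MC statistic is implemented; the related association index and
parsimony-score statistics from the same family are out of scope.

## Peptide physicochemistry

* **GRAVY** is the mean Kyte–Doolittle hydropathy over residues; more
  negative means more hydrophilic.  For the consensus nonapeptide
  `CYIQNCPLG` the hand-summed value is $3.0/9 \approx 0.333$, and the
  Pro8 variant is markedly more hydrophilic ($-0.267$).
* **Net charge at a pH** is the Henderson–Hasselbalch sum over the
  N-terminus and K/R/H (positive) and the C-terminus and D/E/C/Y
  (negative).
* **pI** is found by bisection of the net-charge function on $(0, 14)$ to
  a default width of 0.001 pH units; monotonicity of the charge in pH
  guarantees the crossing, and the result satisfies
  $|\mathrm{charge}(\mathrm{pI})| < 0.01$.

The default pKa set is the Bjellqvist table used by the ExPASy ProtParam
tool, including its residue-specific terminal pKa values; the EMBOSS set
ships as an alternative, and both are editable CSV data, because pI
values are only comparable within one pKa convention.  Peptides are
treated as linear with free termini.  The biological oxytocin ligand is
cyclic (a 1–6 disulfide) and C-terminally amidated, which shifts its true
charge behaviour; the computed values follow the ProtParam convention so
they are comparable with that tool's output, and within-package contrasts
between variants are unaffected.  The reference pH for the net-charge
annotation is 7.3, approximating brain tissue; a pI below 7.3 means a net
negative charge there.  Position-8 variants (Leu/Pro/Ala/Thr) exchange
non-ionizable residues and therefore share one pI exactly; the Phe2
variant removes an ionizable tyrosine, so its pI can differ slightly —
whether published identical-pI statements were computed with tyrosine
ionization active is not resolvable from the outside, and the package
simply computes both.

## Radical and conservative substitutions

A replacement is **radical** if it changes at least one of three
categories — polarity (polar/nonpolar), charge
(positive/negative/neutral), or an ordinal side-chain volume class — and
**conservative** if it changes none.  The category table is data, not
code: the default ships as a CSV with charge positive $\{K,R,H\}$ and
negative $\{D,E\}$, polarity polar $\{R,N,D,C,Q,E,H,K,S,T,Y\}$, and five
volume classes cut from Zamyatnin side-chain volumes at 90, 120, 145 and
170 Å³.  Under this table the ligand-variant substitutions L→P, L→A, L→T
and Y→F are all radical, I→L is conservative, verdicts are symmetric, and
all 190 unordered residue pairs receive a verdict.

Substitutions are called per alignment column against a designated
reference sequence (the human receptor in the motivating analysis);
columns with a gap or `X` in either sequence are skipped and counted
separately.  Per-domain substitution proportions divide the number of
substituted columns in a domain by the domain length (an option divides
by the total substitution count instead, since figures in the literature
are not always explicit about the denominator).  Domain boundaries are
user-supplied CSV intervals; the shipped default receptor topology
(N-terminus of 38 residues, seven transmembrane helices, three loops on
each side, C-terminus, over a 389-residue receptor) is an approximate
reconstruction of the common annotation of the human receptor, because
exact boundary residues for published figures are not available — any
quantitative comparison should substitute the annotation actually used.
Group comparisons of per-species proportions use the unequal-variance
Welch $t$-test; the pooled-variance test is a special case the data
rarely justify.

Sequences are assumed pre-aligned to the reference.  Receptor coding
regions in the motivating system are length-conserved, so the package
does not bundle an aligner; alignment quality is the caller's
responsibility.

## The simulator and what passing tests mean

The generator produces data with the statistical structure the analyses
assume:

* **Trees** under a pure-birth (Yule) process — two lineages from the
  root, exponential waiting times, a uniformly chosen lineage splitting,
  one final interval after the $n$-th lineage.  Tip labels are assigned
  uniformly at random, because Yule labels are exchangeable; labelling by
  creation order would leak depth structure into the labels and bias
  independence tests.  A birth–death process adds nothing needed for
  these tests, so extinction is omitted.
* **Sequences** by a site-independent continuous-time Markov chain (JC69,
  K2P or T92) with the root drawn from the stationary distribution and
  exact matrix-exponential transition probabilities per branch — no
  discretisation error enters the calibration tests.
* **Binary traits** by a two-state chain with separate forward and
  backward rates; low rates give strong phylogenetic signal, high rates
  approach independent coin flips.  The simulated root state is recorded
  so a power study can identify the derived state.
* **Tree samples** by neighbor joining on column-resampled alignments, a
  bootstrap stand-in for a Bayesian posterior.

Every generator is a pure function of its seed, and composite simulators
fan a single root seed out to per-stage sub-seeds so stages can be re-run
independently.  Defaults (20 taxa; ligand 300 and receptor 1,200 sites;
substitution-rate multiplier 0.1) give pairwise divergences in the range
typical of primate coding genes, comfortably below saturation.

The test suite validates, at fixed problem sizes chosen to keep the full
run around two minutes:

* **MC oracle equivalence** on 500 random 5–12-tip trees.
* **MC null calibration**: 200 random traits on a deliberately diffuse
  pseudo-posterior (50 bootstrap trees from a 60-site alignment, 16
  taxa), with 1,000 null replicates each; the p-values are checked for
  uniformity.  Diffuseness matters: on a near-degenerate tree sample the
  integer-valued MC makes the permutation p-value strongly discrete and
  conservative (valid, but far from uniform).  The motivating use case —
  posteriors with weakly supported internal nodes — is the diffuse
  regime.
* **MC power**: traits simulated at rates 0.025/0.025 on 16-tip trees
  (about 0.4 expected transitions, i.e. a trait that arose roughly once),
  conditioned on the derived state being carried by at least three tips
  — a monomorphic or near-monomorphic trait carries no testable
  association — and tested over 10 bootstrap trees from a 1,170-site
  alignment (the receptor coding length).  Rejection at $\alpha = 0.05$
  exceeds 80%.
* **Mirror-tree calibration**: on 200 independent-tree pairs the
  permutation test rejects at the nominal 5% rate (within binomial
  error); on shared-tree pairs the mean $r$ exceeds 0.5 and dominates the
  independent-tree distribution.
* **Distance exactness** against independently written closed forms, and
  5% recovery of a simulated divergence; **NJ exactness** on additive
  matrices.

Passing these tests shows the statistics are implemented correctly and
calibrated *under the generator's assumptions*: site-independent
substitution, no rate variation across sites unless requested, no
indels, clock-like trees, a binary trait evolving independently of the
sequences.  Real data violate several of these (alignment error,
selection, rate variation, correlated traits), so passing tests do not by
themselves certify conclusions about any particular empirical dataset.

## Reproducing a published-style analysis

`run_full_pipeline()` chains the stages on user data: ligand and receptor
FASTA, a tree-sample file (Newick or NEXUS with burn-in fraction), a
taxon-to-state CSV, a domain CSV and a reference taxon.  Exact
reproduction of published numbers for the motivating system additionally
requires the original sequence accessions, the (unstated) distance model
behind the published matrices, the posterior tree sample, and the exact
domain boundaries; the pipeline therefore records every choice (model,
seeds, replicate counts, input hashes) in a run manifest, and the bundled
22-species ligand set and genus-level trait table are clearly-labelled
synthetic stand-ins that match the published counts (22 species, 17
genera, five variants) rather than the unpublished originals.
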