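---
title: "Genetics-first phenotype outlier prediction: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetics-first phenotype outlier prediction: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genofirst)
```

## The problem

Conventional human genetics starts from a phenotype and asks which variants
associate with it.  This package inverts the question: given one genome and
a background cohort, for which of thousands of ontology terms is this
individual a *genetic outlier*?  Predictions are made before any phenotype
is observed, and are only afterwards confirmed against collected phenotype
answers.  The approach targets rare, high-impact missense variation acting
through protein domains, including combinations of variants that no
single-variant association test would see.

## The model, step by step

**Per-variant functional distance.**  A missense substitution at a residue
aligned to match state $j$ of a profile HMM is scored
$d = |\ln P_j(\mathrm{ref}) - \ln P_j(\mathrm{alt})|$, the magnitude of the
log-odds between the state's emission probabilities of the two amino
acids.  This measures evolutionary intolerance: replacing a conserved
residue by one the domain family never tolerates gives a large $d$.
Emissions are pseudocounted (floor $10^{-6}$, renormalised) so the
log-odds is always finite.  The sign and base of the logarithm are
conventions of this package: distances are symmetric magnitudes in nats.
Residues aligned to insertion columns carry no distance — the model has no
comparable emission there.

**Per-term profiles.**  Domain-to-ontology-term links (dcGO-style flat
pairs) select, for each term, every catalogue variant falling inside a
linked domain.  Each term is processed independently; term links are not
propagated along the ontology when profiles are built.  When several hits
cover a residue the highest-scoring hit wins, ties broken by
lexicographic model id, so profile construction is deterministic and
order-independent.

**Genetic distance between individuals.**  Over a term's sites, two
individuals are compared wherever their genotypes differ: a differing
het/hom pair contributes $d$, opposite homozygotes contribute $4d$.
Writing genotypes as alternate-allele dosages $g \in \{0, 1, 2\}$, the
zygosity weight is exactly $(g_a - g_b)^2$, so the total distance is a
squared Euclidean distance on dosage vectors scaled by $\sqrt{d}$ per
site — which is what makes the all-against-all matrix cheap.  Missing
genotypes are treated as homozygous reference and counted; this is
conservative (missingness can never inflate an outlier score).

**Hidden structure.**  The distance matrix becomes a similarity matrix
through a Gaussian kernel, $S = \exp(-D^2 / 2\sigma^2)$, with $\sigma$
the median off-diagonal distance.  The spectrum of the symmetric
normalised graph Laplacian is scanned for its biggest eigengap among
eigenvalues $2..k_{\max}$ (default 10): a cohort split into $k$ groups
shows $k$ small eigenvalues then a jump.  Structure is declared when the
winning gap at position $k \ge 2$ (i) exceeds $\rho = 3$ times the mean
of the other gaps in that window and (ii) is at least a tenth of the
eigenvalue level beneath it.  Condition (ii) was calibrated on simulated
landscapes, and the test suite reproduces the separation: unstructured
cohorts (i.i.d. Hardy–Weinberg genotypes over many modest-effect sites)
keep their maximal relative gap below 0.05, while planted genotype
blocks exceed 0.3, so any floor between those regimes behaves
identically and structure detection is not sensitive to the exact
value.  Without (ii), the dominance rule alone
fires on roughly a third of unstructured cohorts, because their trailing
eigengaps vanish and make the comparison mean arbitrarily small.

**Clustering.**  With structure declared, individuals are embedded in the
leading $m$ Laplacian eigenvectors ($m$ by the elbow — largest second
difference — of the eigenvalue curve, never below $k$; rows
unit-normalised) and partitioned by K-means with a fixed seed and 10
restarts.  Lloyd's algorithm is used: spectral embeddings of discrete
genotypes contain many exactly duplicated rows, on which Hartigan–Wong
stalls.  An empty-cluster event triggers one deterministic re-seed;
second differences are rounded before the elbow argmax so numerically
tied elbows resolve identically regardless of input order.

**Outlier scores.**  Without structure, an individual's raw score is its
mean distance to the background.  With structure it is
$\mathrm{local} + \mu \cdot \mathrm{global}$: the mean distance to the
other members of its cluster, plus the mean distance between its cluster
and the rest of the cohort, down-weighted by the cluster-size penalty

$$\mu = \frac{e^{\gamma\,(n - c)/n} - 1}{e^{\gamma} - 1},$$

with cohort size $n$, cluster size $c$ and $\gamma = 9$, so $\mu$ runs
from 1 (vanishing cluster) to 0 (whole cohort) and removes over 99% of
the global term for clusters above 60% of the cohort.  Both components
are measured on the original distance matrix.  This is a deliberate
design choice: the combinatorial contribution (below) is defined as the
clustered score minus the unclustered mean-distance score, and that
difference is only meaningful when the two live on the same scale; the
unit-normalised eigenspace, whose distances are bounded by 2, is not
commensurable with raw genetic distances.

**Combinatorial contribution.**  Clustering can make a variant *rarer
within a cluster* than in the whole background: a genome that joins a
cluster through shared common genotypes, yet carries an allele absent
from that cluster, gains score from both the cluster's separation
(global) and its own within-cluster rarity (local).  The positive part
of (clustered score − unclustered mean-distance score) quantifies this
gain and is reported per individual.  It is worth noting what the
$\gamma = 9$ penalty implies: $\mu$ falls to about 0.4 already at a
cluster holding 10% of the cohort, so a combinatorial excess can only
arise for small genotype-defined subgroups, a few percent of the cohort
at most.

**The universal transform.**  Raw score distributions differ wildly
between terms, so scores are mapped to
$$s_{\mathrm{trans}} = \sqrt[3]{\;e^{-\varphi\, r/N} \cdot
\frac{s}{\sum_p s(p)} \cdot \frac{s - \min s}{\max s - \min s}\;}$$
with 0-based rank $r$ (rank 0 = top score; ties share their mean rank)
and $\varphi = 150$, which confines material rank contributions to
roughly the top 2%.  Each factor lies in $[0, 1]$ and is monotone in
$s$, so transformed scores lie in $[0, 1]$ and preserve the raw
ordering.  The rank factor is implemented through the exact identity
$e^{-(1 + r/N)\varphi} / e^{-\varphi} = e^{-\varphi r / N}$.  If all
scores are equal the min–max factor is defined as 0 — nobody is an
outlier of a flat landscape.  Calls are made at a default threshold of
0.022 on the transformed score.

**Explaining calls.**  Each above-threshold call is dissected by
ablation: the individual's genotype at one profile site is set to
homozygous reference (the site itself stays, so the cohort geometry is
untouched) and the term re-scored.  A variant is *required* if its solo
ablation drops the call below threshold, *contributing* if it merely
decreases the score (by more than $10^{-9}$).  Types follow: `1-a` one
required variant only; `1-b` one required plus contributors; `2-a` no
single required variant (or several) but one variant's ablation drop
exceeds all others combined; `2-b` the rest — genuinely multi-variant.
Ablating every site scores the individual as a reference-only genome,
which is not necessarily zero.  Carried variants are banded by minor
allele frequency per zygosity: rare (<0.5% het, <1% hom), low-frequency
(<1% het, <5% hom), common above both.

**Confirmation.**  Questionnaires mix a participant's top 25 terms with
the top 25 of a random background decoy; shared terms are asked once,
attributed to the participant, the decoy side taking its next-ranked
term.  Questions with a positive-answer rate of zero or ≥5%, or fewer
than 20 answers, are dropped — a high rate means the question captures a
common phenotype, not an outlier.  Three permutation tests follow: the
mean score over yes-answers against globally re-allocated scores; the
yes-rate above the score threshold against the decoy rate and a
re-allocation null; and a per-term test on the sum of scores over
yes-answers, permuted within term, from which terms are ranked by
p-value and an expected-by-chance curve (mean ± SD over permutation
replicates) is subtracted to give the excess of true phenotypes among
the top $x$.  P-values use the add-one convention
$(1 + b)/(1 + n_{\mathrm{perm}})$; a z-score against the permutation
distribution is reported alongside.  For clinically annotated cohorts,
confirmation is automatic: a call is confirmed when an annotated term is
a *close match* of the predicted term — identical, or in an
ancestor/descendant relation with information contents within 1 nat.
Information content is $-\ln(\text{cumulative annotation count}/\text{total})$,
with counts propagated up the ontology; individuals without annotations
are never confirmed, the necessary assumption for automatic evaluation.

## What the synthetic generator emulates

`generate_world()` builds every input the pipeline consumes: Dirichlet
match-state emissions (concentration 0.3, giving skewed columns so some
substitutions are strongly intolerant), one domain hit per model, a
random ontology DAG, a variant catalogue with a rare/low/common MAF
mixture, and Hardy–Weinberg genotypes for a background cohort (default
500) plus subjects (default 20).  The catalogue couples allele frequency
to substitution tolerance: alternate residues of common variants are
drawn in proportion to their emission probability, rare variants may hit
any residue.  This emulates purifying selection — a catalogue where
maximally deleterious substitutions segregate at 40% frequency would
contradict the premise that emission log-odds measure intolerance.

Planted outliers define ground truth.  A `single_rare` plant gives one
subject a homozygous genotype at a site with MAF 0.1% at the domain's
widest-log-odds site.  A `multi_variant` plant spreads three rare het
genotypes over one term.  A `combinatorial` plant builds a genotype
subgroup (default 2% of the cohort — deliberately small, because the
size penalty erases the combinatorial excess for larger clusters, see
above) sharing one variant, and gives the subject a heterozygous allele
that is common outside the subgroup but absent within it.  The subject
is heterozygous, not homozygous, at that site: a homozygous conditional
rarity pushes the genome so far from its own subgroup that clustering
isolates it as a singleton — the geometry of a single-variant outlier,
not a combinatorial one.  The remaining sites of a combinatorial term
are redrawn from the rare band so that the co-occurrence subgroup is the
term's dominant hidden structure; without this the plant frequently is
not the structure the spectral step finds, and nothing has been planted.

What the generator does *not* emulate: linkage disequilibrium beyond the
explicit co-occurrence plant, population stratification, relatedness,
array batch effects, genotyping error, or realistic ontology topologies.
Passing tests on this generator therefore show that the machinery
recovers the architectures it defines — rare high-impact genotypes,
multi-variant burdens, conditional rarity — not that it is robust to
confounding in real cohorts, which the surrounding study design (QC,
confounder regression) must handle.

## Numerical choices and degenerate inputs

* Emission floors make every log-odds finite; flooring is idempotent so
  written tables round-trip exactly.
* An empty profile yields an all-zero, flagged distance matrix and zero
  scores; an all-identical distance matrix degenerates the kernel and
  forces the no-structure path.
* An all-zero raw-score vector is flagged; all-equal scores transform
  to zero.
* Ranks use average ties; K-means uses a fixed seed, Lloyd, 10 restarts,
  one re-seed on empty clusters; elbow ties are rounded away.
* Batches are scored jointly: subjects are appended to the background
  matrix and influence one another through the eigenproblem, so a batch
  of one is the reference behaviour.

## Problem sizes used by the test-suite

The bundled tests run the full engine on cohorts of 500 background
genomes plus 20 subjects over 200-term worlds (100 seeds for the
planted-outlier recovery rates), 200 simulated answer datasets with
2,000 permutations each for calibration, and small hand-built fixtures
for every oracle comparison.  These sizes keep a complete run in a few
minutes on one CPU while leaving the recovery and calibration rates
statistically meaningful.

## Known limitations

* The log-odds convention (absolute value, natural log) and the
  local/global definitions in distance space are this package's
  choices; other implementations of the same outline may differ in
  detail while following the same model.
* The eigengap detector's relative-gap floor was calibrated on the
  generator's landscapes; pathological real-data spectra (heavy-tailed
  distance distributions, near-duplicate cohorts) may need the exposed
  `rho` / `min_rel_gap` knobs.
* Ablation is single-variant; interactions where only pairs of
  ablations cross the threshold are classified through the dominance
  rule, not exhaustive subset search.
* Scores depend on batch composition by design; comparing calls across
  differently composed batches compares different backgrounds.
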