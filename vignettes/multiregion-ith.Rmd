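---
title: "Methods: multi-region tumor heterogeneity and TCR repertoire analysis"
author: "mrith authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region tumor heterogeneity and TCR repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrith)
```

# Scope and setting

`mrith` implements the downstream analysis of a multi-region tumor
sequencing study: several spatially separated specimens of one primary
tumor (typically five), optional lymph-node metastases, and a matched
normal per patient, each whole-exome sequenced at high depth (the
defaults emulate 290x tumor / 187x normal coverage), optionally joined
by T-cell receptor (TCR) repertoire sequencing of the same regions.
Upstream steps — alignment, primary variant calling, copy-number
segmentation, purity/ploidy inference, HLA typing and MHC binding
prediction — are taken as given: the package consumes their tabular
outputs (MAF-like mutation tables, SEG-like allele-specific segments,
per-SNP B-allele counts, AIRR-style clone tables) and owns everything
after that.

All genomic coordinates are 1-based closed intervals. Every stochastic
component is driven by an explicit integer seed.

# Variant filtering

Somatic SNVs are kept when tumor alt reads >= 4, tumor coverage >= 14,
matched-normal alt reads <= 2 and normal coverage >= 10; indels when
alt reads >= 6, coverage >= 20 and VAF >= 0.1. These are the numeric
post-calling filters only: caller-internal heuristics and manual indel
review are not reproducible from tables and are deliberately not
imitated. Filters are pure functions; every rejected row carries the
complete list of violated rules, and the unit tests compare each filter
against an independent per-row re-evaluation on 10^4 random rows.

A patient is flagged hypermutated at >= 10x the cohort median burden.
Germline variants in a 25-gene homologous-recombination (HR) panel are
called deleterious when coverage >= 30, VAF > 8%, population minor
allele frequency <= 1% (absent MAF is treated as rare), and the variant
is truncating (nonsense/frameshift/splice) or ClinVar-pathogenic.
Driver annotation flags non-silent variants in a driver gene list when
they match a recorded mutation exactly or sit within 15 bp of >= 3
recorded mutations (genomic coordinates; the convention is configurable
input, so users supplying protein-space indices should convert first),
or when a recessive gene carries a truncating variant with SIFT < 0.05
or PolyPhen > 0.995. Neoantigen candidates require predicted MHC-I
affinity strictly below 500 nM.

# Cancer cell fraction and clonality

With VAF $v$, purity $p$, local tumor total copy number $C_t$, normal
copy number $C_n$ and multiplicity $m$:

$$\mathrm{CCF} = \frac{v\,(p C_t + (1-p) C_n)}{p\,m},\qquad
  m_{\mathrm{auto}} = \mathrm{round}\!\left(\frac{v\,(p C_t + (1-p) C_n)}{p}\right)
  \text{ clipped to } [1, n_{major}].$$

The 95% CI is Clopper–Pearson on $v$ (a conservative choice that needs
no large-sample assumption) pushed through the same linear map; a
mutation is subclonal iff the CI upper bound is below 1. CCFs are
reported clipped to $[0, 1.2]$: values above 1 are evidence of
multiplicity misestimation and silently truncating them to 1 would hide
that. The closed form replaces a full purity/ploidy model fit, which is
out of scope here; externally computed CCFs can be supplied instead.
LOH at a locus means the minor allele is clonally deleted
($n_{minor}=0$) with the major allele retained; loss of the alternate
allele is additionally flagged at variant read frequency > 0.7.

# Parsimony phylogenies and mutation timing

Mutation presence per sample is binary: VAF >= 2% and >= 2 supporting
reads. The read-count guard is an addition beyond the VAF rule — at
290x, a single stray read already exceeds 2% at low coverage sites —
and is configurable. Trees are inferred by exhaustive discrete-character
parsimony over all rooted binary topologies on the tumor samples, with
the germline (all-zero profile) as root. Gains (0 to 1) cost 1 and
reversals cost 10: somatic point mutations are effectively never
unmade, but a finite reversal cost keeps scoring well-defined on
arbitrary input. With at most 9 samples the search is exact; beyond
that the function refuses rather than silently switching to a
heuristic. Co-optimal topologies are all returned; the reported tree
maximizes trunk length and then takes the lexicographically smallest
canonical newick, a deterministic stand-in for the manual copy-number
guided adjudication that a human analyst would perform (automatic
CNA-driven rearrangement is intentionally not attempted). Each mutation
is assigned to the gain edge of an optimal reconstruction; when a
homoplastic pattern needs several gains, the edge covering the most
samples is taken, which keeps foreign-clade blocks attached to their
majority clade.

Timing is definitional: trunk = present in all tumor samples of the
patient, private = exactly one, shared branch = the rest. Clone
intermixing is flagged when a sample carries, at CCF >= 0.1, a block of
>= 3 mutations assigned to a branch off its own root-to-leaf path.
Note an intrinsic limitation: when a foreign block's size equals the
support of a sample's true sister clade, the parsimony score ties and
the reported topology (hence the flag) follows the tie-break; the
co-optimal set exposes such cases. Metastatic seeding is classified on
the mutation-collapsed tree: one met clade hanging off the trunk node
with a mutated stem is a monoclonal precursor
(metastasis-to-metastasis spread); met attachments forming an ancestor
chain inside a primary subclade are linear; two or more independent
attachments at the trunk node are explosive.

# Mutational signatures

SNVs are tabulated into the standard 96 pyrimidine-centred
trinucleotide channels and deconvolved against a 30-signature catalog
by non-negative least squares (no sparsity penalty; all 30 signatures
compete, and contributions are reported as proportions of mutations).
Dominant signature = argmax proportion, ties to the lowest index.

The packaged catalog is **synthetic** and is labelled as such: the
reference 30-signature catalog is not redistributed here. Signatures
1, 2, 6, 13 and 22 carry the motif structure of their well-known
namesakes (CpG C>T, TpC-context APOBEC C>T and C>G, GpC-context C>T,
T>A), signature 3 — the HR-deficiency proxy — is a broad dispersed
profile, and the rest are sparse peaked profiles. The peaks were
sharpened at design time so that the 30-way deconvolution is
identifiable at realistic mutation counts: planted three-way mixtures
are recovered within 0.05 per-signature proportion at 5000 SNVs, the
recovery bound the tests assert. A
genuinely flat signature 3, as in the reference catalog, is near the
cone of the other signatures and not identifiable at desk-scale counts
— conclusions about real signature-3 calls should use the real catalog
via the `catalog` argument and expect weaker identifiability.

Trunk-versus-branch dynamics refit exposures on the two phases per
patient (phases under 20 SNVs are flagged low-confidence) and compare a
chosen signature's proportion across patients with a two-sided paired
t-test. One calibration caveat is inherent to NNLS: when the tested
signature is absent from the generating process its fitted proportion
sits on the zero boundary, and the paired test's null distribution is
no longer uniform; the calibration tests therefore generate under a
mixture in which the signature is interior. The signature-3 based
BRCA1/2 prediction uses the empirical ROC AUC via the Mann–Whitney
statistic with ties counted 1/2; the positive-label definition
(germline-pathogenic only, germline plus ubiquitous somatic, or
biallelic only) is the caller's choice of input labels.

# Mirrored subclonal allelic imbalance

Per patient, sample segmentations are merged into a consensus partition
(union of breakpoints, restricted to regions covered by every sample).
On a consensus segment with allelic imbalance in both samples of a
pair, each heterozygous SNP's BAF is scored under two normal densities
truncated to (0,1), centred at the theoretical BAFs

$$\mathrm{BAF}_{major} = \frac{p\,n_{major} + (1-p)}{p\,(n_{major}+n_{minor}) + 2(1-p)},$$

with the scale per segment and sample estimated as the MAD of BAFs
folded about the nearer centre, floored at 0.01 (robust to assignment
uncertainty). "Log-truncated normal" is interpreted as this truncated
normal evaluated in log space; the interpretation is isolated in one
function. Each SNP is assigned to the higher-likelihood haplotype per
sample; the per-SNP reversal log-likelihood ratios, symmetrized over
sample order as $r_i = (-\mathrm{sign}(L_{1i}) L_{2i}
- \mathrm{sign}(L_{2i}) L_{1i})/2$, are tested against zero with a
one-tailed t-test (the symmetrization makes the verdict provably
independent of sample order). An event is mirrored when the test is
significant at alpha = 0.05 and the favored haplotype flips. Balanced
segments and segments with fewer than 10 shared SNPs are skipped with
explicit reasons. Across segments, raw p-values are reported together
with a Benjamini–Hochberg column; no claim is made about which
correction the original procedure used.

# Neutral evolution

The neutral growth model predicts the cumulative count of subclonal
mutations above frequency $f$:

$$M(f) = \frac{\mu}{\beta}\left(\frac{1}{f} - \frac{f}{f_{max}}\right),$$

fitted through the origin on the open VAF window (0.12, 0.24) by least
squares, with $R^2$ computed against the mean of $M$ (so it can go
negative for pathological fits); $R^2 \ge 0.98$ calls the sample
neutral. Eligibility requires purity > 0.5 and >= 12 window SNVs.
$f_{max}$ defaults to purity/2, the expected clonal heterozygous VAF in
a diploid region, and is configurable.

The printed purity-corrected fallback multiplies the slope by
$1/(1+\varepsilon)$, which alone is an unidentifiable
reparameterization; the implemented fallback is the dilution model it
abbreviates: contamination scales observed frequencies by
$1/(1+\varepsilon)$, giving
$M(f) = s/f - s(1+\varepsilon)^2 f/f_{max}$ with
$s = \mu/(\beta(1+\varepsilon))$ — two identifiable parameters, fitted
by profiling (closed-form slope at fixed $\varepsilon$, 1-D search over
$\varepsilon \in [0, 2]$). It is applied only when the plain fit fails,
and `r_squared_adjusted >= 0.98` then calls the sample neutral.

The neutral generator draws VAFs with density proportional to
$1/f^2 + 1/f_{max}$ on $(f_{min}, \sqrt{f_{max}})$, which makes $M(f)$
match the model exactly with no offset ($M(\sqrt{f_{max}}) = 0$; for
$f_{max} = 0.25$ the support ends at 0.5, the clonal VAF of a pure
diploid tumor). Read counts are Poisson coverage with binomial alt
reads. Because the $1/f^2$ shape is parameter-free, the mutation count
(not `mu_eff`) pins the realized slope; the implied true slope is
recorded in the returned truth object for recovery tests, which assert
median relative slope error below 15% at 5000 mutations and depth 200.

# TCR repertoires

Clone identity is the (CDR3 amino acid, V gene, J gene) triple — CDR3
reporting is amino-acid level, and nucleotide-level identity would
break sharing across samples; the choice is configurable by supplying
different identifiers. Preprocessing keeps productive clones, drops
clones at <= 2 reads per million of the sample's productive total, and
downsamples to exactly one million reads (seeded, without replacement)
before diversity metrics when the total exceeds it.

Diversity: Shannon index in bits; evenness = Shannon / log2(unique
clones) (defined as 0 for a single clone); clonality = 1 - evenness
(the standard complement, used where the original clonality formula is
not reprinted); CR4 = summed frequency of the top four clones;
high-frequency clone count at a configurable threshold. The threshold
is stated inconsistently in the source material (0.01% in the methods
and main figure, 0.1% in the results text); the default is 0.01% with
0.1% available — no intent is guessed.

Similarity and distance per sample pair, with equal TRA/TRB weights:

$$D_{J} = \tfrac12\left(\frac{1}{J_{TRA}}-1\right) +
          \tfrac12\left(\frac{1}{J_{TRB}}-1\right),\qquad
  \mathrm{overlap} = \frac{\sum_i (a_i + b_i)}{\sum A + \sum B},$$

where $J$ is the Jaccard index on clone identity sets and the overlap
sums read counts of shared clones. A chain missing from either sample
drops out with the remaining chain at full weight (flagged); zero
similarity yields an infinite distance reported as a configurable cap.
Both distances are computed; the count-overlap distance feeds
neighbor-joining by default, since it comes from the tree-construction
recipe, while the Jaccard distance is the pairwise-similarity summary.
NJ trees clamp negative branch lengths to zero, moving the deficit to
the sister edge so path lengths through the parent are preserved.
Genetic-vs-TCR concordance checks, for each nontrivial genetic clade
among shared primary regions, whether clade members are mutually closer
in the TCR tree (cophenetic) than to non-members; the score is the
fraction of concordant clades, with a cophenetic Spearman correlation
reported alongside.

# The synthetic cohort generator

`simulatePatient()` plants a rooted sample topology, one clone per
topology edge (trunk first), geometric CCF decay (retention 0.75 per
step) along each lineage, and binomial read sampling at Poisson
coverage; trinucleotide contexts come from a chosen signature mixture.
Metastatic seeding patterns (monoclonal precursor, linear chain,
explosive trunk attachment) are constructed topologically, and clone
intermixing is planted by adding a small foreign clade's mutations to
one sample at a chosen CCF — the smallest shared foreign clade, so the
spill is a minority signal rather than a topology-overturning one.
The generator emulates count-level WES data faithfully enough for
recovery tests: what it does **not** model includes sequencing error
(absent samples have exactly zero alt reads), mapping artifacts, copy
number variation (all loci diploid, multiplicity 1), overlapping
subclones within a sample beyond the lineage nesting, and purity
variation across regions. Passing recovery tests on these simulations
therefore demonstrates correctness of the inference machinery, not
robustness to real-data artifacts.

Problem sizes used by the test suite were chosen to exercise each claim
at realistic scale: 5000 mutations / depth 200 for neutral fits, 5000
SNVs for signature recovery, 5-region patients for tree recovery, 1000
replicates for the MSAI and paired-test calibrations, 10^3–10^4
randomized instances for the formula-equivalence oracles.

# Determinism and numerical choices

Every generator takes an integer seed; the pipeline seeds once from its
configuration and writes byte-identical outputs across runs. NNLS is
Lawson–Hanson via `pracma::lsqnonneg`. Binomial CIs are Clopper–
Pearson via beta quantiles. Parsimony uses a vectorized two-state
Sankoff recursion over unique presence patterns; the brute-force
re-scorer in the tests enumerates internal-node states explicitly.
Dominant-signature and co-optimal-tree ties break deterministically
(lowest signature index; maximal trunk then lexicographic newick).
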