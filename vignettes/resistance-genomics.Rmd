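---
title: "Two-timepoint mutation catalogs, network nulls, and PDX screens: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-timepoint mutation catalogs, network nulls, and PDX screens: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistnet)
```

# Overview

`resistnet` implements the analysis arc of a single-patient acquired-resistance
study: a tumor is sequenced before and after resistance to a targeted agent
(here, the FGFR3-directed tyrosine kinase inhibitor pazopanib in a bladder
cancer carrying an FGFR3-TACC3 fusion), and the two somatic mutation catalogs
are contrasted at three levels — clonality (variant allele frequencies),
interaction-network topology, and functional annotation — with a
patient-derived xenograft (PDX) drug screen closing the loop. Each stage is a
module with a small surface, and a synthetic-data module generates inputs with
the statistical structure the analyses assume, so the whole pipeline is
testable offline.

# Mutation catalogs and clonality

A catalog row is one somatic alteration observed by one assay: gene, cDNA
change, amino-acid annotation, mutant reads $m$, coverage $c$, and
$\mathrm{VAF} = m/c$. Stated VAFs are cross-checked against the read counts at
parse time with a tolerance of 0.006: published tables print VAF at two
decimals and occasionally disagree with the read-count ratio by slightly more
than half a rounding unit (the packaged fixture itself contains records off by
up to 0.0055), so the canonical 0.005 half-unit is too strict for real tables
and a one-in-the-third-decimal allowance is added. Recomputed values, not the
printed ones, feed all downstream statistics; rounding to two decimals happens
once, at reporting time, to match the precision at which such tables are read.

**Matching across timepoints.** The identity of a mutation is the (gene, cDNA
change) pair. Comparing two assays, records are matched in two passes: exact
cDNA identity first, then an amino-acid rescue pass for records of the same
gene whose protein change is identical but whose cDNA annotation differs.
The rescue pass exists because different pipelines annotate the same variant
against different transcripts — in the packaged case fixture, two mutations
(TERT E507V, TP53 E258K) are reported under different cDNA coordinates by the
two exome assays while the amino-acid change is identical. Matching on cDNA
alone would misread each as one loss plus one gain; with the rescue pass the
fixture yields the 9 persisting / 53 new / 3 lost partition that the clonality
analysis rests on. Amino-acid strings are otherwise annotation only: a cDNA
match with discordant amino-acid labels (assay-specific position numbering)
still matches.

**Clonality summary.** For a mutation set, `summarize_vaf()` reports the
median two-decimal VAF and the fraction at or above a threshold, default
0.10. The threshold is inclusive because mutation tables report VAF at two
decimals: a mutation printed at exactly 0.10 belongs to the "at least 10%"
class (the fixture has two such records, and only the inclusive reading
reproduces its 9/53 fraction). The persisting-vs-new VAF comparison defaults
to a two-sided Mann–Whitney rank-sum test; the choice is recorded in the
output and a Welch t-test is available. No attempt is made to reproduce any
specific published p-value for this contrast, since the original test is
unidentified; the package's claim is directional (persisting mutations are
clonal, new ones subclonal), and the test on the fixture gives p < 0.001.

# Network topology

Interaction networks are simple undirected graphs: self-interactions removed,
A–B and B–A stored once. All statistics are computed on the giant connected
component; equally sized components tie-break to the one containing the
lexicographically smallest node name, for reproducibility. Genes absent from
the network (e.g. fusion partners outside the interaction sources) are dropped
with a warning rather than inserted as isolates, because every metric is
defined relative to the component.

Per node $v$ with degree $d_v$ and $t_v$ edges among its neighbors:

* clustering coefficient $CC_v = 2t_v / (d_v(d_v-1))$, set to 0 for
  $d_v < 2$ so that set-level means are total;
* K1 centrality (average neighbor degree) $K1_v = \frac{1}{d_v}\sum_{u \sim v} d_u$,
  0 for isolated nodes;
* closeness $C_v = (n-1) / \sum_u d(v,u)$ over the $n$ nodes of $v$'s
  component — the component-local normalized definition, well-posed because
  analysis is restricted to the giant component.

Set-level statistics default to the mean over members (the median is
available); whether a set-level closeness should be a mean or another
aggregate is genuinely underdetermined in this style of analysis, so the
aggregator is a parameter.

# The degree-matched null model

Degree has a profound effect on every other topology statistic, so observing
that a mutated gene set has high clustering or closeness is only informative
relative to sets with the same degree structure. The null model resamples
random gene sets with the same size and the same degree multiset as the
observed set (10,000 draws at full scale; tests use 200–1,000), evaluates the
set statistic on each, and reports the empirical p-value.

Design choices:

* **Exact matching with binned fallback.** Degree classes are matched exactly
  when at least 5 candidate nodes exist; sparser classes (typically the top
  hubs, whose exact degree is unique) fall back to geometric bins
  $[2^i, 2^{i+1})$. Both behaviors are available (`matching = "exact"`
  disables the fallback) and the binned classes are reported, since "same
  degree distribution" admits either reading.
* **Direction.** The default empirical p counts the fraction of resampled
  statistics *greater than or equal to* the observed value — the
  alternative-hypothesis side for claims that the observed set is unusually
  central, clustered, or hub-adjacent. A caption-literal mode counting the
  $\le$ fraction is exposed because figure captions in this literature
  sometimes state the complementary fraction; with ties,
  $p_{\ge} + p_{\le} = 1 + \mathrm{ties}/N$.
* **Plain fraction by default.** The pseudo-count estimator $(x+1)/(N+1)$ is
  available because a reported 0 is statistically improper, but the default
  reproduces the plain-fraction convention. Calibration tests use the
  pseudo-count mode, under which the p-value of a sampler-drawn "observed"
  set is exactly discrete-uniform.
* Observed-set members are eligible for resampling (exclusion is not
  offered; it would bias the null on small graphs).

Calibration and power are both tested: sampler-drawn observed sets give
uniform p-values (Kolmogorov–Smirnov at $\alpha = 0.01$ over 200 replicates of
200 draws on a 300-node graph), and a planted clustered module (20 nodes,
clustering raised 0.25 above the graph mean by edge addition) is detected at
p < 0.05 with 1,000 draws on a 1,000-node graph.

# Enrichment

Term enrichment is the hypergeometric upper tail: drawing the $n$ query genes
from a background of $N$ genes of which $K$ carry the term,
$p = P(X \ge k)$ for the observed overlap $k$, computed via the log-space
tail (`stats::phyper`) so small p-values do not underflow. The background is
the network gene set, not the genome — the question asked is "is this term
over-represented among mutated genes relative to the genes the network
analysis can see at all". FDR control is Benjamini–Hochberg, applied within
each GO namespace by default (the three ontologies are treated as independent
families, mirroring common GO-tool behavior); pooled correction is available.
The default reporting filter is the stringent corrected p < 0.001; `alpha = 1`
disables filtering. Annotation maps are taken as given — no DAG propagation
or true-path up-weighting — so a provided map should already reflect whatever
propagation the user wants.

# Ultra-deep panel post-processing

Threshold inclusivity follows the natural-language reading of each rule:

| filter | rule | boundary |
|---|---|---|
| somatic support | at minimum 5 reads, minimum 1% VAF | inclusive ($\ge$) |
| amplification | $\ge 4$ copies | inclusive |
| homozygous deletion | 0 copies | exact |
| discordant insert | over 2000 bp, or 0 | strict ($>$), plus 0 |
| breakpoint clustering | distance less than 500 bp | strict ($<$) |

Discordant reads are placed at the leftmost mapped coordinate of the pair and
clustered per chromosome by single linkage; clusters need at least 2 reads
(one pair is never a "cluster"). Assembly and breakpoint reconfirmation
against the reference are out of scope — the deliverable is the cluster
coordinate intervals. Copy-number classification accepts copy numbers
directly because the conversion from centered log-ratio and tumor cellularity
to integer copies is pipeline-specific; `compute_log_ratio()` provides the
median-centered $\log_2$ depth ratio that such conversions start from. TMB is
eligible mutations (coding, non-driver, non-dbSNP-germline) per megabase;
published TMB values for the motivating case (38.4 rising to 97.2 mut/Mb)
depend on raw data that are not publicly available and are context, never a
test oracle.

# PDX drug screens

Tumor volume is the caliper formula $lw^2/2$ (axes swapped with a warning if
reversed). TGI uses group medians, per its definition:
$\mathrm{TGI} = (1 - (T_t - T_0)/(C_t - C_0)) \cdot 100$, evaluated by
default at the last day measured in both groups; TGI > 50% is flagged
meaningful. Humane-endpoint flags default to 1,500 mm³ (the lower bound of
the conventional 1,500–2,000 mm³ range, configurable) and >15% body-weight
loss from day 0. Group weight summaries are mean ± sample SD; group-mean
significance testing, when wanted, is a Welch t-test against vehicle with no
multiplicity correction by default, matching how such screens are reported.

# Synthetic data: what it emulates, and what it does not

The generators are fully seed-determined and produce inputs in the exact
formats the analysis functions read.

* **Network**: a static power-law fitness graph, default 1,000 nodes, mean
  degree 9 (≈4,500 edges), tail exponent 2.5, simplified and reduced to its
  giant component — a 1:10-scale stand-in for a full-size interaction network
  of ~9,316 nodes / 42,102 edges. It reproduces heavy-tailed degrees and
  sparse clustering but none of the biological modularity or ascertainment
  bias of curated interaction maps.
* **Catalogs**: 9 persisting mutations present at both timepoints with VAFs
  from Beta(4,4) rescaled to [0.05, 1], and 53 new post-only mutations with
  VAFs from Beta(1.2, 15) (median ≈ 0.06); coverage uniform on [80, 650] and
  mutant reads Binomial(coverage, VAF), with the recorded VAF exactly the
  read ratio. These defaults copy the summary structure of the motivating
  case (clonal persisting, subclonal new, panel-scale depths); they are not a
  fitted evolutionary model, and read counts carry no overdispersion.
* **Annotations**: random terms plus one planted term with a known query
  overlap (default 8 of a 20-gene query in a 30-gene term), giving an exact
  hypergeometric truth for power tests.
* **Growth curves**: exponential volumes $V_0 e^{r e t}$ ($V_0 = 200$ mm³,
  $r = 0.1$/day, arm effect $e$ multiplying the rate), measured twice weekly
  for 21 days with mean-one lognormal noise (CV 10%), 6 animals per arm;
  caliper axes are back-derived at a fixed 1.25 aspect ratio so volumes
  round-trip exactly. The closed-form TGI of the noise-free curves is the
  recovery target in tests.

Passing tests on these generators show that the estimators are correct and
calibrated under the assumed structure; they cannot show robustness to real
interaction-map bias, clonal interference, or measurement artifacts absent
from the models.

# Problem sizes and numerical choices

The test suite runs at desk scale by design: oracle equivalence on 200 random
graphs of up to 50 nodes (brute-force neighbor enumeration and Floyd–Warshall
distances, agreement to 1e-12), null-model calibration at 200 replicates × 200
draws, power at 1,000 draws on 1,000-node graphs, enrichment enumeration over
the full hypergeometric support for N ≤ 30, false-positive calibration over
1,000 random queries, and TGI recovery over 100 replicates (±10 percentage
points at CV 10%, n = 6). Full-scale quantities from the motivating study —
the assembled interaction network itself, its absolute TMB values, the exact
persisting-vs-new p-value (whose original test is unnamed), and the wet-lab
PDX measurements — are documented as external reference points only.

Other numerical conventions: two-decimal rounding uses R's `round()`
(half-to-even; no fixture value sits on an exact half); empirical p-values
compare with non-strict inequalities so ties count as extreme; medians of
even-sized sets are midpoint medians; giant-component and randomization
tie-breaks are deterministic given the seed.

# Limitations

Single-case analyses support hypothesis generation, not inference about
populations; the package computes the descriptive and resampling statistics
faithfully but cannot rescue the n = 1 design. The annotation module tests
terms independently (no DAG structure), the null model resamples node sets
(edge-rewiring nulls are out of scope), and the panel filters implement the
published post-processing rules, not the upstream callers.
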