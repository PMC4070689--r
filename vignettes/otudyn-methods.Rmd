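---
title: "Methods: tracking OTU dynamics in a sequencing batch reactor"
author: "otudyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking OTU dynamics in a sequencing batch reactor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otudyn)
```

## The problem

A laboratory activated-sludge sequencing batch reactor (SBR) run under
constant operating conditions still shows strong internal community dynamics:
individual bacterial populations propagate, recede, and occasionally collapse
abruptly. otudyn implements the computations needed to follow such dynamics
from barcoded 16S rRNA amplicon reads sampled over time: demultiplexing,
OTU clustering, per-sample fraction estimates with confidence intervals,
virtual T-RFLP fingerprints, a washout null model that separates "diluted
out by sludge wastage" from "selectively killed", a substrate-share bound for
rapid propagation, and tree-ordered heatmaps for presentation.

Everything is testable offline: a synthetic-community module generates
reactor time series and barcoded reads with known ground truth.

## The reactor model

The SBR (defaults: working volume $V = 10$ L, feed $V_f = 5$ L/cycle, phase
durations 5/55/120/45/15 min, so $\Delta t = 4$ h cycles) gives a nominal
hydraulic retention time

$$\mathrm{HRT} = \frac{V}{V_f/\Delta t} = 8\ \mathrm{h},$$

and excess sludge is withdrawn once per cycle during the aerobic phase so
that the nominal solids retention time is $\mathrm{SRT} = 10$ d. The
per-cycle biomass wastage fraction $w$ can be written two ways:
the small-fraction ("nominal") form $w = \Delta t/\mathrm{SRT}$ and the
exact form $w = 1 - e^{-\Delta t/\mathrm{SRT}}$. **The exact form is the
package default**: with it the discrete per-cycle decay $(1-w)^n$ coincides
with the continuous first-order washout $e^{-t/\mathrm{SRT}}$ on the cycle
grid, so the discrete simulator and the smooth expected-reduction curve are
a single consistent model (the nominal form differs from continuous decay by
about 1.7% after 20 d at SRT 10 d). The nominal form remains selectable in
`wastage_fraction_per_cycle()`.

Community dynamics are simulated per cycle:
$$X_j \leftarrow X_j\, e^{\mu_j \Delta t} (1 - w),$$
with piecewise-constant specific growth rates $\mu_j$ (per day) and optional
lysis events that multiply a taxon's biomass by a survival fraction at a
stated day. A taxon growing at exactly $\mu = 1/\mathrm{SRT}$ holds its
biomass constant; the community-wide baseline rate in the shipped scenarios
is therefore $1/\mathrm{SRT}$, which keeps total biomass at steady state.

## Fractions and confidence intervals

From the OTU count table $C_{i,j}$ (sample $i$, OTU $j$):

$$f_{i,j} = 100\, \frac{C_{i,j}}{\sum_j C_{i,j}}\ [\%], \qquad
\bar f_j = \frac{\sum_i f_{i,j}}{N}\ [\%],$$

with $N$ the number of samples. "Major" OTUs are those with
$\bar f_j$ strictly greater than 0.5% by default.

Per-point uncertainty treats each OTU's count against the sample total as
binomial and inverts the likelihood-ratio test: the $1-\alpha$ interval is
$\{p : 2[\ell(\hat p) - \ell(p)] \le \chi^2_1(1-\alpha)\}$ with
$\ell(p) = k \log p + (n-k)\log(1-p)$, solved by bracketed root-finding
(`uniroot`, tolerance $10^{-12}$); $k=0$ and $k=n$ pin the corresponding
endpoint to 0 or 1. The $\chi^2$ quantile comes from `stats::qchisq`. No
multiplicity adjustment is applied across OTUs or samples — the intervals
are per-point, as in the visual error-bar use they support. Endpoints agree
with a brute-force grid search (step $10^{-6}$) to $10^{-5}$, and the exact
coverage at $n = 500$ is 94.8–94.9% for $p \in \{0.1, 0.3\}$ and 92.9% at
$p = 0.01$ (binomial discreteness; no interval family avoids this), so the
pooled coverage over those three proportions sits just above 94%.

## Demultiplexing and clustering

Reads are assigned to samples by their 8-base barcode plus the forward
primer (27f by default), both matched with IUPAC ambiguity sets; the reverse
complement of the read is consulted when the forward end does not qualify,
and reverse-orientation reads are stored reverse-complemented so all inserts
share one orientation. Default tolerances are 1 barcode mismatch and
2 primer mismatches; since the barcode sets are generated with pairwise
Hamming distance $\ge 3$, one tolerated mismatch can never misassign a read
between known barcodes — reads are either assigned correctly or binned
(ties between barcodes are always binned, never resolved by position).
The downstream primer region, when detected near the 3' end with the same
matcher, is trimmed and remembered (`had_reverse_primer`): the detection is
automated rather than manual curation, using the identical IUPAC machinery.

Clustering is a deterministic greedy-centroid pass at 97% identity: unique
sequences are visited in order of decreasing duplicate abundance (ties
broken lexicographically), each joins the first centroid at or above the
threshold, otherwise founds a new OTU. Identity comes from an ends-free
global alignment (match $+1$, mismatch $-1$, gap $-2$), defined as matched
columns over alignment length with terminal overhangs free — so 3'
truncations common in pyrosequencing reads do not split OTUs. Two
numerical guards matter here:

* **Coverage condition.** The maximum-score ends-free alignment of two
  *unrelated* sequences can be a short, perfectly identical dovetail
  overlap; without a guard such pairs would score identity 1. Identity is
  therefore 0 unless the alignment covers at least half of the shorter
  sequence, the same kind of coverage rule greedy clustering tools
  conventionally impose.
* **k-mer prescreen.** An optional shared-8-mer screen (q-gram lemma bound,
  padded by the length difference) skips centroid comparisons that provably
  cannot reach the threshold. It is validated against exhaustive comparison
  in the tests and never changes results.

This module intentionally does not replicate any particular legacy
clustering heuristic; determinism and testability were preferred, and the
downstream statistics do not depend on the clustering flavor.

## Virtual T-RFLP

For each demultiplexed read the amplicon is reconstituted as forward primer
+ insert (+ the reverse primer's reverse complement when the downstream
primer region was seen), because the fluorescent label sits on the forward
primer's 5' end and the primer was trimmed at demultiplexing. The T-RF is
the distance from that 5' end to the cut point of the first recognition-site
occurrence (RsaI: GTAC, cut GT^AC, offset 2). Reads without a site
contribute the full reconstituted length *only* when the downstream primer
was detected (the template demonstrably ran to the end); otherwise the
fragment length is unknowable from a truncated read and the read is
excluded, with exclusions book-kept so counts always reconcile. Site search
runs on the labeled strand only; GTAC is its own reverse complement, so this
is lossless for RsaI (documented, not assumed, for other enzymes).

The 8-base barcode is *not* included in fragment sizes by default, because
experimental T-RFLP is typically run with unbarcoded primers; an
`include_barcode` flag exposes the $\pm 8$ bp sensitivity. Virtual profiles
are compared to experimental peak tables by greedy nearest-size matching
within a 5 bp default tolerance (capillary sizing is a few bp off from true
sequence length — a 484 bp predicted fragment matching a 481 bp observed
peak motivates the default), scored by cosine similarity of the
sum-normalized weight vectors. No fragment-length intensity or mobility
correction is applied.

## The washout null model and recession calls

The null hypothesis for a receding OTU is that its growth stopped entirely
while the rest of the community holds total biomass at steady state, so it
is diluted out solely by sludge wastage:

$$f(t) = f_0\, e^{-(t - t_0)/\mathrm{SRT}},$$

anchored at a **user-chosen** day $t_0$ (typically the last observation
before the suspected collapse). The anchor is never auto-detected: choosing
it from the same series the verdict is computed on would make event
detection circular. `detect_selective_recession()` calls
`faster_than_washout` when at least `min_consecutive` (default 2)
consecutive sampled points have their CI upper bound strictly below the
curve — mirroring a visual error-bars-versus-curve argument rather than a
formal test — and `not_receding` for the symmetric exceedance. Two
consecutive points guard against single-point dropouts.

Two caveats are documented deliberately. First, read fractions are treated
as proxies for biomass fractions throughout. Second, the curve is anchored
at a *noisy observation*: its own counting error is comparable to the
per-point CI width at any depth (both scale as $1/\sqrt{n}$), so a truly
non-growing OTU is occasionally (order 5–10% of replicates) called
`not_receding` when its anchor happened to read low. The tests assert this
property statistically over seeds rather than on a single draw. The
`faster_than_washout` direction is what the detector is for, and a planted
95% kill at 2,000 reads/sample is recovered with 20/20 sensitivity and zero
false positives in the shipped benchmark.

## Substrate share

With total biomass at steady state the community produces
$\Delta t/\mathrm{SRT}$ new biomass per unit standing biomass over
$\Delta t$ days. An OTU moving from fraction $f_1$ to $f_2$ must account for
its net gain plus what wastage removed from it (trapezoidal approximation):

$$\mathrm{share} =
\frac{(f_2 - f_1)/100 + \frac{f_1 + f_2}{200}\,\Delta t/\mathrm{SRT}}
     {\Delta t/\mathrm{SRT}}.$$

A steady OTU's share equals its own fraction; shares above 1 flag growth
exceeding the total supply (the steady-state assumption breaks), negative
shares flag decline faster than washout. For a rise from 1.9% to 29.9% at
SRT 10 d the share exceeds 0.5 for any $\Delta t$ between 3 and 5 days
(exceeding 1 below $\Delta t \approx 3.4$ d) — more than half of the
substrate supply captured by a single OTU. Because the day of the 1.9%
observation is a parameter rather than a fixed datum, the interval
$\Delta t \in [3, 5]$ d is scanned and only the qualitative bound
(share $> 0.5$) is asserted.

## Trees and heatmaps

The neighbor-joining implementation is the classic Saitou–Nei agglomeration
with deterministic tie-breaking (lowest index pair in current node order)
and negative branch lengths clamped to zero with a warning; it recovers
additive distance matrices exactly (verified against the generating tree's
path-length matrix over random trees) and agrees with `ape::nj` on
informative matrices. Distances for OTU representatives are
$1 - \mathrm{identity}$, with a Jukes–Cantor correction available; no claim
is made about which distance model best matches any particular published
tree. Heatmap rows follow the tree's depth-first leaf order (optionally
ladderized), columns follow sampling day, and rendering (linear or
$\log_{10}(x + 0.1)$ scale) delegates to pheatmap.

## The synthetic scenario

`default_scenario()` encodes the study-like conditions: a 10 L SBR at SRT
10 d, 30 taxa, 245 d with 75 sampling points, 1,000 reads per sample
(within the hundreds-to-thousands range typical of barcoded pyrosequencing
pools), 0.2% per-base substitution errors, 35% reverse-orientation reads,
80% full-length templates with up to 60 bases of 3' truncation otherwise.
Reference inserts are 420–500 nt, mutually below 90% identity so 97%
clustering is unambiguous; 60% carry an RsaI site. One designated taxon
re-enacts the boom-and-lysis pattern: a rise from ~2% to ~30% of the
community in 5 days (growth 0.72/d against a 0.1/d baseline), an abrupt
lysis event at day 45 with 5% survival, and later propagation episodes. Its
reference is a synthetic sequence planted so that the RsaI T-RF from the
27f 5' end is 484 bp, emulating the fragment length characteristic of this
phenomenon; the digestion code recomputes that length from the sequence at
run time.

What the simulator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: chimeras, PCR and extraction bias,
homopolymer indel errors characteristic of pyrosequencing, quality-score
structure, rRNA-operon copy-number variation, and any difference between
rRNA-molecule and rRNA-gene abundance. Error handling is
substitutions-only by default because the computations under test are
insensitive to the error flavor.

## Problem sizes and numerical choices in the test suite

Read-level tests run scaled-down scenarios (typically 3–12 taxa, 10–150
reads per sample, horizons of days to weeks), chosen so the whole suite
exercises every stage — including two full clusterings of a 200-read set
against an exhaustive oracle and a 20-community detector benchmark at 2,000
reads/sample — in about a minute. Count-level tests (multinomial sampling
directly from biomass) use the full 2,000-read depth where counting power
matters. Root-finding tolerances are $10^{-12}$; grid oracles use step
$10^{-6}$; washout-curve equivalence is checked on whole days, where the 4 h
cycle grid makes the discrete and continuous forms coincide exactly.

## Known limitations

* Greedy clustering quality depends on abundance ordering; it is exact and
  deterministic but not globally optimal, and differs from any specific
  legacy tool's output.
* The recession verdict inherits anchor noise (above); it is a screening
  rule, not a calibrated hypothesis test.
* The substrate-share estimator assumes steady-state total biomass over the
  interval; it flags, but cannot repair, violations.
* Taxonomy assignment, multiple alignment, and de novo maximum-likelihood
  trees are out of scope; taxonomy labels and externally built newick trees
  are accepted as inputs.
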