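# otudyn

Bacterial population dynamics in activated sludge from barcoded 16S rRNA
amplicon time series.

A laboratory sequencing batch reactor (SBR) run under constant conditions
still shows strong internal community dynamics: individual populations
propagate, recede, and occasionally collapse abruptly, as if selectively
killed. otudyn is for microbial ecologists and wastewater engineers who
follow such dynamics with barcoded amplicon sequencing and want the whole
computational chain — from raw barcoded reads to defensible statements like
"this OTU vanished faster than sludge wastage can explain" — reproducible
and testable offline.

## What it computes

* **Demultiplexing** (`demultiplex()`): barcode + primer matching with IUPAC
  ambiguity sets in both read orientations; reverse reads are
  reverse-complemented and pooled; the downstream primer region is detected
  and trimmed.
* **OTU clustering** (`cluster_greedy()`): deterministic greedy-centroid
  clustering at 97% identity (ends-free global alignment: match +1,
  mismatch −1, gap −2, with a minimum-coverage guard).
* **Fraction series** (`compute_fractions()`): per sample *i* and OTU *j*,

  f<sub>i,j</sub> = 100 · C<sub>i,j</sub> / Σ<sub>j</sub> C<sub>i,j</sub> [%],
  f̄<sub>j</sub> = Σ<sub>i</sub> f<sub>i,j</sub> / N [%],

  with per-point binomial profile-likelihood (LRT) confidence intervals:
  the set of p with 2[ℓ(p̂) − ℓ(p)] ≤ χ²₁(0.95). `select_major_otus()`
  keeps OTUs with f̄<sub>j</sub> > 0.5%.
* **Virtual T-RFLP** (`trf_length()`, `build_virtual_profile()`,
  `compare_profiles()`): in-silico RsaI digestion (GT^AC) of reconstituted
  amplicons, measured from the labeled 27f 5' end; full amplicon length for
  site-free reads only when the reverse primer region was found; greedy
  peak matching against experimental electropherogram tables within 5 bp.
* **Washout null model** (`expected_no_growth_curve()`,
  `detect_selective_recession()`): under stopped growth and steady total
  biomass, f(t) = f₀ · e^(−(t−t₀)/SRT); an OTU whose CI upper bounds fall
  below this curve on consecutive samples is receding faster than wastage —
  evidence of selective killing (lytic phage, bacteriocins, ...).
* **Substrate share** (`substrate_share()`): the fraction of total biomass
  production an OTU must have captured to move from f₁ to f₂ in Δt days at
  a given SRT; a steady OTU's share is its own fraction, a share > 0.5
  means more than half of the substrate supply.
* **Trees and heatmaps** (`neighbor_joining()`, `build_heatmap()`):
  Saitou–Nei neighbor joining with deterministic tie-breaks, newick I/O,
  and fraction heatmaps whose rows follow the tree's leaf order.
* **Synthetic communities** (`default_scenario()`, `sample_reads()`):
  ground-truth reactor dynamics (10 L SBR, 4 h cycles, SRT 10 d, nominal
  HRT 8 h) and barcoded reads, including a planted boom-and-lysis taxon
  (2% → 30% in 5 d, then 95% killed) whose RsaI T-RF is 484 bp.

A staged command-line pipeline (`run_stage()` / `run_pipeline()`, thin
wrapper in `inst/cli/otudyn-cli.R`) chains
simulate → demux → cluster → fractions → vtrflp → washout → heatmap over
on-disk artifacts with a JSON run manifest.

## Worked example

```r
library(otudyn)

sc    <- default_scenario(n_taxa = 12, reads_per_sample = 150, horizon = 60,
                          n_sampling_points = 12, seed = 7)
truth <- simulate_dynamics(sc$dynamics, sc$reactor, 60,
                          sampling_days = sc$sampling_days)
sim   <- sample_reads(truth, sc$taxa, sc$sequencing, sc$primers)

dm  <- demultiplex(sim$reads, sc$primers)
#> Demultiplexing result: 1800 assigned / 0 unassigned
tab <- cluster_greedy(dm)
#> OTU count table: 12 samples x 12 OTUs; 1800 reads
ser <- compute_fractions(tab)
#> Fraction series: 12 samples x 12 OTUs (CI level 0.95)
#>   top mean fractions: OTU1=14.67%, OTU2=13.50%, OTU3=10.50%, ...
```

All 1,800 simulated reads demultiplex to their true samples and the 12
planted taxa are recovered as exactly 12 OTUs. The boom-and-lysis taxon
(here `OTU5`) collapses at day 45; anchoring the washout curve at the last
observation before the collapse:

```r
call <- detect_selective_recession(ser, "OTU5", t0 = 44, sc$reactor)
print(call)
#> Recession call for OTU5 anchored at day 44 : faster_than_washout
#>  day observed lower upper expected
#>   49     2.67 0.836  6.09    17.79
#>   55     2.00 0.501  5.10     9.76
#>   60     1.33 0.223  4.06     5.92
```

The observed fractions sit far below the 17.8% → 5.9% that wastage alone
would leave: the population was selectively killed, not washed out. Its
rapid rise implies a dominant substrate share, and its predicted terminal
restriction fragment identifies it in a T-RFLP fingerprint:

```r
substrate_share(1.9, 29.9, dt = 5, config = sc$reactor)
#> [1] 0.719  (flag: "ok")
trf_length(sc$taxa$sequence[sc$taxa$taxon_id == sc$focal], TRUE, sc$primers)
#>   trf status
#> 1 484    cut
```

A rise from 1.9% to 29.9% in five days at SRT 10 d requires 72% of the
whole reactor's biomass production; the 484 bp fragment is where the
corresponding peak appears in an RsaI digest.

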