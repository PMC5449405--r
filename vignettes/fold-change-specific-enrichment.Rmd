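---
title: "Fold-change-specific enrichment: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold-change-specific enrichment: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldspec)
```

## The model

`foldspec` formalises a simple observation about stimulus-response
transcriptomes: genes of one functional group often change expression not
just in the same direction but by a similar *amount*. The unit of analysis
is therefore not "differentially expressed vs not" but a **fold-change
interval** — a window on the ranked response-amplitude scale.

Given a directional list of $n$ genes (up- and down-regulated lists are
never mixed), genes are sorted by ascending linear fold-change magnitude
and cut into $q$ quantiles; quantile $k$ spans ranks
$(\lceil (k-1)n/q \rceil,\ \lceil kn/q \rceil]$, so sizes differ by at most
one and the cumulative count after $k$ quantiles is exactly
$\lceil kn/q \rceil$. Ties in fold change are broken lexicographically by
gene id, which makes the partition a pure function of the data — permuting
input rows cannot change any downstream decision. All
$q(q+1)/2$ contiguous quantile unions form the tested intervals; the full
union $(1,q)$ is kept in step 1 and excluded from step 2 (see below).

Both analysis tracks use the same two-step testing scheme, with the
one-sided Fisher exact test throughout — computed as the exact
hypergeometric upper tail $P(X \ge a)$, never a normal approximation:

* **Step 1 (interval enrichment, genome background).** For each gene set
  (or hexamer) and each of the $q(q+1)/2$ intervals, a 2×2 table of
  membership × interval against a genome-wide universe. Bonferroni
  multiplier: (number of sets actually tested) × (number of intervals);
  candidates must reach adjusted $p < \alpha_1 = 0.001$.
* **Step 2 (fold-change specificity, directional background).** Candidates
  are re-tested on the $q(q+1)/2 - 1$ component intervals, with the
  directional DEG list itself as the universe. Multiplier: (candidates) ×
  (component intervals); the set is fold-change-specific when its minimal
  adjusted $p < \alpha_2 = 0.05$, and is then assigned the interval with
  the most significant enrichment.

Step 2 is what distinguishes "enriched among responders" from "enriched in
a *window* of response amplitudes": a set can be overwhelmingly significant
against the genome (step 1) yet spread evenly across the amplitude scale,
in which case no component interval beats the directional background and
the set is not specific.

### Why the full interval is excluded from step 2

On the full interval every one of the set's DEG members is "inside", so the
2×2 table degenerates ($b = d = 0$) and the one-sided $p$ is identically 1
for any set. Testing it would only inflate the Bonferroni multiplier. The
package asserts this identity in its test suite rather than special-casing
it numerically.

### Best-interval assignment

Among component intervals the winner is the minimal adjusted $p$; exact
ties go first to the shorter interval, then to the one starting at the
weaker end. Shorter-first is a deliberate preference for the *tightest*
specificity claim that the data support; the second key only makes the rule
total and deterministic.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `q` | 6 | quantiles per directional list; 3, 4 and 8 are the robustness settings. More quantiles sharpen the windows but shrink per-interval counts. |
| `alpha1` | 0.001 | step-1 threshold on Bonferroni-adjusted p (candidate selection) |
| `alpha2` | 0.05 | step-2 threshold on Bonferroni-adjusted p (specificity) |
| `min_genes` | 2 | minimum set members inside an interval for the pair to be tested in step 1; pairs below it neither enter the results nor (unless the term is tested elsewhere) the multiplier |
| `background` | annotation genes ∪ DEGs | step-1 universe. The historically faithful background of any given study is usually unrecoverable, so the universe is explicit and configurable (e.g. all expressed genes). |
| `upstream_len` | 1500 bp | promoter window upstream of the TSS; the region extends through the annotated 5′UTR |

The step-1 multiplier counts *sets actually tested* (those clearing
`min_genes` somewhere) rather than the full vocabulary — an auditable
choice, logged on every pipeline run; with a fully tested vocabulary the
two coincide. For hexamers the multiplier is always 2080 × intervals, since
the whole canonical vocabulary is tested.

## Promoter and motif conventions

Promoters are `[−upstream_len; end of 5′UTR]`, strand-aware: for each gene
the representative transcript is the mRNA with the lowest-sorting ID, the
5′UTR end is its annotated `five_prime_UTR` boundary, genes without a UTR
fall back to the pure upstream window, regions are clipped at contig edges
(flagged in the per-gene provenance), and promoters are *not* truncated at
neighbouring genes. Coordinates are converted to 0-based half-open on read
(GFF3 is 1-based closed).

Hexamers and their reverse complements are one variant; the canonical
representative is the lexicographically smaller of the pair under
A < C < G < T, giving $(4096-64)/2+64 = 2080$ classes of which 64 are
palindromic. Enrichment uses gene-level *presence* (≥ 1 occurrence),
the standard reading of a gene-level 2×2 design; occurrence counts are
available (`scan_hexamer_presence(counts = TRUE)`) without any
faithfulness claim attached. Scanning one strand with canonicalisation is
mathematically equivalent to scanning both strands for presence; windows
containing `N` simply match nothing.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` defaults encode the study conditions the package was
validated under: 789 up- and 659 down-regulated genes, linear fold changes
truncated to 1.5–88 (up) and 1.4–143 (down), $q = 6$. Magnitudes are drawn
from a truncated log-normal (`meanlog = log 3`, `sdlog = 1.2`) — a
heavy-tailed shape matching those ranges; any strictly positive
distribution would serve, and truncation by inverse-CDF avoids probability
mass piling up at the clip boundaries. Planted terms place
$\operatorname{round}(\pi s)$ of their $s$ members uniformly inside the
target rank interval and the rest uniformly among the same direction's
remaining DEGs — which is exactly the configuration that reconstructs the
worked 2×2 example (a 108-gene set with 96 members inside a 263-gene
interval of 789 genes: table 96, 12, 167, 514; fractions 88.9% vs 33.3%).
Planting on *rank* intervals rather than raw fold-change thresholds matches
how the pipeline itself stratifies. Background terms draw uniformly from
the whole universe, and non-DEG genome genes receive annotations and
promoters too, so step-1 backgrounds are realistic. Synthetic promoters
are i.i.d. ACGT with configurable GC (default 0.36, a plant-promoter-like
composition; the closed-form presence check uses GC 0.5 where the formula
assumes uniform composition).

What the generator does **not** model: correlated term memberships (real GO
terms nest and overlap), ontology structure (propagation is tested on
hand-built DAGs instead), non-uniform promoter composition (CpG/TATA
structure, repeats), positional motif preferences, and any dependence
between fold change and annotation beyond the planted effect. Passing
recovery tests therefore demonstrates that the *procedure* finds what it
defines as fold-change-specific structure under controlled conditions —
not that any particular biological dataset will yield the same term lists.

## Numerical and degenerate-input choices

* The Fisher tail is computed by `phyper` (exact in double precision); the
  test suite checks it against an independent `choose()`-based enumeration
  to 10⁻¹² on random tables with universes up to 200.
* Bonferroni adjustment is `min(1, m·p)`; adjusted values never fall below
  raw ones.
* Degenerate margins (empty set in the universe, set = universe, $a = 0$)
  all resolve to $p = 1$ through the hypergeometric identity rather than
  special-case code.
* DEGs missing from a supplied background are added to it with a warning
  (dropping them silently would bias the margins); DEGs without promoters
  are excluded from both margins of the motif tests, with a warning,
  *before* partitioning.
* Annotation propagation is a transitive closure over `is_a`/`part_of`
  with cycle detection (the error names one offending cycle); it is
  idempotent, so re-propagating closed annotations is safe.
* Result TSVs print doubles with 17 significant digits so that
  write-then-read round-trips are bit-exact.

## Benchmark problem sizes

The packaged simulations use desk-scale sizes chosen so every property is
measurable with comfortable statistical margins: type-I control uses 500
null annotations (400 DEGs, 50 terms, 2000-gene universe); term recovery
uses 20 replicates of the 1200-gene / 50-background-term / π = 0.85
configuration; hexamer recovery uses 20 replicates of 600 DEGs among 3000
genome promoters with 60% vs 10% planted presence; the robustness grid
re-runs recovery at $q \in \{3,4,6,8\}$ with π = 0.9 on single-quantile
targets. The hexamer-recovery fixture uses 300 bp promoters: at 1500 bp a
given hexamer class already occurs by chance in
$1-(1-2/4096)^{1495} \approx 52\%$ of random promoters, which would swamp
a planted 60%-vs-10% insertion contrast at these gene counts, whereas at
300 bp the chance floor is ≈ 13%. The null for the hexamer family-wise
error is simulated directly on presence (i.i.d. Bernoulli, 10%
everywhere), since presence is the statistic the test consumes.

## Known limitations

* Bonferroni control is deliberately conservative; a false-discovery-rate
  variant would flag more sets but is intentionally not offered inside the
  faithful two-step mode.
* Step-2 tests across intervals of one set are strongly dependent (nested
  intervals share genes); Bonferroni remains valid but conservative under
  this dependence.
* The best-interval assignment reports a single window even when several
  overlapping windows are nearly equally significant; consult the full
  per-interval table (`$per_interval`) when the point assignment matters.
* Promoter extraction trusts the GFF3's representative-transcript and UTR
  annotations; alternative TSSs are not modelled.
* With very small directional lists (n comparable to q) single quantiles
  hold only a couple of genes and step 2 has little power; the partition
  refuses n < q outright.
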