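---
title: "Targeted variant detection by k-mer walking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted variant detection by k-mer walking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmwalk)
```

## The model

`kmwalk` treats variant discovery as a graph problem over k-mer space. The
evidence is a *canonical k-mer count table*: every k-long window of every
read, collapsed across strands by taking the lexicographic minimum of the
window and its reverse complement, mapped to its occurrence count. The
query is a *target sequence* chosen by the user; its own k-mers form a path
graph (linear when all are distinct), and any variant with at least k
bases of intact flank on both sides must appear as an alternative walk that
departs this path after a shared k-mer and re-enters it at another.

Three assumptions underlie the approach:

1. **k-1 overlap as linkage.** Two k-mers overlapping by k-1 bases are
   taken as evidence that some molecule carries their union. Read-level
   co-occurrence is *not* checked (see Limitations).
2. **Linearity of the target.** If a target repeats one of its k-mers the
   walk is ambiguous; such targets are rejected with the smallest
   linearizing k reported, and `audit_targets()` measures how much of a
   sequence catalogue is usable at a given k.
3. **One event per walk.** Each emitted walk is interpreted as a single
   contiguous event; co-occurring events on the same haplotype interact
   only through the zero-coverage filter (below).

## Walking

The search is depth first, seeded at every target k-mer. At a node, the
four suffix extensions are counted (canonical lookups; absent k-mers count
0). A candidate survives only if its count is strictly greater than the
count threshold `c` (default 5) **and** strictly greater than `P` times the
best competing sibling extension at that node (default `P` = 0.05). The
sibling-ratio reading of `P` is a design decision: "a fraction of the
alternative k-mer count" is interpreted locally, at each branching node,
against the strongest alternative — this makes a 4% branch competing with
a 96% reference path die at `P` = 0.05 and survive at `P` = 0.01, the
behaviour the thresholds exist to control. A branch terminates the first
time it touches any target k-mer (upstream re-entry is what a tandem
duplication looks like) and is abandoned once it carries more than `s`
non-target k-mers (default 500). The step limit, not the read length, caps
detectable duplication size: branch k-mers spanning a duplication junction
need only k-long windows from individual reads, so a 60-bp duplication is
recovered from 50-bp reads.

Revisiting a branch k-mer is allowed (bounded by `s`), which keeps short
repeats walkable; a `max_walks` cap (default 1000) truncates pathological
repeat-rich targets with a prominent warning.

### Walk selection

All deduplicated walks are placed in a union graph where target edges weigh
0.01 and branch edges 1.0. Walks are selected greedily in increasing total
weight — ties broken lexicographically on the assembled sequence, so output
is deterministic — until every observed branch edge is covered. On
single-event graphs this is exactly the minimal-path explanation; on
multi-event graphs the greedy cover may order outputs differently from an
exhaustive shortest-path enumeration, but covers the same edges.

## Calling

Each selected walk is diffed against the target by stripping the longest
common prefix and suffix. When prefix and suffix would overlap, the suffix
is clipped: the *prefix anchor wins*. Ambiguous placements (events inside
repeats or homopolymers) therefore collapse to the single placement
adjacent to the end of the matching prefix, which puts a tandem-duplication
insertion immediately after its copied block — precisely the convention the
insertion subtyping needs, since the inserted string is compared against
the equally long flanks on either side of the insertion point: an exact
flank match is an ITD, > 50% ungapped positionwise identity is an I&I,
anything else a plain Insertion. The 50% boundary is exclusive (4/4 ITD,
3/4 I&I, 2/4 Insertion for 4-bp events). Ungapped comparison is a design
choice; no alignment method is implied by the subtype definitions, and the
ungapped rule reproduces the canonical NPM1-type assignments.

### Quantification

The local coverage ratio is `alt / (alt + ref)` where `alt` is the mean
count of the branch k-mers and `ref` the mean count of the target k-mers
strictly between divergence and re-entry. When that span is empty (upstream
re-entries, i.e. duplications), the two target k-mers adjacent to the
junction stand in; when the branch itself is empty (a pure repeat-mediated
jump), the two path k-mers flanking the junction do. `ref = 0` gives ratio
1 (homozygous alternative). Mean-based pooling is a deliberate choice —
min- or junction-based variants would be noisier at the same coverage — and
is validated by the 4%-mixture scenario reporting a ~4% ratio.

### Filters

* `zero_coverage_target`: some target k-mer *outside* the divergent span
  has count 0. Such walks can be spillover from a related transcript
  sharing subsequences with the target, so they are hidden by default; but
  the same flag also hides a real event co-occurring with a homozygous SNV
  elsewhere on the target, which is why `keep_filtered` re-surfaces flagged
  rows with the flag visible rather than discarding them.
* `below_ratio`: local coverage ratio below `P`.

A target whose own path is fully covered and yields no walks produces an
explicit Reference call (reference-expression denominators need it); a
target with zero-coverage k-mers and no walks is reported as not expressed.
Variant-mode targets (fusion junctions, partial tandem duplications)
invert the logic: full coverage of the target's k-mers confirms the
encoded event, and alternative walks — which then represent wild type or
alternative isoforms — are reported through the same pipeline.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `k` | 31 | bp | window length; larger k needs longer targets and reduces effective depth, smaller k raises false reconstruction risk |
| `c` (`count_threshold`) | 5 | count | minimum branch k-mer count, exclusive; suppresses sequencing-error chains |
| `P` (`ratio_threshold`) | 0.05 | fraction | sibling-ratio gate during walking and ratio filter on calls; lower to 0.01 for rare subclones or biased allelic expression |
| `s` (`max_steps`) | 500 | k-mers | branch length cap; bounds detectable duplication/insertion size |
| `L` (`min_count`) | 2 | count | minimum stored table count; drops k-mers seen in a single read |
| quality threshold | 10 | Phred | windows containing a base below it are not counted; 0 disables. The Phred-10 reading of the upstream counter's quality flag is a recorded decision, not an external fact |

## The simulator and what tests show

`scenario()` generates self-contained fixtures for nine event classes
(SNV, 4-bp insertion, deletion, indel, short and long ITD, fusion, 4%
mixture, ITD-with-downstream-homozygous-SNV). Conditions: random 240-bp
target regions with deterministic mutation sites, 50-bp reads at 200×
total coverage split equally between haplotypes, 0.5% substitution error,
uniform Phred-40 qualities (an optional low-quality tail exercises the
quality filter). The 4% mixture uses 75-bp reads at 1500× so that the
minority branch clears `c` with margin at its 4% share. Haplotypes are
embedded in read-length transcript flanks, because targets interrogate
regions *inside* expressed transcripts: without flanks, coverage ramps to
zero at the target boundary (only reads starting exactly at base 1 cover
the first k-mer), which would spuriously trigger the zero-coverage filter
— an artifact of truncated templates, not a property of the method.

The simulator emulates substitution errors only (indel errors behave the
same way through the `L` and `c` gates: isolated low-count chains), no
splicing, no expression heterogeneity, no fragment-size structure, and no
read pairing (pairs are irrelevant to k-mer counting). Passing the
recovery suite therefore shows that counting, walking, classification and
filtering are correct under clean mixtures at realistic coverage; it does
not certify behaviour under splice-variant interference or
paralog-induced spillover, which is exactly the situation the
zero-coverage filter exists to intercept.

Test and acceptance problem sizes are the package's own choice: 20 seeds
per scenario, 200 random toy instances (k ≤ 5, targets ≤ 15 bp) for the
exhaustive walk-enumeration oracle, and 50 random read sets for the naive
recount oracle — small enough to run in a couple of minutes, large enough
that every event class and both threshold regimes are exercised at every
seed.

## Numerical and degenerate-input choices

* Strictly-greater comparisons throughout (`count > c`, identity `> 0.5`),
  matching the definitions of the thresholds.
* Canonical form: lexicographic minimum under A < C < G < T; comparisons
  are pure-ASCII and locale-independent.
* Dump interchange uses the two-column text dialect only, keys sorted, so
  save→load round-trips byte-exactly; loading defensively merges a key and
  its reverse complement if both appear.
* Tables are held fully in memory (plain hashed environment): targets are
  short and querying is dominated by table residency, so a disk-backed
  store would buy nothing at this scale.
* Result TSVs have a fixed column order, 4-decimal ratios and a
  deterministic row order (target, position, notation), so identical
  inputs produce identical bytes.
* Targets must be N-free and at least 2k−1 bp; both violations are errors,
  not silent fixes.

## Known limitations

* **Read dependency is ignored.** A walk is a chain of k−1 overlaps; no
  check confirms that single reads support consecutive branch k-mers.
  Lowering k raises the risk of chimeric reconstructions; the requirement
  that walks begin and end on target k-mers is the main guard.
* **Single event per walk.** A homozygous SNV downstream of an ITD hides
  the ITD behind the zero-coverage filter (visible with `keep_filtered`);
  editing the target or re-running with the SNV incorporated is the
  recovery path.
* **Strand folding at small k.** Canonical tables cannot distinguish a
  k-mer from its reverse complement, so at toy scales (k ≤ 5) a walk can
  step onto the reverse strand of the target itself and produce fold-back
  paths. At k = 31 the probability of such coincidences is negligible, but
  toy demonstrations must choose fold-back-free sequences.
* **Near-period duplications.** A duplication shorter than k whose unit
  coincidentally extends its period by a few bases creates a k-mer cycle
  admitting composite double-copy walks alongside the true event;
  duplications longer than k are immune (their cycles pass through target
  k-mers and are cut by first-touch termination).
* Insertion subtypes are assigned by ungapped identity; gapped near-
  duplications may be labelled Insertion rather than I&I.
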