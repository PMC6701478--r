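# kmwalk

Targeted variant detection in raw, unaligned sequencing reads by k-mer
walking over a canonical k-mer count table.

## The problem

Clinically important events in hematological cancers — FLT3 internal tandem
duplications (ITDs), NPM1 4-bp insertions, DNMT3A R882 substitutions, fusion
transcripts such as NUP98–NSD1 — are awkward for alignment-based callers:
duplications can approach or exceed the read length, and fusion junctions do
not exist in the reference. `kmwalk` sidesteps alignment entirely. The user
supplies a short *target sequence* covering the region of interest; the
sample's reads are reduced to a table of canonical k-mer counts; and variants
are discovered as alternative paths through k-mer space that leave the target
and rejoin it.

## The method

A target of length L is decomposed into its L − k + 1 overlapping k-mers
(default k = 31), forming a linear directed graph when all k-mers are
distinct. A depth-first walk starts at each target k-mer and follows
suffix-overlapping k-mers queried from the count table. A branch is extended
only through k-mers whose count exceeds a fixed threshold *c* (default 5)
**and** exceeds a fraction *P* (default 0.05) of the best competing
extension at the same node; branches that fail to re-enter the target path
within *s* steps (default 500) are abandoned. Each surviving walk is an
approximate local assembly of a variant haplotype sharing both target
extremities. Walks are reduced to a minimal set covering all observed
non-target edges (target edges weighted 0.01, branch edges 1.0), diffed
against the target by common prefix/suffix anchoring, and classified:

* **Substitution** — removed and added strings of equal length;
* **Deletion** / **Insertion** — one side empty;
* **ITD** — inserted string identical to the adjacent target flank;
* **I&I** — insertion with > 50% positionwise identity to the flank;
* **Indel** — insertion adjacent to a deletion.

Each call carries a local coverage ratio alt/(alt + ref) over the divergent
span and a minimum k-mer coverage; calls whose target path has
zero-coverage k-mers outside the divergent span, or whose ratio falls below
*P*, are flagged and hidden unless `--keep-filtered` is given. Targets can
also be supplied in *variant* mode (e.g. a fusion junction): full k-mer
coverage of the target then confirms the expected event.

Because evidence is k-mer counts rather than single reads, a duplication is
detectable whenever its branch fits within *s* steps — the read length is
not a limit (a 60-bp duplication is recovered from 50-bp reads).

## Worked example

Simulate a heterozygous 12-bp ITD, count 31-mers, and call:

```r
library(kmwalk)
cmd_simulate("itd_short", "demo", seed = 4)
cmd_count("demo/reads.fq", "demo/table.txt", k = 31)
cmd_find("demo/targets.fa", table_path = "demo/table.txt", cfg = run_config())
```

which prints (alt_sequence column truncated here):

```
1384 reads -> 494 canonical 31-mers (min count 2) -> demo/table.txt
sample  target         type  position  genomic_position  removed  added         notation       ratio   min_coverage  filters  alt_sequence
sample  tgt_itd_short  ITD   111       NA                         ACGTCCAAAGAA  /ACGTCCAAAGAA  0.5233  33            PASS     GTCAAATTGCC...
```

One ITD call: the 12-bp string `ACGTCCAAAGAA` is inserted at target position
111 as an exact copy of the preceding 12 bases, at a local coverage ratio of
0.52 (heterozygous) with every k-mer on the alternative path seen at least
33 times. The same pipeline is available from a shell via the installed
`exec/km` script (`km simulate`, `km count`, `km find`, `km audit`).

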