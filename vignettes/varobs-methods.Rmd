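---
title: "Counting local variant observations: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting local variant observations: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varobs)
```

## The problem

After a rare-disease exome or genome has been called and annotated, thousands
of candidate variants remain. The least biased way to shrink that list is
population frequency: variants common in *any* population are very unlikely to
cause a rare Mendelian disorder. Public catalogs cover single nucleotide
variants (SNVs) and small indels well, but they miss two things a sequencing
center sees every day: variation specific to the local population, and
recurrent artifacts of the local wet-lab/caller pipeline. For structural
variants (SVs) the situation is worse — inconsistent calling makes public SV
frequencies unreliable altogether.

`varobs` maintains a *local observations database*: every case (a family or a
single individual) the lab sequences is counted into a store, and any future
query VCF can be annotated with how many previous cases carried each variant.
Filtering at, say, 1% local frequency then removes both locally common
variation and recurrent artifacts. The store updates continuously — cases are
added and removed one at a time, never by rebuilding.

## Counting model

**Cases, not alleles.** The unit of counting is the case. A variant seen in
one, two or three members of a trio contributes exactly one observation. This
is deliberate: diagnostic cohorts are enriched for affected individuals and
their carrier relatives, so allele counting would inflate the frequency of
disease alleles; once-per-family counting caps that bias. Consequently the
frequency written by annotation and export is

> `Frq = Obs / n_cases`,

a *case* frequency with the number of loaded cases as denominator, not an
allele frequency. Affected status is read from the PED file but plays no role
in counting.

**Identity of small variants.** SNVs and indels are identified exactly by the
string `chrom_pos_ref_alt`. This requires the input VCF to be decomposed
(exactly one ALT per line) and normalized; multi-allelic lines are rejected
with an error rather than split in place, because splitting inside the loader
would hide non-normalized alleles from the user (a `--skip-bad-records` mode
downgrades this to a logged skip). The `_` separator keeps the key injective:
plain concatenation could not tell chromosome "1" at 2,300 from chromosome
"12" at 300.

**The GQ gate.** By default a variant line is loaded only if at least one
individual both carries the alternative allele and has genotype quality
strictly above 20. "That same individual" matters: a confident homozygous
reference call in the mother does not rescue a dubious heterozygous call in
the child. A threshold of 0 disables the gate entirely, including for calls
with no GQ at all; any positive threshold treats a missing GQ as failing. The
homozygote counter is likewise driven only by passing individuals: a line is
flagged homozygous when some individual with a passing call is `1/1`
(hemizygous calls written `1` are carriers but never homozygotes — no ploidy
inference is attempted).

**Reversibility.** Every case document records exactly which observation
documents and clusters it touched, with the contributed positions. Deleting a
case therefore decrements counters and position accumulators exactly, removes
documents that reach zero, and restores the store to its previous dumped
state. Duplicate case ids are refused before any counter is touched, so
re-running a load script is harmless.

## Structural variant clustering

SV breakpoints wobble between samples and callers, so exact keys do not work.
Instead each SV is reduced to a type plus two endpoint coordinates (position A
from CHROM/POS; position B from INFO/END, POS + |SVLEN|, or the mate
coordinate of a break-end ALT), and the store groups similar SVs into
clusters on the fly:

* A cluster is an SV type, two running-mean endpoint positions, and a fixed
  padding interval around each endpoint.
* An incoming SV **matches** a cluster when the types agree, the chromosome
  pair agrees, and *both* endpoints lie within the cluster's interval of the
  corresponding mean. Among several candidates the **closest** wins, with
  distance the sum of the two endpoint offsets (ties go to the
  earliest-created cluster, making replays deterministic).
* On a match, the member count and the exact integer position accumulators are
  updated — means are always the exact arithmetic mean of all members, stored
  as sums plus a count so that dump/restore cannot drift. On no match, a new
  cluster is founded at the SV's own positions.

**Padding.** The interval is 2 kb for variants longer than 10 kb and 10% of
the length for smaller ones (rounded half away from zero, floor 1 bp). The
boundary is strict: a variant of exactly 10,000 bp takes the 10% branch
(1,000 bp). Interchromosomal variants have infinite length and always get the
2 kb interval. Both knobs (`sv_max_pad_bp`, `sv_small_frac`,
`sv_large_threshold_bp`) are store parameters: wide enough to absorb caller
noise, narrow enough not to merge distinct events, and tunable per data
source. They are frozen into the store at creation; the CLI refuses a later
load under a conflicting padding policy because clusters built under two
geometries would not be comparable.

**The interval never changes** after the cluster is founded — it derives from
the founding SV's length. Growing it with the mean length would make matching
depend on membership history in a way that is impossible to reason about or
to reverse.

**Insertions** typically have END equal to POS, so a fractional interval of a
1 bp span would collapse to nothing; for INS records the length (and hence
the padding) comes from |SVLEN| and both endpoints sit at POS.

**Paired records.** Inversions and translocations are often emitted as two
break-end lines. Both mates of an intrachromosomal adjacency normalize to the
same ordered endpoint pair (and interchromosomal mates to the same ordered
chromosome pair, digits compared numerically, other names lexicographically),
so the pair lands in one cluster — as two observations, one per VCF line. No
deduplication is attempted: callers are assumed to represent the same
biological event the same way in every sample, so recurrence counting remains
consistent even when the count unit is the record rather than the event.

**Order sensitivity, honestly.** Sequential clustering is not
order-invariant in general: an adversarial chain of SVs, each within the
interval of its neighbour only, can end in different cluster counts under
different load orders. The package does not hide this; its tests assert the
guarantees that actually hold — well-separated events (pairwise farther than
twice the maximum padding) never merge under any order, jittered re-calls of
one event (within a quarter interval) always coalesce to one cluster, means
always equal the brute-force member means, and the whole sequential process
replays an independent reference implementation exactly.

## Sample-identity profiles

Loading the same individual under two case ids would double-count every one
of their variants. Besides the case-id check, the store can fingerprint
samples: genotypes at a small panel of sites are classified as hom-ref / het /
hom-alt / missing, and two profiles are compared by the fraction of
concordant calls over sites non-missing in both. A comparison needs at least
10 jointly called sites to mean anything; at or above 0.95 concordance the
sample is considered a re-upload. Because close relatives share much of a
profile, profiling is advisory by default (a warning) and only refuses the
load under `--check-profile`. The packaged panel
(`profile_panel_synthetic.tsv`) is synthetic and matched to this package's
simulated genome; production deployments should substitute a panel of common,
well-genotyped sites for their genome build (TSV with columns
chrom/pos/ref/alt).

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` provides the package's test bed and the input to the
database-size experiment. Its defaults are fixed study conditions, chosen
once to mirror a small diagnostic service at desk scale:

* **220 cases** — 200 eligible for databases plus 20 held out for annotation,
  a ~1/4-scale version of a background-of-hundreds / test-set-of-tens split;
  25% of cases are trios, the rest singletons.
* **200 shared SNV sites** whose carrier counts follow a 1/i spectrum (the
  neutral site-frequency shape), so most shared variants are rare and a few
  are common — the regime in which a frequency filter has something to do.
* **20 private SNVs per case**, the irreducible private variation a database
  can never filter.
* **30 recurrent SV events** with breakpoints jittered uniformly within ±25%
  of each event's padding interval, emulating caller imprecision, plus **5
  private SVs per case**. Event loci are spaced ≥ 1 Mb apart so distinct true
  events cannot fall within one another's padding.
* **GQ ~ uniform 30–99 with a 5% low-quality (5–20) fraction**, so the GQ
  gate is exercised without dominating the counts.

Everything is deterministic per seed, and a truth table records each
variant's true carrier set and each recurrent SV's identity.

The generator deliberately omits linkage disequilibrium, demography, mutation
spectra, genotype-error correlation and caller-specific artifact structure.
Passing tests on this cohort therefore demonstrates the *counting and
clustering machinery* — conservation, reversibility, cluster recovery under
jitter, and the qualitative direction of the size effect — not any real-data
percentage. The filtered fractions it produces depend directly on the chosen
spectrum and private-variant load and should not be read as predictions for
a real cohort.

## The database-size experiment

`size_experiment()` rebuilds the classic design: hold out test cases, build
databases of increasing size from the remaining pool, annotate the test cases
against each, and record the fraction of their variants at or above the 1%
frequency cutoff (i.e. removed as common). Within a replicate the databases
are nested — the 50-case database extends the 10-case one — which mirrors a
continuously growing store and pairs the curves across sizes. Across 20
replicate draws the mean filtered fraction increases with database size with
shrinking increments, the diminishing-returns shape expected when ever rarer
variants need ever larger denominators to be seen at all. The absolute level
is a property of the synthetic spectrum; only the shape is the claim.

## Numerical and storage choices

* Cluster means are kept as exact sums plus counts; matching uses the
  real-valued mean, and dump/restore round-trips the sums losslessly (they
  are integers well inside double precision).
* Exported SV positions round half *down* (a mean of 100200.5 is emitted as
  100200), documented here because VCF has no fractional positions.
* Exported and annotated frequencies are written with 4 significant digits;
  stored counts are always integers.
* The store is an embedded document store: R environments keyed by variant
  key, cluster id and case id, dumped as a directory of JSON-lines files
  (`cases.jsonl`, `snv.jsonl`, `sv_clusters.jsonl`, `meta.json`) with
  deterministic document order and field order, so dumps diff cleanly and
  byte-identity is meaningful (load timestamps are the only varying field).
  Case-id lists inside documents are dumped sorted, which also makes the
  final SNV-side state independent of case load order.
* Export sorts records by a deterministic natural chromosome order (numeric
  names ascending, then others lexicographically); no "chr" prefix
  harmonization is attempted anywhere — chromosome names are exact strings,
  and a query VCF in a different dialect simply annotates nothing, which the
  annotate report makes visible.
* Degenerate inputs: an empty store exports a header-only VCF; an SV record
  with neither END nor SVLEN is an error at coordinate time (annotation
  skips such records with a count rather than failing the whole file);
  non-positive lengths are errors.

## Problem sizes used by the test suite

The packaged tests run cohorts of 3–220 cases and clustering instances of up
to 50 SVs (200 random instances against a brute-force reference; permutation
tests on sets of 4 and 8). The acceptance-style checks use the default
220-case cohort with 20 replicates of the size experiment. These sizes were
chosen as the smallest at which every claimed property is actually
discriminating — cluster recovery, order invariance, concavity of the size
curve — while keeping the whole suite comfortably interactive.

## Known limitations

* Sequential clustering is order-sensitive for pathological breakpoint
  chains (documented above); no re-clustering pass exists to repair it.
* No reciprocal-overlap matching: two deletions sharing 95% of their span but
  with distant breakpoints are different clusters by design.
* Frequencies use the case denominator; hemizygous and mosaic genotypes are
  not modelled.
* The profile mechanism is a simple concordance check, not a kinship
  estimator; siblings can exceed the threshold on a small panel, which is why
  enforcement is opt-in.
* Single-writer semantics: concurrent loads into one store directory are not
  supported (readers of a dumped store are always consistent).
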