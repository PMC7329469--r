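# varobs — a local observation database for genomic variants

`varobs` keeps track of every variant observed in the sequencing cases a lab
processes — SNVs, small indels and structural variants (SVs) — so that
rare-disease analyses can filter out locally common variation and recurrent
pipeline artifacts that public frequency catalogs miss. It is aimed at
clinical genomics and core-facility bioinformaticians who joint-call families
(or singletons) and need a continuously updatable background frequency
resource: cases are added or removed one at a time; the database is never
rebuilt.

## The model in brief

* A **case** is one family or singleton upload (VCF + PED). Each variant line
  counts **once per case**, no matter how many family members carry it — the
  guard against enrichment of pathogenic alleles in affected families. The
  reported local frequency is `Frq = Obs / n_cases`.
* **SNVs/indels** are identified exactly by the key `chrom_pos_ref_alt`
  (decomposed, normalized input required; multi-allelic lines are rejected).
  Each observation document tracks `obs_count`, a homozygote count and the
  contributing case ids. By default only calls with genotype quality
  `GQ > 20` (in the carrying individual) are loaded; `--gq-threshold 0`
  disables the gate.
* **SVs** are matched approximately. An SV is its type plus two endpoints
  (position A = CHROM/POS, position B = END / POS+|SVLEN| / break-end mate).
  The store clusters similar SVs on the fly: a cluster keeps running-mean
  endpoints and a fixed padding interval — 2 kb for variants larger than
  10 kb (and all interchromosomal variants, whose length is infinite), 10% of
  the length for smaller ones. An SV joins a cluster when type and chromosome
  pair agree and both endpoints fall within the interval of the cluster
  means; with several candidates it joins the **closest** (sum of endpoint
  offsets). Cluster membership count over total cases is the local SV
  frequency.
* A **genotype-profile** check (concordance over a site panel) can catch the
  same individual re-uploaded under a new case id.

## Worked example

```r
library(varobs)

vcf <- read_vcf(system.file("extdata", "example_trio.vcf", package = "varobs"))
vcf
#> <vcf_data> 4 record(s), 3 sample(s)
#>   categories: INDEL=1, SNV=2, SV=1

ped <- read_ped(system.file("extdata", "example_trio.ped", package = "varobs"))
store <- store_new()
load_case(store, ped, snv_vcf = vcf)
#> loaded case FAM1: 3 snv, 1 sv observations (1 new clusters); 0 gq-filtered, 0 rejected

store
#> <obs_store> 1 case(s), 3 SNV/INDEL document(s), 1 SV cluster(s)
#>   gq_threshold=20, sv padding: 2000 bp (>10000 bp), 10% below
```

The trio carries an SNV at 1:240360 that is homozygous in the child, so the
observation document shows one observation (once per family) of which one is
homozygous:

```r
get_observation(store, snv_key("1", 240360, "G", "C"))[c("obs_count", "hom_count", "case_ids")]
#> $obs_count
#> [1] 1
#> $hom_count
#> [1] 1
#> $case_ids
#> [1] "FAM1"
```

The 40 kb deletion became a cluster with the fixed 2 kb endpoint interval:

```r
cluster_table(store)[, c("sv_type", "chrom_a", "mean_a", "mean_b", "interval_bp", "obs_count")]
#>   sv_type chrom_a mean_a  mean_b interval_bp obs_count
#> 1     DEL       3  1e+06 1040000        2000         1
```

`annotate_vcf(query, store, out)` decorates a query VCF with
`Obs`/`Hom`/`Frq` INFO fields (SNVs by exact key, SVs through the same
cluster matching, read-only); `export_vcf(store, out, which = "snv")` writes
the whole database as a frequency VCF for use with tools like vcfanno.
`store_dump()` / `store_restore()` persist the store as a directory of
JSON-lines files.

## Command line

The same operations are available from the shell via `exec/varobs`
(installed under the package's `exec/` directory), which persists the store
in a `--db` directory between calls:

```sh
varobs load --db obs.db --variant-file fam1.snv.vcf --sv-variants fam1.sv.vcf --family-file fam1.ped
varobs annotate --db obs.db --in query.vcf --out query.annotated.vcf
varobs export --db obs.db --out local_freq.vcf --kind snv
varobs cases --db obs.db
varobs delete --db obs.db --case-id fam1
```

Exit status is 0 on success, 1 for usage/state errors (e.g. the case already
exists), 2 for malformed data.

## Synthetic cohorts and the size experiment

`generate_cohort()` simulates a family cohort with shared SNVs on a power-law
carrier spectrum, private variants, and recurrent SVs with jittered
breakpoints (deterministic per seed, with a truth table).
`size_experiment()` holds out test cases, builds nested databases of
increasing size from the rest, and reports the fraction of test-case variants
filtered at a frequency cutoff — reproducing the diminishing-returns growth
of filtering power with database size. See the methods vignette
(`vignettes/varobs-methods.Rmd`) for the model, parameter rationale and
limitations.

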