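# motubar

Paired-end COI metabarcoding of host–parasitoid communities, as a tested R
package.

## The problem

Caterpillars and sawfly larvae are attacked by parasitoid wasps and flies
that develop inside their hosts. Reconstructing who-eats-whom normally
means rearing thousands of larvae and identifying hard-to-tell-apart
specimens morphologically, or Sanger-barcoding each individual. COI
metabarcoding identifies host *and* parasitoid(s) from one mixed tissue
sample in a single MiSeq run — but the ~658-nt COI barcode is longer than
2×300 bp reads, so the mates of a pair never overlap and most standard
amplicon pipelines (which merge pairs) do not apply.

`motubar` implements the full workflow for this non-overlapping setting:

* **demultiplexing** by 7-nt MIDs (≤ 1 mismatch) with run-based quality
  truncation (cut before the first run of > 3 bases with Q ≤ 20; mates
  < 100 nt drop the pair);
* **de-novo chimera screening** with a two-parent breakpoint model over
  abundance-ordered uniques;
* **greedy centroid clustering** at 97% identity into MOTUs (molecular
  operational taxonomic units), with per-sample singleton removal;
* **dual-read consensus classification**: each mate is searched
  independently, only references matching *both* mates are retained,
  forward/reverse identities are averaged, hits within 0.5 points of the
  best average vote, and the assignment is the deepest rank where ≥ 50% of
  retained hits agree on the full lineage prefix — with an LCA fallback
  against a secondary reference set for clusters without a COI match;
* **evaluation**: mock-community recovery (≥ 97% identity over ≥ 100 nt
  against per-specimen Sanger barcodes), a three-method
  identification-success comparison via k-sample equal-proportions
  chi-square tests, and a BIN-versus-morphospecies reference-library
  completeness audit;
* **synthetic data**: a generator for stratified reference libraries, mock
  community designs (dominant host, rare parasitoids, bacterial symbionts,
  contaminants), and error-bearing paired reads with a full truth manifest,
  so the whole pipeline is testable without downloads.

The core statistic of the comparison layer is the k-sample test of equal
proportions: with pooled success rate p̂ = Σsᵢ/Σnᵢ, the statistic
χ² = Σᵢ [(sᵢ − nᵢp̂)²/(nᵢp̂) + ((nᵢ−sᵢ) − nᵢ(1−p̂))²/(nᵢ(1−p̂))] on k − 1
degrees of freedom, without continuity correction. Sequence comparison is a
single shared definition: semi-global alignment (free terminal gaps,
+1/−1/−2 scoring), identity over aligned columns, always paired with a
minimum-overlap guard of min(100 nt, sequence length).

## Worked example

```r
library(motubar)

# 1. Write a seeded synthetic mock-community dataset (5 samples,
#    14 insect taxa, host = 80% of each sample, 0.1% error, 2% chimeras)
dir <- file.path(tempdir(), "mock")
ds <- simulate_dataset(dir, seed = 7, reads_per_sample = 1000,
                       error_rate = 0.001, chimera_rate = 0.02)

# 2. Run the full pipeline against the simulated reference library
cfg <- pipeline_config(
  inputs = list(r1 = file.path(dir, "reads_R1.fastq"),
                r2 = file.path(dir, "reads_R2.fastq"),
                mids = file.path(dir, "mids.tsv"),
                ref_fasta = file.path(dir, "refs.fasta"),
                ref_tax = file.path(dir, "refs_tax.tsv"),
                fallback_fasta = file.path(dir, "fallback.fasta"),
                fallback_tax = file.path(dir, "fallback_tax.tsv"),
                barcodes_fasta = file.path(dir, "barcodes.fasta"),
                specimens = file.path(dir, "specimens.tsv")))
res <- run_pipeline(cfg)

res$motus
#> <motu_set: 19 MOTUs, 4905 reads, 5 samples>
table(res$motu_table$category)
#>       contaminant              host        parasitoid putative_symbiont
#>                 2                 4                10                 3
res$recovery
#> Recovery: 32/32 individuals (100.0%), 19/19 taxa (100.0%)
```

All 14 designed insect taxa come back as MOTUs with species-correct
lineages (4 host + 10 parasitoid), the 3 bacterial symbionts are flagged
`putative_symbiont` via the LCA fallback, and the plant/beetle spike-ins
land in `contaminant`.

The packaged benchmark tables drive the comparison and audit layers:

```r
t1 <- load_fixture_tables("table1")
m <- matrix(t1$n_success, nrow = 3, byrow = TRUE,
            dimnames = list(unique(t1$method), unique(t1$level)))
compare_methods(m, 22)
#>     level      chi2 df    p_value
#> 1  family 2.0307692  2 0.36226307
#> 2   genus 5.1150000  2 0.07749824
#> 3 species 0.4962406  2 0.78026607

library_completeness(load_fixture_tables("table2"))
#> parasitoid: 465 specimens, 91 morphospecies, 104 BINs
#>   % BINs assigned: family 94.2, subfamily 75.0, genus 59.6, species 39.4
#> host: 330 specimens, 97 morphospecies, 108 BINs
#>   % BINs assigned: family 100.0, subfamily 100.0, genus 98.1, species 90.7
```

No identification method differs significantly from the others at any rank
(all p > 0.05), and the audit shows the familiar asymmetry: ~91% of host
BINs resolve to species against the local reference library, but only ~39%
of parasitoid BINs do.

## Package layout

| Path | Contents |
| --- | --- |
| `R/synth.R` | reference-library / mock-design / read simulators |
| `R/io.R`, `R/lineage.R` | FASTA/FASTQ/taxonomy/MOTU-table IO, lineage model |
| `R/preprocess.R` | MID demultiplexing, quality truncation, length filter |
| `R/seq_compare.R`, `src/align.cpp` | shared identity definition, k-mer prefilter |
| `R/cluster.R` | dereplication, chimera screen, greedy clustering, singletons |
| `R/classify.R` | dual-read consensus, LCA fallback, Sanger best-hit |
| `R/evaluate.R` | recovery scoring, proportion tests, library audit |
| `R/pipeline.R`, `R/cli.R` | orchestration, config, CLI dispatcher |
| `vignettes/motubar-methods.Rmd` | methods and design notes |

See the methods vignette for the scientific rationale behind every
threshold and the limits of what the synthetic benchmark establishes.
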