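# virotax

Viral contig triage and taxonomic classification with calibrated marker
profile HMMs.

## The problem

Metagenomic assemblies mix viral contigs — free phages, eukaryotic
viruses, and prophages embedded in host contigs — with abundant cellular
DNA, and viruses share no universal marker gene that would support a
16S-style taxonomy. A practical route is a library of protein profile
HMMs in which each model is *taxon-informative*: its hits separate one
viral taxon from all others by bit score. `virotax` implements the
computational core of such a workflow for people building or evaluating
viral annotation pipelines:

1. **Marker calibration** — from a homology-search hit table
   (model x sequence x taxid x bit score), decide at which rank
   (genus → subfamily → family → order) a model is informative and derive
   per-model bit-score cutoffs. With `S1` the minimum best-score inside
   the target taxon and `S2` the maximum best-score outside it:

   ```
   GA_seq = TC_seq = S1
   GA_dom = TC_dom = S1 - 3   if (S1 - 3) > S2, else S1
   NC_seq = NC_dom = S2       (omitted when no competing taxon exists)
   ```

   The cutoffs are written into HMMER3 model headers (`GA`/`TC`/`NC`
   lines) so `hmmscan --cut_ga` applies them natively.

2. **Taxon statistics** — per-taxon CDS count means and standard
   deviations from assembly reports, descendant-aggregated marker counts,
   and the taxon-specific ratio `TSR = min(1, n_markers / mean_CDS)`,
   which scales classification stringency by marker density.

3. **Contig triage** — combines VirSorter categories, VirFinder
   score/p-value and PPR-Meta classes into high-confidence (HC),
   low-confidence (LC), putative-prophage (PP) or excluded verdicts
   after a 1.5 kb length filter, and excises prophage regions.

4. **Taxonomic voting** — per contig, gated marker hits (one per CDS)
   vote at each rank, finest first. A candidate taxon is accepted when
   its hit proportion is at least `0.6 x TSR` **and** the contig's CDS
   count does not exceed `mean_CDS + 2 * sd_CDS` for that taxon;
   otherwise the vote escalates to the next rank.

5. **Benchmarking** — truth-labels contigs from nucmer `show-coords`
   alignments (viral iff ≥ 70% of the length is covered at ≥ 90%
   identity, merged-interval union) and scores predictions with
   precision / recall / F1.

6. **Synthetic fixtures** — seeded generators for every input format
   (lineage TSV / NCBI dmp taxonomy, curation hits, assembly tables,
   FASTA, GFF3, hmmscan domain tables, predictor tables, coords files)
   with planted ground truth, so the full pipeline runs offline.

## Worked example

```r
library(virotax)

tree <- taxonomy_tree(
  taxid  = c("O", "F", "SF", "G", "H", "t1", "t2", "t3"),
  name   = c("Caudo_order", "Drexlerviridae", "Tempevirinae",
             "Tlsvirus", "Hanrivervirus", "sp1", "sp2", "sp3"),
  rank   = c("order", "family", "subfamily", "genus", "genus",
             "species", "species", "species"),
  parent = c("O", "O", "F", "SF", "SF", "G", "G", "H"))

hits <- data.frame(model_id = "VMRK00001", seq_id = sprintf("s%d", 1:4),
                   taxid = c("t1", "t1", "t2", "t3"), evalue = 1e-12,
                   full_score = c(61.2, 44.0, 55.4, 40.1))
curate_markers(hits, tree)
#>    model_id  rank taxon   S1   S2 GA_seq GA_dom TC_seq TC_dom NC_seq NC_dom
#> 1 VMRK00001 genus     G 55.4 40.1   55.4   52.4   55.4   52.4   40.1   40.1
```

Per-taxid best scores inside genus `G` are {61.2, 55.4} and the best
competitor (`H`) reaches 40.1, so the model is informative at the genus
rank with `S1 = 55.4`, `S2 = 40.1`; the domain cutoff is trimmed by 3
bits because that does not cross `S2`.

```r
st <- compute_taxon_stats(
  data.frame(assembly_id = sprintf("a%d", 1:4),
             taxid = c("t1", "t1", "t2", "t3"),
             cds_count = c(52, 60, 56, 48)),
  curate_markers(hits, tree), tree)
st[st$taxon %in% c("G", "SF"), ]
#>   taxon      rank mean_cds   sd_cds n_assemblies n_markers        tsr
#> 1     G     genus       56 4.000000            3         1 0.01785714
#> 2    SF subfamily       54 5.163978            4         1 0.01851852

vote(data.frame(cds_id = sprintf("c1_%d", 1:5), model_id = "VMRK00001",
                taxon = c(rep("G", 4), "H"), rank = "genus",
                confidence = "high"),
     n_cds = 54, st, tree)[c("outcome", "deciding_rank", "taxon",
                             "proportion")]
#> $outcome       "classified"
#> $deciding_rank "genus"
#> $taxon         "G"
#> $proportion    0.8
```

Four of five informative hits support genus `G` (proportion 0.8 ≥
0.6 × 0.018) and the contig's 54 CDS fit within 56 + 2·4, so the contig
is classified at the genus rank.

```r
metrics(list(tp = 13, fp = 1, tn = 206, fn = 4))
#> $precision 0.9285714
#> $recall    0.7647059
#> $f1        0.8387097
```

## Command line

```sh
inst/scripts/virotax simulate --seed 1 --out fixtures/
inst/scripts/virotax curate   --hits fixtures/curation_hits.tsv \
    --taxonomy fixtures/taxonomy.tsv --out markers.tsv
inst/scripts/virotax stats    --assemblies fixtures/assemblies.tsv \
    --markers markers.tsv --taxonomy fixtures/taxonomy.tsv --out stats.tsv
inst/scripts/virotax triage   --fasta fixtures/contigs.fasta \
    --virsorter fixtures/virsorter.csv --virfinder fixtures/virfinder.tsv \
    --pprmeta fixtures/pprmeta.csv --out triage/
inst/scripts/virotax classify --domtbl fixtures/scan.domtbl \
    --markers markers.tsv --stats stats.tsv \
    --taxonomy fixtures/taxonomy.tsv --cds fixtures/cds.gff3 --out class/
inst/scripts/virotax bench    --coords fixtures/alignments.coords \
    --fasta fixtures/contigs.fasta \
    --predictions triage/triage_assignments.tsv --out bench/
```

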