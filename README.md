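# ctyper

Typing a bacterial population by the leader end of its CRISPR array.

CRISPR loci record a chronological history of encounters with phages and
plasmids: new spacers are inserted at the leader end, old ones persist at
the trailer end. Deep amplicon sequencing of the leader-end fragment
therefore resolves a natural population — for example a bloom-forming
*Microcystis* population under phage pressure — into coexisting **CRISPR
genotypes (CTs)**, each defined by a shared ordered repertoire of
leader-end spacers, and tracks their relative abundances through time.

`ctyper` is an R package for that analysis, from raw paired-end FASTQ to
genotype and diversity tables:

1. **Read processing** — sliding-window quality trimming (window mean below
   a Phred threshold cuts the read), mate-specific length filters, a
   global ≥ Q20-over-80%-of-bases filter, and overlap-based pair merging
   (minimum 60 bp, maximum 301 bp overlap at ≥ 90% identity; disagreements
   resolved by base quality).
2. **Clustering** — greedy incremental clustering of merged amplicons at
   95% identity with 90% length coverage; downstream stages work on
   cluster representatives weighted by cluster size.
3. **Spacer extraction** — direct-repeat detection by mismatch-tolerant
   Hamming scan; spacers are the inter-repeat segments, numbered from the
   leader (position 1 = newest).
4. **Spacer dictionary** — unification of spacer sequences into numbered
   identities allowing up to 6 mismatches against the canonical, seeded by
   a reference catalog so catalog spacer IDs stay stable.
5. **CT typing** — assignment by the shared order of leader-end spacers
   against a disjoint reference catalog; arrays with ≥ 3 novel spacers
   found new CTs; singleton arrays and 1–2-novel-spacer arrays are
   discarded, ambiguous (multi-CT) arrays are reported, never resolved by
   majority.
6. **Variant classes** — within each CT, arrays are classified as
   `origin` (contiguous prefix of the reference repertoire), `new_plus`
   (leading novel spacer(s) then the prefix), `proto` (contiguous block
   starting at position ≥ 2 — the ancestral state), or `others`
   (deletions, internal novelties).
7. **Diversity** — Shannon index H = −Σ pᵢ ln pᵢ, bias-corrected Chao1
   S₁ = S_obs + F₁(F₁−1)/(2(F₂+1)), and analytic rarefaction
   E[Sₙ] = Σᵢ (1 − C(N−Nᵢ, n)/C(N, n)).
8. **Protospacer search** — exhaustive ungapped scan of spacer canonicals
   against user-supplied phage/plasmid FASTA, both strands, reported as
   matches/length.
9. **Simulator** — a fully seeded generator of reference catalogs,
   per-sample (CT, variant) compositions, and paired-end FASTQ with
   per-read ground truth, so every stage is testable without deposited
   data.

## Worked example

```r
library(ctyper)
cfg <- pipeline_config()                    # all thresholds, documented defaults
sim <- simulation_config(n_reference_cts = 6L, n_samples = 3L,
                         n_read_pairs = 3000L, rng_seed = 42L)
gen   <- generate_catalog(sim, cfg)         # disjoint spacer repertoires
comp  <- simulate_composition(gen, sim)     # per-sample (CT, variant) mix
reads <- synthesize_reads(gen, comp, sim, "sim", cfg)
res   <- run_pipeline(reads$samples, gen$catalog, cfg, "run")

print(res$pooled, digits = 3)
#>    ct weight fraction_total fraction_assigned dominant
#> 1 CT1   1010         0.3367            0.3388     TRUE
#> 2 CT2    761         0.2537            0.2553     TRUE
#> 3 CT3    538         0.1793            0.1805     TRUE
#> 4 CT4    316         0.1053            0.1060     TRUE
#> 5 CT5    232         0.0773            0.0778     TRUE
#> 6 CT6    124         0.0413            0.0416     TRUE
```

`fraction_total` is each genotype's share of all amplicon weight (the
denominator includes unassigned/discarded reads); `dominant` flags CTs
above the 1% threshold. The simulated dominant genotype was planted at
32% and is recovered at 33.7% — within multinomial sampling noise of the
realized truth. Per-sample diversity and the leader-end variant
trajectory of the dominant CT:

```r
print(res$diversity, digits = 4)
#>   sample S_obs F1 F2 chao1 shannon_H
#> 1    S01     6  0  0     6     1.606
#> 2    S02     6  0  0     6     1.606
#> 3    S03     6  0  0     6     1.524

report_tables(res, ct = "CT1")$fig4
#>   sample ct_label origin new_plus   proto others total_weight
#> 1    S01      CT1  0.538    0.412 0.00664 0.0432          301
#> 2    S02      CT1  0.501    0.440 0.00000 0.0587          341
#> 3    S03      CT1  0.519    0.438 0.00543 0.0380          368
```

The planted variant mix for CT1 was origin 0.50 / new_plus 0.45 /
proto 0.004 / others 0.046; the recovered per-sample fractions oscillate
around it, the way leader-end variant prevalences oscillate in a real
bloom season. `report_tables()` also emits pooled genotype fractions with
rare CTs binned (`fig1`), dominant-CT trajectories (`fig2`), and pooled
variant fractions per CT (`fig3`).

A command-line interface wraps the same stages:

```sh
Rscript -e 'ctyper::ct_cli()' simulate --outdir sim --seed 7 --pairs 2000 --samples 3 --cts 8
Rscript -e 'ctyper::ct_cli()' run --samples sim/samples.tsv --catalog sim/catalog.txt --outdir run
Rscript -e 'ctyper::ct_cli()' report --rundir run --ct CT1
Rscript -e 'ctyper::ct_cli()' validate-catalog --catalog sim/catalog.txt
```

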