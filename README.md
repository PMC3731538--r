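# mircurate

Biogenesis-guided curation of mammalian microRNAs from small RNA
sequencing read stacks.

Small RNA libraries are full of sequences that merely look like miRNAs:
tRNA/rRNA/snoRNA turnover fragments, repeat-derived reads, and mapping
artifacts. Genuine canonical miRNAs betray themselves through their
biogenesis: Drosha excises a 60–100 nt stem-loop precursor, Dicer cuts it
into a ~22-nt miRNA/miRNA\* duplex with 2-nt 3′ overhangs, and the
sequencing reads over a real precursor therefore pile into **two sharp
~22-nt peaks spaced 10–20 nt apart** whose sequences pair into the
predicted hairpin with the RNase-III overhang stagger. `mircurate` turns
these observations into a reproducible accept/reject decision tree for
candidate precursors, and organizes what survives into named mature
products, seed families, genomic cistrons, and expression profiles.

The decision tree applies, in fixed order (first failure wins):

1. pooled read count < 50 → `INSUFFICIENT_READS`
2. distinct read sequences < 5 → `LOW_NONREDUNDANT`
3. \> 30 genomic copies and no cistron membership → `EXCESS_MULTIMAP`
4. ≥ 50% overlap with a non-miRNA ncRNA annotation, or a non-templated 3′
   CCA (tRNA acceptor end) on the dominant read → `NCRNA_OVERLAP`
5. dominant read is the reverse complement (≤ 2 edits) of an accepted
   mature → `COMPLEMENT_ARTIFACT`
6. no bimodal read pattern or failed hairpin/overhang check →
   `NO_PATTERN_OR_FOLDBACK`
7. neither cistron membership nor EST evidence → `NO_EXPRESSION_EVIDENCE`
8. otherwise `ACCEPTED`

Reads are aligned to flank-extended precursors at ≤ 2 edits (mismatch,
insertion, deletion — the budget that absorbs non-templated 3′ A/U
additions and G→A editing); multi-mapping reads count fully at each
lowest-error location. Secondary structure comes from ViennaRNA's
`RNAfold` when available, with a built-in deterministic base-pair
maximizer as fallback. Arm products are named by the miRBase-style
convention (`hsa-miR-125b-1`, `hsa-miR-125b-1*`, `-5p`/`-3p` when neither
arm exceeds 80% dominance), families by
`sf-<lowest member>(<size>)`, cistrons (loci within 5 kb, multi-copy
aware) by `cluster-<lowest member>(<size>)`.

A seeded simulator ships with the package and generates fully labeled
cohorts — prototypical hairpins plus tRNA-like, low-depth, and
repeat-derived decoys — so the entire workflow is testable end to end
without any external data.

## Worked example

```r
library(mircurate)

co  <- make_cohort(sim_params(seed = 42,
                              decoy_mix = c(prototypical = 4, trna_like = 2,
                                            low_depth = 2, repeat_like = 2)))
res <- curate_cohort(co$candidates, co$reads, co$annotation, co$est)
res
#> <curation_result: 10 candidates, 4 accepted>
#>           accepted    EXCESS_MULTIMAP INSUFFICIENT_READS      NCRNA_OVERLAP
#>                  4                  2                  2                  2
```

Ten simulated candidates: the four prototypical hairpins are accepted, the
two tRNA decoys fail on annotation overlap plus their non-templated CCA,
the two shallow loci fail the 50-read floor (42 and 43 reads), and the two
repeat loci (BED copy counts > 30, no cistron) are set aside. Accepted
precursors yield named products with their arm tallies:

```r
res$products[1:2, c("name", "precursor_name", "designation", "read_count")]
#>         name precursor_name designation read_count
#> 1  sim-miR-1      sim-mir-1      mature        443
#> 2 sim-miR-1*      sim-mir-1        star         57
```

443/500 arm-assigned reads (89%) sit on the mature arm, so the duplex gets
mature/star designations. The classic curation display shows why the
locus was accepted — the log4 coverage histogram with two sharp peaks, and
the top five reads per arm by error tier:

```r
cat(render_alignment_view(res$stacks[["sim-mir-1"]],
                          co$candidates[["sim-mir-1"]],
                          res$arms[["sim-mir-1"]]))
#> >sim-mir-1 chrSim:9426-9483(+) reads=500 distinct=32
#> CCTAATGTATGAGT...CAATCCCCGTAACGAGCCGCCCAAAAAAAAAAAAAAGGCGGCTCGTTACGGGGATTGGA...
#>                   :######################||.          ||||||||||||||||||||||:.
#> # errors: 0
#>                    AATCCCCGTAACGAGCCGCCCA x256 [mature]
#>                    AATCCCCGTAACGAGCCGCCCAA x43 [mature]
#>                    ...
#>                                           GGCGGCTCGTTACGGGGATTGG x35 [star]
#>                                           ...
```

(Lines shortened here; the view is monospace over the full 257-nt extended
sequence.)

A thin command-line front end wraps the same functions:

```sh
inst/scripts/mircurate simulate --seed 1 --out cohort/
inst/scripts/mircurate decide --precursors cohort/precursors.fa \
    --bed cohort/loci.bed --genome cohort/genome.fa \
    --reads cohort/reads.tsv --annotation cohort/annotation.bed \
    --est cohort/est.tsv --out report.tsv
```

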