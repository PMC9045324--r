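# replicontools

Validation and comparison of **linear bacterial replicon** assemblies —
built for the giant linear plasmids (GLPs) and linear chromosomes of
high-GC actinomycetes, where three recurring analyses are normally done
by hand:

1. **Virtual rare-cutter digestion with pulsed-field gel (PFGE) band
   matching.** An assembly is digested *in silico* (DraI, AseI, BfrI,
   XbaI built in; any site^offset accepted) and the predicted fragment
   multiset is matched one-to-one against observed gel band sizes under a
   relative-error cap, with sub-threshold fragments (default < 30 kb)
   modelled as invisible and near-equal fragments allowed to co-migrate
   into one band.
2. **Collapsed terminal-inverted-repeat (TIR) resolution.** When an
   assembler collapses a long TIR, the reported contig carries the repeat
   once — at twice the read depth of the unique central region. From a
   per-base coverage track the package segments the depth profile
   (median smoothing + binary segmentation), calls the end-anchored
   2× arm, and reconstructs the true plasmid: length **2R + C** and full
   sequence `arm + central + revcomp(arm)`.
3. **Rearrangement and SNP mapping between near-identical plasmids.**
   Unique 21-mer anchors are merged into maximal exact matches, chained
   into synteny blocks, and the block layout is classified into typed
   events (insertion, deletion, inversion, translocation, duplication)
   plus SNP/short-indel calls with codon-level coding effects
   (synonymous / missense / nonsense / frameshift / in-frame).

Around these sit transposase-density summaries and a seeded permutation
test for breakpoint–mobile-element association, plus a fully seeded
**synthetic-data module** (replicons, planted CDS cassettes, planted
rearrangements, coverage tracks, gel observations — all with exact truth
tables) so the entire pipeline is testable offline.

## Worked example

Build a TIR plasmid with a 167,000-bp arm and a 22,563-bp central region,
collapse it as an assembler would, and recover the full plasmid from the
collapsed contig's coverage profile:

```r
library(replicontools)

src <- generate_replicon(190000, gc_target = 0.70, seed = 101, id = "glp")
sim <- make_inverted_repeat_plasmid(src, R = 167000, C = 22563)
trk <- simulate_coverage(sim$collapsed$length, c(1, 167000),
                         baseline = 40, noise = 0.15, seed = 101)
(seg <- segment_coverage(trk))
#>    start    end mean_depth
#> 1      1 167000   80.02159
#> 2 167001 189563   39.99680
call_collapsed_repeat(seg, contig_id = sim$collapsed$id)
#> <collapsed_repeat_call> glp_collapsed: left arm 1-167,000 (R=167,000),
#>   central 167,001-189,563 (C=22,563), ratio 2.00, full length 356,563 bp
```

The 189,563-bp contig segments into a 167-kb region at depth ~80 and a
22.6-kb region at ~40; the arm/central ratio 2.00 sits in the accepted
band [1.6, 2.4], so the contig is called as a collapsed repeat and the
plasmid reconstructs to 2·167,000 + 22,563 = 356,563 bp.

Digest the full plasmid and match it against a simulated gel:

```r
frags <- digest_replicon(sim$full, "DraI")
sort(frags$fragment_bp, decreasing = TRUE)
#> [1] 123601 123601  35017  25880  24232  24232
obs <- simulate_gel_observation(frags, size_error = 0.02, seed = 7)
match_bands(frags, obs, rel_tol = 0.06)
#> <band_match_report> 3 matched (3 bands), 0 predicted unmatched,
#>   0 observed unmatched, 3 below visibility
```

Note the mirrored fragment sizes (123,601 and 24,232 each appear twice —
fragments internal to one arm always come in pairs on a TIR plasmid) and
the three fragments under 30 kb that leave no band, exactly the situation
a PFGE validation has to tolerate.

Mapping a derived plasmid against its parent works the same way at any
scale:

```r
cmp <- compare_replicons(parent, derived)   # anchors, blocks, events, snps
cmp$events                                  # typed, 1-based loci
cmp$snps                                    # substitutions + short indels
```

## Scope

Raw-read basecalling/assembly, annotation generation, BUSCO, BGC
prediction and telomere reconstruction are out of scope; the package
consumes standard FASTA / GenBank flat file / GFF3 / bedGraph inputs.
See the vignette (`vignettes/linear-replicon-analysis.Rmd`) for the
models, parameter defaults, resolution limits and simulator assumptions.
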