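# introtrace

Tracing a donor allele through a rice breeding program, computationally:

* **KASP genotype calling** — call `allele1_hom` / `het` / `allele2_hom` /
  `no_call` from endpoint FAM/HEX/ROX fluorescence by exact 1-D clustering
  on the dye-ratio angle, and summarise mutant-haplotype carriers across a
  variety panel.
* **Trio origin classification** — assign every SNP of an improved line to
  donor / receptor-parent / heterozygous / unknown origin against its two
  parents' call sets on a common reference.
* **Introgression blocks** — windowed donor-SNP density along each
  chromosome and maximal-run segmentation into donor (or unknown-origin)
  blocks, exported as bedGraph/BED.
* **Marker design** — codominant InDel markers, CAPS markers via in-silico
  restriction digest (IUPAC motifs, e.g. HinfI G^ANTC), allele-specific KASP
  primer sets, in-silico PCR, and codon-level CDS variant annotation.
* **Synthetic data with ground truth** — trio genomes with planted
  introgression segments and clustered unknown-origin SNPs, fluorescence
  plates, and marker amplicon pairs, all pure functions of (config, seed).

The motivating use case is the ALS (acetolactate synthase) herbicide
tolerance allele S627N (CDS 1880 G→A): screen a panel for carriers, confirm
the donor by genome-wide origin classification, locate the introgressed
segments, and design PCR markers for selection.

## The core statistic

For each SNP site where the improved line *I* is non-reference, with donor
*D* and receptor *R* genotypes for the same alternate allele (absent parent
records count as hom-ref), the origin category is decided in fixed
precedence:

```
het(I)                  -> heterozygous
hom_alt(R), same allele -> receptor
hom_alt(D), same allele -> donor
otherwise               -> unknown
```

Category counts and half-up 2-decimal percentages reproduce published
partition tables; windows of the donor category (fraction ≥ 0.5, ≥ 10 SNPs,
≥ 2 consecutive windows by default) yield the introgression blocks.

## Worked example

```r
library(introtrace)

# simulate a trio with a donor block around the target locus on chr2
cfg <- trio_sim_config(seed = 7)
tr  <- simulate_trio(cfg)
tab <- classify_trio(tr$improved, tr$donor, tr$receptor)
tab$summary
#>      category count percent
#>         donor  3114   11.88
#>      receptor 21172   80.75
#>  heterozygous   105    0.40
#>       unknown  1829    6.98
#>         total 26220  100.00

track  <- windowed_density(tab, cfg$genome, window = 1e5, step = 5e4)
blocks <- call_blocks(track, category = "donor", table = tab)
blocks[1:2, ]
#>   chrom   start     end n_snps mean_fraction category
#> 1  chr1 1401485 1899256    512         0.904    donor
#> 2  chr2  801153 1199293    420         0.887    donor

# KASP screen: 194 varieties, 18 homozygous mutant
g  <- c(rep("allele1_hom", 176), rep("allele2_hom", 18))
pl <- simulate_plate(plate_sim_config(g, marker_id = "S627N", seed = 3))
calls <- call_genotypes(normalize_plate(pl$plate), marker_id = "S627N")
table(calls$call)
#> allele1_hom allele2_hom
#>         176          18
```

Each called block is a run of windows dominated by donor-specific SNPs; its
`n_snps` is re-counted from the per-site table and its bounds are clipped to
the outermost donor SNP. The 18/194 screen corresponds to a carrier
frequency of 9.28% (`summarize_panel()`).

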