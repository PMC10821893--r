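# mitoquant

Quantification of tandem-fluorescent mitophagy reporters, cytosolic
mtDNA readouts, and the statistics that compare them across groups —
as an installable, tested R package.

## The problem

Aging tissue shows altered mitophagy and, downstream of mitochondrial
damage, mtDNA escaping into the cytosol where it triggers cGAS/STING
inflammation. Two imaging assays carry most of that evidence:

- **mito-QC mitolysosome counting.** The mito-QC reporter is a
  mitochondria-targeted mCherry-GFP tandem. GFP is quenched in acidic
  lysosomes, so cytoplasmic mitochondria are mCherry⁺GFP⁺ while
  mitochondria under lysosomal degradation (*mitolysosomes*) are
  mCherry⁺GFP⁻. Counting them from confocal z-stacks is two-channel
  mask arithmetic: preprocess (rolling ball 25 px, Gaussian blur
  σ = 1 px), threshold both channels with one batch-frozen threshold
  each, subtract the GFP⁺ mask from the mCherry⁺ mask, and count 3D
  connected components. The GFP⁺ mask volume is the mitochondrial
  mass.
- **Cytosolic DNA focus calling.** Anti-DNA staining is cleared of
  organellar signal by zeroing it inside the union of the TOMM20⁺ and
  DAPI⁺ masks; the remaining puncta are counted per cell by
  prominence-based maxima detection on the maximal projection.

Around these sit colocalization (Manders overlap coefficient
r = ΣAB / √(ΣA²·ΣB²)), projection MFI and area-fraction readouts,
cytosolic/mitochondrial mtDNA ratios from fraction-resolved qPCR
(R = 2^−(Ct_cyto − Ct_mito), levels normalized to nuclear 18S), and a
normality-gated test policy (Shapiro-Wilk screening → Student's
t / Mann-Whitney U with exact small-sample p, ANOVA with Tukey or
Šidák post-hocs, Spearman's ρ), reporting mean ± s.e.m.

The package implements every pixel-level primitive from scratch
(each one verifiable against a brute-force oracle in the test suite),
composes them into the named procedures, and ships a synthetic-scene
generator that plants mitochondrial networks, mitolysosomes, nuclei
and cytosolic DNA foci with a full ground-truth registry — so the
whole pipeline is testable end to end without any raw data download.

## Worked example

```r
library(mitoquant)

# a synthetic reporter stack with 25 planted mitolysosomes,
# shot + read-out noise at default levels
p  <- sceneParams(seed = 42L, nMitolysosomes = 25L)
sc <- generateReporterStack(p)

# freeze batch thresholds on a reference image, then count
thr <- freezeThresholds(sc$stack, c("mCherry", "GFP"),
                        radius = 25, sigma = 1)
round(thr, 2)
#> mCherry     GFP
#>   45.80   47.16
countMitolysosomes(sc$stack, thr)
#> QuantResult [ count_mitolysosomes ] image: image
#>    n_mitolysosomes = 25
#>    mitochondrial_mass_um3 = 139.08
#>    mitolysosome_volume_um3 = 7.78
```

All 25 planted mitolysosomes are recovered; the mitochondrial mass is
the calibrated volume of the GFP⁺ network mask in µm³.

```r
# a qPCR cohort with a true 10-fold cytosolic mtDNA increase in the
# old group and 0.3-cycle Ct noise
cp <- cohortParams(nPerGroup = 8L, foldChange = 10,
                   ctNoiseSd = 0.3, seed = 42L)
cohortAnalysis(generateQpcrCohort(cp))
#> Cytosolic/mitochondrial mtDNA ratio analysis
#>     gene group n      mean        sem
#>   mt-Nd2 young 8  1.067235 0.09672894
#>   mt-Nd2   old 8 10.423842 1.33874836
#>   mt-Co1 young 8  1.060721 0.11120137
#>   mt-Co1   old 8 10.641436 0.87604740
#>  mt-Cytb young 8  1.079469 0.10841282
#>  mt-Cytb   old 8 10.735058 0.90500053
#>
#> Per-gene fold change (contrast/reference):
#>     gene fold_change                                    test      p_value
#>   mt-Nd2    9.767145 Mann-Whitney U test (two-tailed, exact) 1.554002e-04
#>   mt-Co1   10.032268               Welch t test (two-tailed) 9.902058e-06
#>  mt-Cytb    9.944757 Mann-Whitney U test (two-tailed, exact) 1.554002e-04
```

The configured 10-fold enrichment is recovered per gene, and the test
column records which route the normality-gated policy took for each
gene.

Batch use from a shell goes through the thin wrappers in
`inst/scripts/` (`quantify.R`, `mtdna_ratio.R`, `gstats.R`), which
read YAML configs and CSV manifests and write CSV/JSON results plus a
reproducibility log (package version, config hash, input hashes,
seed).

## Documentation

The methods vignette (`vignettes/mitoquant-methods.Rmd`) describes the
models and assumptions, every tunable parameter with units and
defaults, what the scene generator does and does not emulate, the
numerical edge-case decisions, and known limitations.
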