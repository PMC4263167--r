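# cpmr — Colour Pattern Modelling and dominance analysis for butterfly wings

`cpmr` quantifies whole-wing colour patterns and the genetic dominance
relationships they reveal at a wing-patterning supergene.  It is aimed at
evolutionary biologists working on mimicry polymorphism (e.g. *Heliconius
numata*, where supergene alleles controlling alternative mimetic forms are
brought together in heterozygotes by controlled crosses) and, more
generally, at anyone who needs pixel-level homology across categorical
colour patterns without hand-placed landmarks.

## The method

**Colour Pattern Modelling (CPM)** turns each standardized wing photograph
into a categorical raster over a small set of colour classes (black,
orange, yellow + background), then registers all wings into one model
frame with similarity transforms chosen to maximize a categorical
template-matching score against an average *wing model* — the per-pixel
class-frequency raster over all wings — which is itself rebuilt from the
registered wings and refined recursively.  After convergence, every model
pixel is a homologous trait across specimens.

On the aligned stack the package computes, per allele pair (a, b):

* the genotype **modal patterns** (per-pixel modal colour);
* the surface-based heterozygote trait
  *T* = #(pixels matching modal_a and differing from modal_b) / wing
  surface;
* the **dominance coefficient**
  *h*_raw = (*T̄*_ab − *T̄*_bb) / (*T̄*_aa − *T̄*_bb), normalized to the
  dominant direction so *h* = max(*h*_raw, 1 − *h*_raw) ∈ [0.5, 1]
  (*h* = 1: strict dominance; *h* ≈ 0.5: co-dominance);
* **dominance heat maps** (per-pixel proportions of heterozygotes matching
  the dominant, the recessive, both or neither modal);
* **colour hierarchy** statistics: conformity to a transitive colour
  dominance order (black > orange > yellow), conformity to complete
  dominance of one allele, per-colour-pair expression probabilities and
  colour hierarchy maps;
* **permutation tests** (exact by enumeration for small groups) for group
  contrasts such as sympatric vs parapatric *h*, and the correlation of
  *h* with the phenotypic distance between homozygotes in PCA space.

A synthetic wing generator with known allele patterns, configurable
dominance mechanisms (`colour_hierarchy`, `full_dominance`, `mosaic` with
a programmable dominance fraction) and nuisance transforms provides ground
truth for every stage; see the methods vignette
(`vignettes/colour-pattern-modelling.Rmd`).

## Worked example

Simulate a three-allele crossing experiment under the colour-hierarchy
mechanism and run the full pipeline (categorize → align → phenotype space
→ dominance):

```r
library(cpmr)
cfg <- list(
  out_dir = "runs/demo", seed = 42,
  simulate = list(preset = "demo", n_per_genotype = 4, resolution = 192,
                  mechanism = "colour_hierarchy",
                  pair_class = list("arc/bic" = "sympatric",
                                    "arc/tar" = "sympatric",
                                    "bic/tar" = "parapatric")),
  categorization = list(merge_threshold = 60),
  alignment = list(n_iter = 3, tol = 1e-4),
  analysis = list(n_perm = 999))
run_pipeline(cfg)
read.delim("runs/demo/dominance.tsv")
```

Output (abridged):

```
     pair n_ab  T_aa   T_ab    T_bb     h dominant_allele pair_class
1 arc/bic    4 0.773 0.5351 0.00654 0.690             arc  sympatric
2 arc/tar    4 0.243 0.0593 0.01163 0.794             tar  sympatric
3 bic/tar    4 0.789 0.2426 0.00496 0.697             tar parapatric

hierarchy conformity: 0.948
P(black) where homozygotes differ black vs orange: 0.953
```

Reading the table: `T_aa ≈ 0.77` says the *arc* homozygotes share ~77% of
the wing surface with their own modal where it differs from the *bic*
modal; the heterozygote mean `T_ab = 0.54` sits 69% of the way from the
*bic* homozygote mean toward the *arc* one, giving *h* = 0.69 with *arc*
dominant.  Because these crosses were generated under the colour
hierarchy, 94.8% of informative heterozygote pixel-observations express
the hierarchy-dominant colour, and black wins over orange at 95.3% of the
pixels where the homozygotes disagree in exactly those colours.  The run
directory also contains per-pair heat-map PNGs, PCA scores, transforms,
QC metrics and a provenance record; `qc_report("runs/demo")` flags
outlier specimens (>3 MAD on unresolved pixels, alignment score or
neither-modal fraction).

A thin command-line wrapper is installed at `inst/cli/cpm.R`
(`Rscript cpm.R run --config pipeline.yaml`, plus `simulate`, `qc`,
`permtest`).

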