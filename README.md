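# mitoamp

Kinetic modelling and 3D image quantification of PINK1/Parkin mitophagy
amplification.

During PINK1/Parkin mitophagy, damaged mitochondria are coated with
Ser65-phosphorylated ubiquitin (pS65-Ub), which recruits the autophagy
receptors OPTN and NDP52. Beyond this ubiquitin-dependent route, lipidated
Atg8 proteins (LC3/GABARAPs, "Atg8PE") on the growing phagophore recruit
additional receptors through their LIR motifs — a second, Atg8-dependent
positive feedback loop that amplifies autophagosome biogenesis. `mitoamp`
packages the computational side of studying this amplification, for
systems biologists and cell biologists quantifying selective autophagy:

* **Kinetic model** — a 21-state ODE system coupling the PINK1/Parkin
  pS65-Ub loop and the NDP52/Atg8PE LIR loop. Binding steps follow
  mass-action kinetics (`v = k_on·A·B`, with opposing `k_off`), conversions
  follow Michaelis–Menten kinetics (`v = k_c·E·S/(K_m+S)`) with opposing
  reactions throughout; the mitophagy readout is total lipidated Atg8.
  Variant networks ablate the LIR loop (`LIR_V136S`: association constants
  of the two receptor–Atg8PE binding reactions set to zero), the UBD route
  (`UBD_C443K`) or PtdIns(3)P signalling (`PI3K_INHIBITED`). Simulation
  (stiff ODE integration), bounded least-squares fitting and rate-constant
  robustness analysis are included.
* **3D image quantification** — the automated segmentation workflow for
  confocal stacks: mitochondria by sliding-paraboloid background
  subtraction, Bernsen local thresholding and seeded 3D watershed; foci
  (Atg13/WIPI2b/Atg16L1 puncta) by montage histogram normalization and
  global thresholding; object-based positivity, receptor translocation and
  foci statistics, with all the workflow's standard constants as defaults.
* **mtKeima cytometry gating** — a triangular gate aligned with the
  untreated population's principal axis and translated to enclose 99.8% of
  untreated events; treated samples are read as percent 561 nm-shifted.
* **Synthetic data** — seed-deterministic generators (image stacks with
  tubular mitochondria and punctate foci, model time courses, cytometry
  mixtures) with full ground truth, so every stage runs and is tested
  without external data.

See the vignette (`vignettes/mitoamp-methods.Rmd`) for the model equations,
parameter choices, segmentation semantics and known limitations.

## Worked example

Simulate stimulated mitophagy under wild-type NDP52, the LIR mutant and
PI3K inhibition:

```r
library(mitoamp)

net <- build_default_network()
cmp <- compare_variants(net, c("WT", "LIR_V136S", "PI3K_INHIBITED"),
                        t_end = 7200)
print(cmp$summary, digits = 3)
#>          variant atg8pe_end     auc ratio_end auc_ratio
#> 1             WT        289 1753832     1.000     1.000
#> 2      LIR_V136S        213 1117746     0.735     0.637
#> 3 PI3K_INHIBITED          0       0     0.000     0.000
```

After two hours of simulated depolarization the wild-type network has
lipidated essentially the whole Atg8 pool (289 of 300 nM, after a lag and
switch-like rise). Removing the LIR feedback loop leaves the response
pointwise lower (AUC ratio 0.64); blocking PI3K keeps lipidation at its
(near-zero) resting baseline even though ubiquitin-dependent NDP52
recruitment remains active.

Segment a synthetic confocal field and quantify receptor translocation:

```r
gen  <- generate_image_stack(image_scene(), seed = 1)
rois <- segment_mitochondria(gen$stack, "mito")
rois
#> <roi_set> 12 objects, 8640 labelled voxels
pos <- classify_positive(rois, "receptor", sd_threshold = 10)
translocation_fraction(rois, pos)
#> [1] 33.26   # ground truth: 33.4% of mitochondrial volume positive
```

Build an mtKeima gate on an untreated sample and read a treated one:

```r
untr <- generate_facs_sample(n = 20000, positive_fraction = 0, seed = 1)
gate <- build_mtkeima_gate(untr$sample)
100 * mean(in_gate(gate, untr$sample))
#> [1] 99.8
mix <- generate_facs_sample(n = 20000, positive_fraction = 40, seed = 2)
percent_positive(mix$sample, gate)
#> [1] 40.1
```

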