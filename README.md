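# isletscope

Whole-section stereology of pancreatic islets: unbiased quantification of
endocrine cell mass from calibrated multi-channel fluorescence images.

## The problem

Endocrine cell mass — the area of insulin-, glucagon- and
somatostatin-positive tissue expressed as a percentage of total pancreas
area — is the central quantity in studies of beta-cell loss and diabetes.
The pancreas makes this measurement treacherous: islets range from single
cells to clusters of thousands, they are scattered unevenly, their cellular
composition changes with islet size, and endocrine density differs between
head, body and tail. Classical shortcuts (analyzing a few "islet-rich"
fields, point-counting grids, a single tissue block) each inject a sampling
bias of known direction but unknown size.

`isletscope` is for quantitative histologists and islet biologists. It
implements whole-section analysis — every structure in the section is
segmented and normalized to the manually contoured pancreas area — plus the
classical estimators themselves, so that their bias can be measured against
the whole-section reference on the same data. A synthetic section generator
with complete ground truth makes every stage testable without any specimen.

## What it computes

* **Tissue mask**: the manual pancreas outline minus every exclusion region
  (vessels, ducts, fat) occupying more than 0.05% of the section; all mass
  estimates are normalized to this area.
* **Percent endocrine area**: `100 * endocrine area / pancreas area`, per
  hormone and for the composite mask, after rolling-ball-style background
  subtraction and per-channel thresholding (manual or exact Otsu).
* **Per-islet morphometry**: each endocrine structure, from singlet to large
  islet, gets an identification number, its stained and filled (total) area,
  centroid, perimeter, circularity `4*pi*A/P^2` (1 = perfect circle), and
  Feret diameter (longest distance within the structure).
* **Cell typing**: nuclei are segmented by distance-transform watershed; the
  perimeter of each nucleus is expanded by 1 pixel and the most prevalent
  hormone signal in that perinuclear ring assigns the cell type
  (beta/alpha/delta), with per-islet cell counts.
* **Analytics**: log-binned islet size distributions in cell-equivalents
  (area / 178 um^2), composition-by-size curves with SEM, area-fraction
  curves, and 3-D size/shape scatter data with kNN density coding.
* **Stereology simulations**: point-counting grids (`100 * positive /
  total vertices`), islet-rich panel selection curves, every-nth-section
  designs, block-selection schemes (head/body/tail), and largest-N-islet
  cell-ratio estimates — each compared against the whole-section value.

## Worked example

```r
library(isletscope)

# a synthetic 900 x 900 um section: 14 islets, one vessel-like exclusion
p <- synth_params(frame_um = c(900, 900), n_islets = 14, seed = 11,
                  exocrine_nuclei_per_mm2 = 300,
                  n_exclusions = 1, exclusion_radius_um = c(70, 90))
g <- generate_section(p)

res <- quantify_section(g$section, g$contours,
                        run_config(thresholds = list(insulin = 100, glucagon = 100,
                                                     somatostatin = 100, nuclei = 100)))
print(res)
#> section_summary: 14 islets, 6.528e+05 um^2 pancreas, 3.507% endocrine
#>   nuclei: 305 (132 classified)
```

All 14 planted islets are recovered and the percent endocrine area matches
the generator's ground truth (3.5070%). The islet table carries the
morphometry and per-type cell counts:

```r
head(res$islets, 4)
#>   islet_id endocrine_area_um2 total_islet_area_um2 circularity feret_um count_insulin count_glucagon
#> 1        1                700                  741        0.61     44.0             4              0
#> 2        2                879                  921        0.59     44.6             4              1
#> 3        3                528                  554        0.58     40.2             3              0
#> 4        4               5697                 5956        0.72     95.7            27              6
```

Rows are single structures: islet 4 is a 33-cell islet, 96 um across, with
27 beta- and 6 alpha-cells; its total area exceeds its stained area because
unstained intra-islet pixels are annexed when the structure is filled. The
same section under a classical 25-um point-counting grid gives:

```r
pc <- point_count_estimate(composite_endocrine_mask(res$masks[g$section$hormones]),
                           make_grid(c(900, 900), 25), 1)
#> 31 of 1296 vertices -> 2.39%
```

a single-offset grid estimate of 2.39% against the whole-section 3.51% —
the kind of discrepancy the sampling simulations quantify systematically.

A command-line front end wraps the same functions
(`inst/cli/isletscope.R`, subcommands `synth`, `quantify`, `point-count`,
`panel-bias`, `block-sim`, `top-n-ratios`).

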