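---
title: "Dose metrics and tiered statistics for air-liquid interface aerosol exposures"
author: "alidose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose metrics and tiered statistics for air-liquid interface aerosol exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alidose)
```

## The problem

In air-liquid interface (ALI) toxicology, airway cell cultures are exposed
directly to an aerosol, and the biological response must be related to the
*delivered* dose: how many particles, how much mass, and how much particle
surface area actually landed per square centimetre of the cell layer.  For
nanostructured metal aggregates this is not a single measurement.  The
number concentration and size distribution come from a scanning mobility
particle sizer (SMPS); the relation between a particle's mobility diameter
and its mass comes from a DMA-APM tandem, because fractal aggregates do not
obey the spherical $m \propto d^3$ law; the surface area per unit mass
comes from transmission electron microscopy (TEM) of the primary particles;
and the fraction of particles entering the exposure chamber that actually
deposit on the cultures is measured by counting particles on silica wafers
in scanning electron microscope (SEM) images.  `alidose` implements this
chain end to end, together with the three-tier statistical analysis of the
resulting exposed/control response ratios.

## Models and estimators

### Number size distributions

A distribution is stored as SMPS instruments export it: bin-centre mobility
diameters $d$ (nm) with densities $dN/d\log_{10} D_p$ (#/cm^3 per
log10-decade).  The total concentration is the trapezoid integral of the
density over the $\log_{10} d$ axis; on a uniform log grid this equals the
familiar midpoint sum $\sum_i n_i \, \Delta\log_{10}d$ for interior bins,
with the edge bins carrying half weights so that a flat density spanning
exactly one decade integrates to its own value.

The count median diameter (CMD) and geometric standard deviation (GSTD)
are computed by the moment method: CMD is the geometric mean of the
number weighting and GSTD is $\exp(\mathrm{sd}(\ln d))$.  For a lognormal
distribution the geometric mean equals the median, so the moment method is
exact there, and it is deterministic — no least-squares fitting step whose
convergence would need its own tests.  On grids with at least 48 bins per
two decades the discretization error in CMD and GSTD is below 2% (checked
by round-tripping analytic lognormals through the summary).

A single occupied bin is a legitimate degenerate case (synthetic
monodisperse aerosols); its GSTD is reported as exactly 1.

### The mass-mobility power law

For aggregates formed by diffusion-limited cluster aggregation, single
particle mass follows a power law in the mobility diameter,

$$ m(d_{me}) = k \, d_{me}^{D_{mm}}, $$

with $D_{mm} \approx 2.0$–$2.2$, as opposed to 3 for compact spheres.  The
fit is ordinary least squares on $(\ln d_{me}, \ln m)$, with $d_{me}$ in
metres (SI), so $D_{mm}$ is the slope and $k$ the exponentiated intercept;
the 95% CI on $D_{mm}$ uses the t distribution on the slope standard
error.  Unweighted OLS in log space is the standard estimator for
mass-mobility exponents and matches the multiplicative error structure of
APM mass measurements; nothing in the data motivates orthogonal or
weighted regression, and the choice is recorded here because the estimator
is otherwise a genuinely open design point.  Two-point data give the exact
closed-form slope but no CI; the result is flagged rather than silently
reporting zero-width intervals.

The mass size distribution is the bin-wise product
$dm/d\log_{10}D_p = dN/d\log_{10}D_p \cdot m(d_{me})$, integrated like the
number distribution and converted to mg/m^3 (the TEOM reporting unit;
1 mg/m^3 = 1e-3 µg/cm^3, implemented as a single constant).  For a
lognormal number distribution this pipeline obeys the moment identity
$c_m = c_N \, k \, \mathrm{CMD}^{D_{mm}}
\exp(D_{mm}^2 \ln^2\!\mathrm{GSTD}/2)$, which the tests verify against
independent numeric quadrature.

### Primary particles, Sauter diameter, specific surface area

TEM primary-particle diameters are summarized by the number-, surface-
($d^2$) and mass- ($d^3$) weighted geometric means with multiplicative
spread bounds $\mathrm{GM}/\mathrm{GSD}$–$\mathrm{GM}\times\mathrm{GSD}$.
Whether such summary tables use geometric or arithmetic weighted means is
convention-dependent; geometric means are used because the multiplicative
bounds they imply are the natural spread statement for lognormal-like
samples, and this choice is flagged in the documentation.

The Sauter diameter $d_{va} = \sum d^3 / \sum d^2$ is the diameter whose
surface-to-volume ratio matches the population's, and the specific surface
area follows the sphere convention

$$ \mathrm{SSA} = \frac{6}{\rho \, d_{va}}, $$

with no fractal surface correction: the aggregate surface is modelled as
the sum of its primary-particle spheres.  For lognormal samples the Sauter
diameter obeys the Hatch–Choate conversion
$d_{va} = \mathrm{GM}\exp(2.5 \ln^2\mathrm{GSD})$, used as an independent
oracle in the tests.

The surface-area size distribution of aggregates is
$dSA/d\log_{10}D_p = dN/d\log_{10}D_p \cdot m(d_{me}) \cdot \mathrm{SSA}$,
so the total surface-area concentration factorizes exactly as
$c_{SA} = c_m \cdot \mathrm{SSA}$.  For sintered near-spheres the
geometric surface $\pi d^2$ is used per bin instead, which coincides with
the SSA route when the per-bin SSA $6/(\rho d)$ is inserted.

### Deposition efficiency

Deposited particles on wafer images are counted by the classic chain:
3×3 mean smoothing, thresholding (Otsu's method on the smoothed image by
default, a fixed threshold optionally), and 8-connected component counting
with a minimum component size of 4 px, which rejects the 1–3 px clusters
that wafer-background noise produces.  8-connectivity and Otsu are the
defaults of the widespread imageJ-style workflow this reproduces.  One
caveat is inherent to Otsu: it always splits the histogram in two, so on a
particle-free frame the automatic threshold is meaningless — blank frames
should be processed with a fixed threshold.

Efficiency is estimated per image as the deposited areal density divided
by the areal density of particles entering per insert,
$(\mathrm{count}/A_{img}) \, / \, (c_N v / SA_{insert})$; image values are
averaged within each wafer area, and the chamber estimate is the
unweighted mean ± sample standard deviation across areas.  The exact
normalization of imaged sub-areas to the insert total is not part of any
instrument convention; the flux-ratio form above is the reconstruction
adopted here.  A single scalar efficiency is used; its known size
dependence (tens of percent below 100 nm) is out of scope.

When the chamber's unipolar charger fails, only the fraction of particles
charged at equilibrium (default 0.20) deposits electrostatically, so the
effective efficiency is the linear time weighting
$E_{eff} = E(1-f) + E \cdot q \cdot f$ with $f$ the faulted time fraction
and $q$ the charged fraction.  The endpoint efficiencies are usually known
while the fault timing is not; the formula inverts trivially for $f$.

### Dose metrics

With $v$ the aerosol volume passed over one insert, $SA_{insert}$ the
membrane area and $E$ the deposition efficiency,

$$ N_{dose} = \frac{c_N v E}{SA_{insert}}, \qquad
   m_{dose} = \frac{c_m v E}{SA_{insert}}, \qquad
   SA_{dose} = \frac{c_{SA} v E}{SA_{insert}}. $$

Defaults are $v = 1500$ cm^3 (one hour through one insert),
$SA_{insert} = 0.33$ cm^2 (a 6.5 mm membrane) and $E = 0.36$, all
overridable, including per exposure record (needed for charger-fault
corrections).  A confluent cell layer is assumed, so dose per cm^2 of
membrane equals dose per cm^2 of cells.  The dispatcher resolves the mass
and surface-area pathway from morphology and available inputs — sphere
integration for sintered particles with a bulk density, the mass-mobility
product for aggregates with a fit, the online TEOM concentration
otherwise — and records which pathway produced each number.  A
surface-area dose is reported absent rather than guessed when neither an
SSA nor sphere geometry applies (the silver aggregates are the canonical
case: no primary-particle analysis, hence no SSA).

Two kinds of documented discrepancy arise when recomputing a published
dose table from its own printed concentrations.  First, rows affected by
instrument faults (a charger short circuit, a pressure-induced flow drop)
are only reproducible with their corrected per-row efficiencies, or not at
all from the tabulated inputs; the affected rows are handled explicitly in
the tests rather than by loosening tolerances.  Second, printed inputs are
rounded; recomputed doses can disagree with printed doses by several
percent purely from last-digit rounding of a two-significant-figure
concentration, so the reproduction checks allow half-unit rounding of the
printed input before applying their 5% band.

### Tiered response statistics

Responses are exposed/control ratios.  Tier 1 pools everything for one
endpoint and cell line and applies a two-sided one-sample t test against
1 with a t-based 95% CI; tier 2 repeats this per material (series of a
material are pooled); tier 3 regresses the ratio on a dose metric by OLS
and declares a dose response when the slope's two-sided p is below 0.05.
An ANCOVA compares material-specific slopes against a common slope by the
F test on the dose-by-material interaction.

Choices worth recording: replicate inserts within an exposure level are
treated as independent observations (level-mean aggregation can be done
upstream); ratios are analysed untransformed to mirror the
exposed/control presentation, with a log-scale option; p-values are
reported unadjusted — tiers are descriptive screens, not confirmatory
families — though `p.adjust` can be applied downstream; censored
(below-LOD) observations are excluded from every estimate, and a group
that is entirely censored is flagged non-evaluable instead of contributing
a zero.  Degenerate inputs are flagged, not computed around: fewer than 3
distinct doses makes a regression non-evaluable, a constant sample has no
t statistic, and a single-material table makes the ANCOVA an error.

## The synthetic-data generator

Every input the pipeline consumes can be generated with known ground
truth, from one scenario object so the stages stay mutually coherent.  The
default scenario mirrors a mid-range copper aggregate exposure: a
lognormal aerosol with $c_N = 2.58\times10^6$ /cm^3, CMD 115 nm, GSTD
1.67; a mass-mobility law with $D_{mm} = 2.08$ and 5% multiplicative
lognormal APM noise over 40–360 nm; lognormal primary particles with GM
4.65 nm and GSD 1.19 (the GSD implied, via Hatch–Choate, by the ratio of
the surface- to number-weighted means of the copper sample); a 36%
deposition efficiency; and a linear viability decline of 0.05 per µg/cm^2
with Gaussian noise of 0.1.

Per-bin spectrum noise is Poisson on counts (physical for a counting
instrument) rather than Gaussian on densities.  Wafer images carry bright
non-overlapping disks on a noisy background plus bright collinear 3-px
speck runs; under the counting chain's 3×3 smoothing, only the windows
centred on a run's middle pixel see all three bright pixels, so each run
survives thresholding as a 1–3 px cluster — exactly the noise class the
size floor must reject — and specks are placed so clusters can never merge
into a countable component.

What the generator does *not* emulate, and what passing tests therefore do
not show about real data: multiple-charge and transfer-function artefacts
in SMPS inversions; CPC photometric-mode bias at high concentrations;
size-dependent deposition efficiency; spatial deposition patterns and
aggregate alignment on wafers (real aggregates form ridges and networks
that defeat single-particle counting); TEM measurement error on primary
particles; and any nonlinearity or saturation in the biological response.

## Numerical choices and problem sizes

Integration is trapezoidal on the $\log_{10}$ axis everywhere, so number,
mass and surface-area totals are consistent by construction.  Diameters
cross every interface in nm and are converted to SI only inside the power
law.  Monodisperse spikes place the full concentration in the bin nearest
the requested diameter.  Component labelling uses 8-connectivity via a
pixel-adjacency graph; the test oracle is an independent flood fill.

The validation suite runs at deliberately modest sizes chosen to keep
Monte-Carlo error well inside the asserted tolerances: 1000 replicates for
CI coverage (binomial sd ≈ 0.7 pp at 95%), 2000 replicates for type-I
calibration (sd ≈ 0.5 pp at 5%), $10^5$ draws for Hatch–Choate moment
checks (relative error ≪ 1%), 96–192 grid bins for quadrature checks, and
3×256² px images for counting.

## Known limitations

The package starts from measured or generated diameter lists and spectra;
it does not invert raw instrument data.  The deposition estimate treats
counted wafers as representative of all inserts.  The statistics stage
implements the tier scheme described above — unadjusted p-values, linear
models only; Hill-type nonlinear dose-response models are out of scope.
Reproducing published biological p-values requires the underlying
response data, which are external; the statistical machinery is validated
by calibration and power simulation instead.
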