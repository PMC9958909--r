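---
title: "Methods: models, thresholds and numerical choices in nmrdomain"
author: "nmrdomain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and numerical choices in nmrdomain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nmrdomain` implements the standard desk-level analyses used to
characterize a small protein domain by solution NMR and analytical SEC:
secondary-structure calling from carbon secondary chemical shifts,
flexibility classification from heteronuclear NOEs, binding-site mapping
from fast-exchange titrations, rotational-correlation-time and
apparent-molecular-weight estimation from ^15^N relaxation, and
oligomer-state assessment from a Kav-vs-log(MW) calibration.  This
vignette records the models behind each stage, the tunable parameters with
their defaults and units, and the numerical decisions that were genuinely
open, so that results are interpretable without reading the source.

## Constructs and theoretical masses

Expression constructs are handled in full-length (UniProt) numbering,
1-based and inclusive.  Cloning scars left after tag cleavage (typically
Gly-Ala-Met) are carried as a prefix whose residues take the numbers
immediately preceding the native start, so a "GAM" prefix on a construct
starting at residue 21 is numbered 18-20 and every residue keeps its
full-length coordinate in all downstream plots and reports.

Theoretical masses are sums of *average* residue masses plus one water:
free termini, reduced cysteines, no modifications, no isotope-label mass
shift.  This matches how "theoretical kDa" values are conventionally
quoted for expression constructs even when the NMR sample itself is
^13^C/^15^N-labelled.  Masses are kept at full precision internally and
displayed at two decimals.

The repository bundles `Q14151_synthetic_standin.fasta`, a *synthetic
stand-in* for the full-length SAFB2 sequence: it reproduces the residue
identities documented for the characterized positions (G21, G26, R29,
S31, L33, R45, N46, N52, K53, S54, G68, Q69, D70; G404, N408, W410, N425,
N441, N485, and a single proline in 404-485) but is otherwise invented.
Mass computations on it do not reproduce the published construct masses;
supply the genuine UniProt record for those.

## Secondary chemical shifts

The combined C&alpha;/C&beta; secondary chemical shift is defined as

$$\mathrm{SCS} = \Delta\delta C\alpha - \Delta\delta C\beta,$$

where each &Delta;&delta; is the observed shift minus the residue-specific
random-coil value.  Helix formation moves C&alpha; downfield and C&beta;
upfield, so the difference amplifies both effects into one trace; strands
do the opposite.  For glycine (no C&beta;) and residues with an
unassigned C&beta;, the C&alpha; deviation alone is used.  The bundled
random-coil table is a standard neutral-pH, 25 &deg;C compilation
(id `"wishart1995"`); because the generators and the analysis share the
same table, element calling is insensitive to the specific coil set as
long as one set is used consistently.  No sequence-neighbour corrections
are applied by default; the table lookup is the single point where a
corrected table could be substituted.

Elements are called from maximal runs over *consecutive* residue numbers:
at least **3** residues with SCS strictly above **+1 ppm** make a helix,
at least **4** residues strictly below **-1 ppm** make a strand.  Strict
inequalities are deliberate (a value exactly at the threshold does not
count), and residues missing from the profile break runs, since an
unassigned residue gives no evidence of continuity.

## Heteronuclear NOE flexibility

The steady-state {^1^H}^15^N NOE is the per-residue intensity ratio
I~sat~/I~ref~.  Ratios below **0.5** are labelled `flexible`, above
**0.65** `rigid`; the band in between is reported as `intermediate`
rather than forced into either class.  Ratio uncertainties are propagated
from per-list noise estimates as
&sigma; = |ratio| &middot; &radic;((&sigma;~sat~/I~sat~)&sup2; +
(&sigma;~ref~/I~ref~)&sup2;); peak-fitting software reports errors by
various internal schemes, and this quadrature rule is the package's
stated, reproducible substitute.

The rigid core is the longest stretch of rigid residues in which
interruptions (non-rigid or unobserved) of up to `max_gap = 3` consecutive
residues are tolerated.  The default of 3 reflects that short flexible
stretches inside an otherwise rigid domain (a mobile loop of a few
residues) should not split the core; with stricter gap settings the same
profile decomposes into sub-cores, which is sometimes the more honest
reading for genuinely segmented domains.

## Titrations and chemical shift perturbations

The combined amide CSP uses the conventional 1/5 nitrogen scaling,

$$\mathrm{CSP} = \sqrt{(\Delta\delta N / 5)^2 + (\Delta\delta H)^2},$$

and the same scaled metric serves as the distance for peak matching and
as the 2D vector space (&Delta;&delta;H, &Delta;&delta;N/5) for
trajectory cosines.  CSPs are computed apo &rarr; endpoint (highest
molar ratio); intermediate points are used only for trajectory checks,
where fast exchange predicts collinear motion across ratios.

Significance thresholds are computed from all CSPs in a profile as the
mean, twice the standard deviation, or mean + 2 SD (default).  The
*population* (n-divisor) standard deviation is used, matching common
practice in CSP scripts; the three modes are all first-class and recorded
in reports because figure-legend conventions ("2&times; standard
deviation") are ambiguous about including the mean.  Residues must be
*strictly* above the threshold.

Peak pairing is by residue identity for assigned lists; a greedy
nearest-neighbour mode (smallest scaled distance within `tol`, ties by
lowest residue number) covers unassigned endpoints such as mutant or
pH-shifted spectra.  Pairs moving further than `tol = 0.15` ppm are kept
but flagged as "jumps".

Foldedness is assessed from amide ^1^H dispersion: `folded` requires a
^1^H range above 1.5 ppm *and* a ^1^H standard deviation above 0.35 ppm;
collapsed (unfolded) spectra cluster near the random-coil window and fail
both.  Variant binding is graded over the wild type's significant
residues: the summed-CSP extent ratio is cut at 0.1 (`abolished`) and 0.7
(`reduced` vs `wt_like`), and either non-abolished verdict additionally
requires conserved trajectories (median cosine > 0.8); conserved extent
along different directions is reported as `nonspecific`.

## ^15^N relaxation and correlation times

Per-residue rates come from least-squares fits of
I(t) = I&#8320;e^&minus;Rt^, started from a log-linear regression with a
Levenberg-Marquardt fallback; fit quality is 1 &minus; SSR/SST, rate
errors come from the fit covariance, and non-positive fitted rates are
flagged and excluded downstream.  Flat curves are reported as R = 0 and
flagged rather than fitted.

The correlation time is estimated from the R2/R1 ratio:

$$\tau_c = \frac{1}{2\pi\nu_N}\sqrt{\frac{3}{2}\frac{R_2}{R_1} -
\frac{7}{6}} \quad (\text{default}), \qquad
\tau_c = \frac{1}{4\pi\nu_N}\sqrt{6\frac{R_2}{R_1} - 7} \quad
(\text{classical}),$$

with &nu;~N~ = 0.10136767 &times; the proton frequency.  The two readings
differ only in the constant under the root (7/6 vs 7/4 after factoring).
Validated against the package's own spectral-density oracle (below), the
classical reading stays within ~3% of the true &tau;~c~ over 2-12 ns at
600-700 MHz, while the default reading is accurate to ~5% above ~4 ns but
biased upward by tens of percent near 2 ns, where the smaller subtracted
constant inflates the root argument.  Both are provided because published
work uses both conventions; for small, fast-tumbling domains the
classical reading is the better-behaved choice, and the default is kept
for continuity with the 7/6 convention.  Ratios at or below the root
boundary (7/9, resp. 7/6) raise a domain error: they belong to the
extreme-narrowing regime where the estimator is invalid.

Domain averages are plain means (a 10%-trimmed mean is available for
exchange-contaminated profiles) over residues with valid rates; when a
hetNOE profile is supplied, only rigid residues enter, so flexible
termini do not bias the result.  R1&rho; can stand in for R2 to suppress
exchange contributions and is flagged as such in the result.  Apparent
molecular weight uses the empirical **0.6 ns/kDa** proportionality for
globular proteins near 298 K (6 ns &harr; 10 kDa), exposed as a
parameter.  A relative R2 standard deviation above **50%** flags
chemical exchange.

## SEC calibration

K~av~ = (V~e~ &minus; V~0~)/(V~c~ &minus; V~0~) is fit by ordinary least
squares against log&#8321;&#8320;(MW) over the standards; apparent MWs
invert the line, with extrapolation beyond the calibrated K~av~ range
warned about.  Oligomer state is classified from the apparent/monomer
mass ratio with boundaries at **1.4** and **1.75**: well below 2 because
apparent SEC masses of non-globular or exchanging species scatter
substantially, yet far enough apart that a clean monomer and a clean
dimer land in different classes while exchange-averaged monomer-dimer
mixtures fall in between.  Both boundaries are parameters.

## Synthetic data and what passing tests mean

Every input has a seeded generator with attached ground truth, pure in
(parameters, seed):

* **Titrations** use the exact single-site isotherm
  f~b~ = ((P+L+K~d~) &minus; &radic;((P+L+K~d~)&sup2; &minus; 4PL))/2P
  and the fast-exchange limit (peaks move by f~b~ times the endpoint
  vector).  Defaults: 0.1 mM protein, K~d~ = 0.01 mM, ratios
  0/0.5/1/1.85/4/6; ^15^N jitter is 5&times; the ^1^H jitter so both axes
  contribute equally on the combined scale.
* **Relaxation** rates come from the standard ^15^N dipolar + CSA
  expressions with the model-free spectral density (r~NH~ = 1.02 &Aring;,
  &Delta;&sigma; = &minus;160 ppm, isotropic tumbling); decays are
  mono-exponential with multiplicative noise.  Delay-list presets cover
  the common 9-11-point T1/T2/T1&rho; series.
* **Shift tables** are coil values plus +2.8/&minus;0.4 ppm
  (C&alpha;/C&beta;) in helices and &minus;1.5/+2.0 ppm in strands -
  magnitudes within accepted empirical ranges, chosen as generator
  parameters rather than claims about any particular protein.
* **hetNOE profiles** are a plateau with a 3-residue linear decay to the
  terminal value; **SEC runs** place standards on a known line
  (defaults resemble a 24-mL analytical column with a five-protein
  low-MW kit).

The generators emulate the *geometry* of real data (offsets, isotherms,
exponentials, noise levels) but not spectral artefacts: no peak overlap,
no line-shape or intermediate-exchange effects, no baseline or
chromatogram distortions, and noise is Gaussian and independent.
Recovery statistics quoted by the test suite (planted binders recovered
in &ge;90% of 200 seeded titrations at a 0.02-ppm noise floor; planted
elements within one residue in &ge;95% of seeds at &sigma; = 0.3 ppm)
therefore demonstrate correctness of the algorithms under their stated
models, not performance on crowded experimental spectra.  Test problem
sizes - 40-53-residue chains, 50-peak titrations, 8-10-residue
relaxation sets, 100-200 seeds - were chosen as the smallest sizes at
which these statistics are stable.

## Known limitations

* No K~d~ fitting from CSP isotherms, no line-shape or slow/intermediate
  exchange modelling; trajectory analysis assumes fast exchange.
* No per-residue model-free fitting (S&sup2;, &tau;~e~, R~ex~) and no
  anisotropic diffusion; the &tau;~c~ estimator assumes an isotropic
  rigid rotor, and its default reading should not be trusted below
  ~3 ns (use the classical reading there).
* NMR-STAR support is limited to the `Atom_chem_shift` loop of v3
  entries; everything else in a deposition is ignored with a notice.
* The bundled FASTA is a labelled synthetic stand-in, not the native
  SAFB2 sequence.
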