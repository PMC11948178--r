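---
title: "Methods: ADC biotransformation analysis from intact mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ADC biotransformation analysis from intact mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcbiotx)
```

# The problem

Antibody-drug conjugates (ADCs) change chemically in circulation: the
thiosuccinimide linkage formed by maleimide conjugation hydrolyses (+18 Da),
payloads deconjugate and the freed cysteine thiols pick up a cysteine cap
(+119 Da), and the linker-payload itself can fragment along its bonds.
Intact LC-MS of the immunocaptured ADC reveals these events as mass shifts
on the light and heavy chains, but assigning the deconvoluted peaks by hand
is slow. `adcbiotx` automates the two-step workflow used in practice:

1. **Build a delta-mass library** from the linker-payload structure by
   constrained bond-cleavage enumeration plus a small set of common
   biotransformations.
2. **Match deconvoluted chain masses** against theoretical proteoform
   candidates assembled from the antibody chain sequences, drug load,
   glycans, cysteinylation and the library, then quantify fractional
   abundances over pharmacokinetic (PK) time points.

# Cleavage enumeration

The linker-payload is a molecular graph (`parse_structure()`): heavy atoms
with implicit hydrogens filled by standard valence rules, bonds flagged as
ring bonds by cycle membership (a bond is on a cycle iff it is not a
bridge). The conjugation site is one attachment atom, given as an index or
found by a substructure pattern (`mol_pattern()`, matched by element- and
bond-order-colored VF2 subgraph isomorphism). The built-in
`maleimide_pattern()` maps the maleimide ring **nitrogen**: ring bonds are
never cleaved, so every ring atom identifies the same retained fragment,
and the nitrogen is the one choice that is unique even on a symmetric,
unconjugated maleimide.

`enumerate_cleavages()` considers every subset of one or two non-ring
bonds (configurable up to three). Removing the subset, the product is the
connected component containing the attachment atom - only fragments still
conjugated to the antibody are observable on the intact chain. A subset is
valid only if **every** broken bond touches that component; otherwise the
subset produces the same fragment as a smaller cut and would inflate the
count. Each broken-bond stub on the retained fragment is capped with one
hydrogen (homolysis plus hydrogen transfer, the common convention in
metabolite software; `cap = "minusH"` and `"none"` are available because
commercial tools do not document their choice). Formula-identical products
from different bond sets are kept and flagged rather than merged, since
positional isomers are distinct cleavage hypotheses.

`expand_library()` crosses the cleavage set with the default
biotransformations - hydrolysis (+H2O), oxidative deamidation to the
alcohol (R-NH2 to R-OH, net -NH+O, +0.984 Da) and their combination - and
adds the three parent-only entries, giving `(m + 1) c + m` entries for
`c` cleavages and `m` modifications; the unmodified parent is the
reference conjugate, not a library entry. With the bundled structure's 46
cleavages this yields a 187-entry library. A modification that would drive
an element count negative (deamidating a nitrogen-free fragment) is
skipped with a warning.

## The bundled linker-payload structure

Real ADC linker-payload structures of the class this workflow targets are
proprietary. `synthetic_pbd_linker_payload()`
(`inst/extdata/sg3584_like_synthetic.mol`) is a **synthetic** stand-in: a
maleimide cap, an aliphatic spacer, an N-methyl amide linkage and a fused
aromatic head, in the style of pyrrolobenzodiazepine linker-payloads. Its
acyclic bond topology was chosen so the constrained enumeration yields 46
products, the published combinatorial size for this workflow class, which
makes the downstream shapes (187-entry library) representative. It is not
any real molecule, and its cleavage count is verified in the tests against
an independent brute-force oracle.

# Proteoform candidates

`chain_mass()` sums residue masses (computed from elemental compositions,
so monoisotopic and average scales share one source of truth) plus one
water, minus two hydrogens per intrachain disulfide. Disulfide counts
default to the IgG1 convention (LC 2, HC 4) and are user-configurable -
commercial software absorbs them into sequence annotations.
`apply_fixed_mods()` implements C-terminal lysine loss and N-terminal
pyroglutamate formation; `glycan_mass()` covers the common IgG glycans
(G0, G0F, G1F, G2F, Man5) as monosaccharide residue compositions.

`enumerate_candidates()` crosses drug load (DAR 0..sites), glycans,
cysteinylation of unconjugated sites (+C3H5NO2S per cap, modelling the
disulfide-linked cysteine on a freed thiol) and per-payload modification
assignments drawn from the delta-mass library. Payloads are
indistinguishable, so assignments are multisets: a DAR-3 chain with a
hydrolysis-only library yields the 0-3 x H2O ladder. Labels such as
`"HC + 3PL + 2H2O + G0F"` are bijective with the candidate components
(`parse_label()` inverts them), and a combinatorial guard aborts with
advice when the candidate space explodes. Intrachain-bridge formation
between two freed thiols (a -2H variant sometimes hypothesised for DAR-1
heavy chains) is not modelled.

# Deconvolution

The proprietary maximum-entropy deconvolution of vendor software is
deliberately replaced by transparent **charge-envelope summation**: for
each neutral mass M on a grid (default 0.5 Da over 20-80 kDa), the score
is the summed interpolated intensity at (M + z x 1.00727646)/z over
charges 10-60 within 1000-5000 m/z. Local maxima above 1% of the top
score, supported by at least 3 charge states, become peaks. Isotope
structure is not modelled - envelopes at these masses are isotopically
unresolved, so reported masses live on the average-mass scale, and
matching defaults to average-scale theoretical masses (monoisotopic is
also emitted).

Three artifact classes needed explicit treatment, because a candidate at a
rational multiple of a true mass samples the *same line apexes* and can
score as high as the true peak:

* **Double-mass (2M)** artifacts collect only the even charge lines; their
  charge support has fill about 0.5 inside its own span. A fill filter
  (default minimum 0.6) rejects them, and a second test drops any peak at
  twice another peak's mass whose support is almost entirely explained by
  the half-mass peak's charge lines (a genuine 2M species has odd-charge
  lines of its own).
* **Half-mass (M/2)** artifacts score about half the true peak (they
  sample every second line); a dominance rule removes a peak when a peak
  with >= 1.5x its score shares >= 50% of its supporting m/z positions
  (intensity-weighted; positions coincide within ~one peak width,
  default 0.25 m/z). The factor 1.5 sits between the ~2x true-to-artifact
  ratio and 1; a 3x factor cannot reject these artifacts.
* **Composite artifacts** borrow lines from several true peaks at rational
  charge ratios; the dominance test therefore runs against the union of
  all sufficiently stronger peaks.

Peak positions are refined in two stages: a least-squares parabola on the
log score over the hump's upper part, then per-charge line-apex averaging
- each supporting charge line's apex is located on the m/z grid (3-point
parabola), converted to a neutral mass, trimmed of outliers beyond 2 Da of
the median (a line apex can be captured by another species' nearby line),
and intensity-weighted. The summed score hump is slightly skewed because
its width scales with charge; individual line apexes are not.

Preprocessing (`preprocess()`) smooths with a 5-point moving average
matched to the profile peak width, subtracts a binned-minimum baseline
(20 m/z bins, linearly interpolated, re-centred at the residual median so
the noise estimate is unbiased), zeroes points below 5x the median
absolute deviation, and removes surviving runs shorter than 3 grid points
(a real profile peak spans several points; isolated spikes are noise).
In the study pipeline preprocessing is applied **per scan** before window
summation (`preprocess_run()`): summing n scans grows the noise floor by
sqrt(n) while an eluting species' signal is concentrated in a few scans,
so cleaning first preserves minor species near the detection limit.

# Annotation and quantification

`match_peaks()` applies a fixed absolute tolerance (default 3 Da,
boundary-inclusive, per common intact-ADC practice; the equivalent ppm is
mass-dependent and both are reported). All in-tolerance candidates are
returned ranked by |ppm| with ties broken toward the lower theoretical
mass; peaks with several matches are flagged for review rather than
auto-resolved - choosing the chemically plausible assignment is a human
judgment. `consolidate()` keeps species observed in at least a configured
fraction of time points (inclusive boundary) and zero-fills the species x
sample grid, mirroring the practice of retaining only reproducible peaks.

`fractional_abundance()` divides each species' intensity by its
(sample, chain) group total; unidentified peaks are excluded from the
denominator by default. `aggregate_replicates()` reports the mean and
sample standard deviation (n - 1; a single subject gives 0) per species
and time point; `percent_difference()` implements the mean-denominator
percent change with a configurable sign convention (default new minus
old). Samples with no observed signal are reported as zero, not dropped.

# The synthetic study

`sim_scenario()` fixes the study conditions the package is tested under:

* a DAR8 cysteine conjugate - LC with 1 conjugation site, HC with 3
  (interchain disulfides repurposed for conjugation), LC ~23.5 kDa
  unglycosylated, HC ~49.5 kDa with G0F; the sequences are deterministic
  synthetic draws (`make_synthetic_chains()`), not real antibodies, since
  additivity - not absolute mass - is what the tests must probe;
* PK sampling at 1, 24, 72, 120, 168 and 336 h with n = 3 subjects;
* first-order per-site kinetics: hydrolysis at 0.04 /h (99% per site by
  120 h, matching the qualitative "complete hydrolysis by 120 h"
  behaviour of stable cysteine conjugates) competing with deconjugation at
  0.002 /h followed by cysteinylation; hydrolysis protects against
  retro-Michael deconjugation, so only unhydrolysed payloads deconjugate.
  The chain species distribution is the multinomial over sites
  (`simulate_species()`); species below 1% are considered under the
  detection floor and not rendered;
* spectra: a Gaussian charge envelope per species centred where its m/z is
  nearest 1800 (sigma 2 charges), Gaussian profile peaks at resolving
  power 8000 on a 0.05 m/z grid over 1000-5000 m/z, Gaussian elution
  profiles (LC 1.95 min, HC 4.5 min), a flat 2% baseline, additive
  Gaussian noise at S/N 50 (20 in the stress tests), and 10% lognormal
  subject-level abundance noise per species.

The Gaussian envelope shape is a modelling convenience; the deconvolution
does not assume it. What passing the synthetic tests shows is that the
pipeline's combinatorics, mass arithmetic and charge-envelope inversion
are correct under realistic noise; it does not certify behaviour on real
data with adducts, chromatographic tailing, detector saturation or
co-eluting plasma proteins (albumin and its cysteine adduct, for
instance, are only identified if their masses are in the candidate space).

# Problem sizes and defaults

The shipped tests run the full study - 6 time points x 3 subjects, two
retention-time windows per run, ~40 scans of 80,001 points each - plus a
20-replicate single-spectrum deconvolution stress test at S/N 20 and 100
random-graph enumeration cross-checks; together they complete in a few
minutes on one core. The pipeline applies `consolidate()` with threshold 0
in the synthetic study: every species there is genuinely present, and the
reproducibility filter exists for real data where noise peaks recur
irregularly (its 0.5 default reflects the "found in most time points"
practice). Chain-specific deconvolution mass windows (LC 20-40 kDa, HC
40-80 kDa) are part of the scenario: they mirror how analysts window
deconvolution around the expected chain mass, and they keep each window's
harmonic images out of range.

# Known limitations

* Ring-opening cleavages, stereochemistry and protonation states are out
  of scope; cleavage likelihoods are not ranked.
* The 3 Da tolerance can span several candidates at heavy-chain masses;
  the package flags but does not adjudicate these.
* Deconvolved masses are average-scale; monoisotopic matching is provided
  but only meaningful for isotopically resolved data.
* The dominance rule can in principle suppress a genuine species at
  exactly half the mass of a 1.5x stronger co-eluting species whose
  support it shares; chain-specific mass windows make this configuration
  rare, and real half/double-mass coincidences within one chain's window
  are rarer still.
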