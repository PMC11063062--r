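---
title: "Models and methods in ms2deconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ms2deconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms2deconv)
```

# The problem

In DDA acquisition the instrument isolates a narrow m/z window (typically
±0.5–1 Th) around a chosen precursor and fragments everything inside it. When
a second ion co-elutes within that window — an isobaric compound, an orphan
isotopologue, or any other co-isolated species — the recorded MS2 spectrum is
a mixture. Treating that chimera as the precursor's spectrum depresses library
matching scores and can flip the top annotation entirely. In SWATH-DIA the
problem is structural: windows are 25–50 Th wide, so *every* spectrum is a
mixture and precursor–fragment links must be reconstructed computationally.

`ms2deconv` addresses both: regression-based subtraction for DDA chimeras, and
chromatogram-shape decomposition for DIA.

# Chimera assessment

MS2 scans are assigned to MS1 features when the scan precursor lies inside the
feature's m/z range and its RT inside the feature's RT range; features without
explicit ranges get `mz_med * (1 ± ppm_tol*1e-6)` and `rt_med ± rt_tol`.
Co-assigned scans merge with intensity-weighted mean m/z per fragment group
and summed intensity, then normalize to base peak 100 (the normalization
convention used throughout; the choice is arbitrary but must be consistent
because mixing weights are interpreted relative to it).

Cleanliness is judged on the single MS1 scan nearest in RT (ties to the
earlier scan — a deterministic, reproducible rule). The in-window centroid
closest to `mz_med` is the main ion; other in-window centroids above the
acquisition intensity threshold are contamination ions. The threshold is
interpreted as an absolute abundance by default because vendor acquisition
thresholds are absolute; a relative mode (`relative_threshold = TRUE`) is
available since some workflows reason in fractions of the main ion.
Contaminants within 1 mTh of the main ion are treated as the same centroid
(duplicate-report artifacts in centroided data).

# Candidate spectra

Each contamination ion is resolved to exactly one candidate class, in order
I → II → III → IV; an ion that resolves to none is dropped from the
regression with a warning (its fragments then simply stay in the spectrum —
a conservative failure mode).

* **Class I, orphan isotopologues.** A contaminant at `mz` with a parent
  centroid at `mz − n·1.003355/z` (n ∈ {1, 2}, the ¹³C–¹²C mass difference;
  heavier isotopologues are too weak to matter) whose intensity is at least
  the contaminant's. The parent's spectrum is split per fragment into an
  unshifted and a shifted peak; the shifted fraction is the probability the
  heavy isotope sits in the fragment, approximated by the carbon-count ratio
  `n_C(fragment)/n_C(precursor)` when fragment formulas are available and by
  the m/z ratio otherwise. The m/z-ratio fallback assumes carbon density is
  roughly uniform along the fragment mass — adequate for the small shifts it
  gates, and documented as an approximation.
* **Class II, in-data clean spectra.** The two MS2 scans nearest in RT whose
  precursor matches the contaminant within tolerance and which are themselves
  assessed clean; the nearer wins. The search radius is capped at `2·rt_tol`:
  a clean scan far outside the feature's chromatographic neighborhood is more
  likely a different isomer than the same ion.
* **Class III, library spectra.** All records within the precursor ppm
  tolerance; the one most similar to Spectrum 0 is retained (ties to the
  lower record id). Similarity to the *chimera* — not to an unknown truth —
  is the only available criterion, and it is biased toward candidates that
  explain observed fragments, which is exactly what the regression needs.
* **Class IV, transformation-network predictions.** For an ion matching no
  library precursor, the top predicted formula seeds a one-hop network of
  common biotransformations (±H2, ±CH2, ±O, ±H2O, ±NH3, ±CO, ±CO2, ±C2H2O,
  ±SO3, ±C6H8O6, ±C2H4, ±HPO3; an editable TSV resource). Neighbors' library
  spectra are cleaned by elemental containment — a fragment whose formula
  needs more atoms of any element than the ion's formula, or a new element,
  cannot come from it — and the most Spectrum-0-similar survivor becomes the
  candidate. The network is deliberately one hop: propagation multiplies
  candidates without adding evidence. Class IV spectra are synthetic, so they
  carry a penalty mapped linearly from similarity, `10·(1 − s)`: 0 for a
  perfect match, 10 for no match. Only the endpoints are principled; linear
  interpolation is the least-structured choice between them.

Formula prediction enumerates CHNOPS compositions (defaults C ≤ 40, H ≤ 80,
N ≤ 10, O ≤ 20, P ≤ 5, S ≤ 5) by looping over the CNOPS grid and solving the
hydrogen count from the residual mass, filters by RDBE ≥ 0 and common-range
element ratios (H/C ≤ 6, N/C ≤ 1.3, O/C ≤ 3), and ranks by |ppm|. The ratio
filters matter in practice: nitrogen-rich compositions such as C5H6N7O are
isobaric with C6H12O6 to ~5 μDa and would otherwise tie on mass alone.

# The elastic-net model

With Spectrum 0 as response `y` and one unit-norm column per candidate
(main ion first) on a merged m/z axis:

$$\min_{\beta \ge 0}\; \sum_i (y_i - (X\beta)_i)^2
 + \lambda \sum_j pf_j \left[ \tfrac{1-\alpha}{2}\beta_j^2
 + \alpha\,\beta_j \right]$$

Penalty factors are 1 for the main ion and classes I–III, `1 + penalty` for
class IV — the per-coefficient-factor form is how a "10 times penalty" acts
multiplicatively on one component's regularization without distorting the
others. Non-negativity is imposed because spectra are physical mixtures;
negative mixture weights have no meaning here. A useful consequence: on the
non-negative orthant the L1 term is linear, the objective is a smooth convex
quadratic, and cyclic coordinate descent with exact per-coordinate minimizers
converges reliably (tolerance 1e-6 on the largest coefficient change, capped
at 1e4 sweeps; hitting the cap flags, but does not throw).

The `(α, λ)` pair is tuned per spectrum over a fixed grid: α ∈ {0, 0.1, …, 1}
and 10 λ values log-spaced over three decades down from
`λ_max = max_j |x_jᵀy| / n` — the largest column–response correlation, the
point at which a pure-lasso fit first activates a coefficient. 110 solutions
are evaluated and the minimal *unpenalized* RSS wins: penalized objectives at
different λ are not comparable, whereas RSS measures what the subtraction
step actually needs — how well the candidates explain the chimera. Ties
prefer larger λ, then larger α (the sparser fit).

The main-ion column is the main ion's best library spectrum when one exists,
else Spectrum 0 itself: the column must exist for `β_MAIN` to be defined, and
Spectrum 0 is the best available stand-in for an unannotated main ion.
Subtraction removes `Σ_c β_c x_c` per bin, clamps at zero, drops bins below
0.5% of the post-subtraction base peak (residual crumbs of imperfectly
cancelled contaminant fragments), and normalizes. `β_MAIN = 0` or an empty
remainder is a failed deconvolution: the original spectrum passes through,
flagged, rather than emitting an artifact.

# DIA reconstruction

Per feature, fragment EICs are extracted from the feature's SWATH window
(overlapping windows resolve to the nearest window center, so a precursor
never belongs to two windows) over the feature's RT range padded by one peak
width. Peaks are detected on Savitzky–Golay-smoothed traces (2nd order,
5-point) with a prominence rule of ≥ 3× the MAD of the sub-median trace — a
noise proxy that needs no separate blank; traces with relative dynamic range
below 1e-6 are discarded as flat. Peaks group into clusters when apexes agree
within `rt_tol` and shapes correlate (Pearson ≥ 0.8 by default; 0.8 tolerates
5% intensity noise while separating peaks half a width apart). The model peak
is the cluster's most intense member — the highest-SNR shape template.

All EICs are then decomposed over the model-peak traces by non-negative least
squares (the package's own solver at λ = 0; all EICs share the scan grid so
no resampling is needed). The pseudo-MS2 intensity of a fragment is its
weight on the feature's cluster times the model-peak apex intensity — apex
rather than area, because apex is what the weight scales; area is available
by integrating the model trace if preferred. Fragments below 1% of the
pseudo-MS2 base peak are dropped: chromatographic tails of neighboring
compounds overlap any finite window and produce numerically tiny but nonzero
weights that are noise, not signal.

# Consensus and library search

Replicate consensus counts each aligned fragment group across replicates:
frequency ≥ threshold keeps it (≥ rather than >, so 1-of-2 at threshold 0.5
keeps shared fragments — the natural reading for small replicate counts);
optionally a fragment failing frequency is rescued when it appears in a
reference spectrum of the same precursor *and* was seen at least twice. The
count-≥-2 reading resolves an ambiguity between "over 2" and
"only once … excluded" in favor of the interpretation under which the
single-observation exclusion rule is exactly the complement of the rescue
rule. A single input spectrum skips consensus entirely. Kept groups average
their per-replicate normalized intensities.

Search scoring combines four components in `[0, 1]`:

* **MS2 similarity** — cosine of √-intensity vectors (the square root
  compresses dominant peaks, the convention of mainstream metabolomics
  search engines; plain cosine via `sqrt_transform = FALSE`), or spectral
  entropy similarity `1 − (2S_ab − S_a − S_b)/ln 4`.
* **MS1 and RT similarity** — `exp(−|Δ|/tol)`, an exponential deviation
  kernel: 1 at zero deviation, e⁻¹ at one tolerance.
* **Isotope similarity** — `max(0, 1 − Σ|obs − theo| / Σ theo)` over M+1 and
  M+2, with theoretical patterns from truncated polynomial expansion of
  per-element natural abundances (C, H, N, O, S; P is monoisotopic).
  A missing observed pattern scores 0 by default — conservative, since
  absence of satellites is weak evidence against a carbon-rich formula —
  with a `"drop"` mode that removes the term and renormalizes.

The composite is `(MS2 + MS1 + RT + 0.5·Isotope)/3.5 × 100`, or denominator
2.5 without RT (disabled by default: library RT annotations are rare and
instrument-specific). A perfect self-match scores exactly 100 either way.
Queries scoring below 10 may fall back to neutral-loss search: the query's
NL spectrum (precursor − fragment m/z, intensities mirrored) is scored
against NL spectra of the one-hop network neighbors of its predicted
formula, with the same composite. Exports deduplicate by InChIKey keeping
the top score, then keep the top N per query.

# Decoys and null evaluation

Decoy runs perturb MS1 centroids by 10–30 ppm (random sign per centroid —
the magnitude range is specified, the sign symmetric to avoid systematic
drift) and multiply intensities by Uniform(0.01, 50); retention times and
SWATH windows are untouched. DDA MS2 spectra are replaced by the
0.5–2×-jittered spectrum of an isobaric library compound with a different
InChIKey; without such a compound the scan is perturbed like MS1 and noted.
Every decoy compound is a true negative; a top hit equal to the original
identity is a false positive. The default set is 18 decoys per replicate.

At fixture scale this test is only meaningful if the library offers isobaric
alternatives — otherwise the original is the lone candidate at its precursor
and trivially tops every ranking. The synthetic library generator therefore
supports *isomers* (same formula and precursor, independent spectrum,
distinct InChIKey), mirroring the isomer-rich composition of real reference
libraries.

# Synthetic data: what it emulates, what it does not

The generators emulate: Gaussian chromatographic peaks (σ configurable,
default 4 s within the typical 6–20 s base-width range), M+1/M+2 isotope
satellites at theoretical abundances, co-isolation chimeras built as weighted
unions of two known spectra (weights 0.1–0.9), multiplicative log-normal
intensity noise at a stated CV (default 5%, a typical fragment-intensity
repeatability), SWATH cycles of one MS1 scan plus one scan per window with
1-Th window overlaps, mass-close compound pairs (−CH4+O, Δ ≈ 36 mDa: inside
an isolation window, outside ppm search tolerance) and exact isomers.

They do not emulate: peak tailing or asymmetry, in-source fragmentation,
adduct multiplicity, electronic noise floors, mass-accuracy drift, or
intensity-dependent centroiding artifacts. Passing tests on these fixtures
therefore demonstrates correctness of the algorithms under their stated
model — recovery of known mixing weights, exact fragment bookkeeping — not
robustness to every vendor-specific artifact of real acquisitions.

Problem sizes used by the test and acceptance suites — libraries of 10–1000
records, runs of 4–20 features, 100 two-ion chimeras, 18-decoy sets — were
chosen so the full suite exercises every path in well under a minute of
deconvolution work while keeping every statistical check (median weight
error < 10%, ≥ 90% similarity improvement, DIA precision/recall, pooled FPR)
at a sample size where the property, not sampling luck, decides the outcome.

# Numerical choices and degenerate inputs

* m/z is compared in double precision; ppm = 1e6·Δmz/reference.
* Duplicate centroids within 1e-4 Th merge on construction
  (intensity-weighted m/z, summed intensity).
* Fragment alignment merges peaks at `mz_tol` (default 0.01 Th) with
  intensity-weighted group centers; zero-intensity groups fall back to the
  plain mean.
* Design columns normalize to unit Euclidean norm; coefficients are
  rescaled back for subtraction and reporting.
* Empty spectra: normalization and similarity error or return 0 with a
  warning, respectively; consensus of nothing errors; an all-zero EIC gets
  zero weights everywhere.
* All tie-breaks are deterministic: earlier scan, lower record id, larger
  λ then larger α, nearest window center.
* RT is stored in seconds throughout; MSP `RETENTIONTIME` fields are
  treated as minutes (MS-DIAL convention) and MGF `RTINSECONDS` as seconds.
* Missing mzML isolation metadata falls back to precursor ± 0.75 Th with a
  warning (typical DDA quadrupole default), configurable.

# Known limitations

* Class IV prediction inherits every weakness of formula prediction; outside
  CHNOPS (halogenated compounds, metal adducts) it stays silent.
* The isotope model covers C/H/N/O/S only and M+1/M+2 only.
* The DIA decomposition assumes fragments of one compound share one
  chromatographic shape; shoulder peaks merged by the detector blur cluster
  boundaries.
* Ion mobility, all-ion fragmentation, and profile-mode data are out of
  scope; profile scans are rejected at read time.
* The adduct set is the common four (`[M+H]+`, `[M+Na]+`, `[M+NH4]+`,
  `[M-H]-`); multiply charged small molecules are handled only in orphan
  isotopologue detection (z ≤ 2).
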