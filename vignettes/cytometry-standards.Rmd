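---
title: "Models, conventions and design decisions in cytostd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design decisions in cytostd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cytostd` implements the open flow-cytometry data-standards family —
FCS list-mode files, XML gate descriptions, CSV classification-results
tables and ZIP archival containers — together with a synthetic-data
pipeline that exercises all of them end to end. This vignette is the
package's account of the underlying models, the parameters that matter,
the places where the standards leave room and what this package pins
down, and what the passing test suite does and does not demonstrate.

## The FCS layer

An FCS file is a 58-byte ASCII header (version tag plus six 8-digit
byte-offset fields), a delimited TEXT segment of keyword/value pairs,
and a binary DATA segment; offsets are inclusive on both ends and a 0
in a header field means "absent" (or, for DATA in files larger than
the 8-digit fields can address, "see `$BEGINDATA`/`$ENDDATA` in
TEXT"). We write FCS 3.1 with one dataset per file, little-endian,
delimiter `/`, UTF-8 TEXT; we read versions 2.0–3.1, both byte orders,
mixed per-parameter bit widths, and `$NEXTDATA` chains by explicit
dataset index. `$DATATYPE` F (float32), D (double) and I (unsigned
integer) are supported; ASCII data (deprecated in 3.1) is a named
error. Integer values are masked to the significant bits implied by
`$PnR` (next power of two minus one), as the standard requires.

Two conventions deserve explanation:

* **Offset stability.** `$BEGINDATA`, `$ENDDATA` and `$NEXTDATA` are
  written as fixed-width zero-padded values, so the TEXT length — and
  hence every offset — is independent of the values themselves and the
  file can be assembled in a single pass.
* **The delimiter ambiguity.** A doubled delimiter inside a value means
  one literal delimiter; a doubled delimiter *at a token boundary* is
  ambiguous in the delimited-TEXT design itself. The reader resolves
  runs of delimiters by greedy left-to-right pairing; the writer
  additionally refuses keyword names or values that *begin* with the
  delimiter (trailing delimiters remain representable and round-trip).
  This restriction is what makes the serialize→parse round trip exact.

Event data are exposed exactly as stored: `$PnE` amplification
keywords are preserved but never silently applied, because gate
definitions carry their own explicit transformations.

## Scale transformations

All five transformation kinds use the harmonized parameter quadruple:
`T` the top-of-scale data value, `M` the number of display decades,
`W` the linearization width in decades near zero, `A` additional
negative-display decades (or the additive offset, for the linear
kind). Every kind maps `T` to display value 1:

* `flin(x) = (x + A)/(T + A)`
* `flog(x) = log10(x/T)/M + 1`
* `fasinh(x) = (asinh(x·sinh(M ln10)/T) + A ln10) / ((M + A) ln10)`
* `logicle` — the inverse of the biexponential
  `B(y) = a·e^{by} − c·e^{−dy} − f`, whose constants are derived from
  (T, M, W, A) via the standard construction (`d` solves
  `2(ln d − ln b) + w(d + b) = 0`, `c/a = e^{(b+d)x0}`, and `a`, `f`
  are fixed by `B(x1) = 0`, `B(1) = T`)
* `hyperlog` — the inverse of `EH(y) = a·e^{by} + c·y − f` with
  `c/a = e^{b x0}/w`.

`B` and `EH` are strictly increasing with available derivatives, so
forward evaluation inverts them by a vectorized safeguarded
Newton/bisection iteration: brackets are expanded until they straddle
the target, Newton steps are taken where they stay inside the bracket
and bisection otherwise, stopping at a step below 1e-14 (at most 100
iterations). In practice this converges to machine precision;
top-of-scale and inversion errors measured by the acceptance script
are below 1e-13. Display values outside [0, 1] are extrapolated rather
than rejected — the underlying functions are defined there, and gate
vertices occasionally sit slightly outside the nominal range.

One numerical subtlety: with `W = 0, A = 0` the logicle degenerates to
a scaled `sinh` and approaches the pure log scale away from zero. At
the conventional lower comparison point one decade above the bottom of
scale, the residual `asinh` curvature is `≈ 0.00993/(M ln10)`, which
drops below 1e-3 only for `M ≥ 4.5` decades. The limit-agreement
property is therefore stated (and tested) for displays of at least 4.5
decades — the default in practice.

## Compensation

The spillover matrix convention follows the FCS 3.1 `$SPILLOVER`
definition and is pinned prominently because vendor tools disagree:
rows are fluorochromes, columns are detectors, and with events as row
vectors `observed = true · S`, so compensation right-multiplies by
`S⁻¹`. Matrices with non-unit diagonals are normalized row-wise by
their diagonal on parse (with a warning); matrices whose determinant
falls below `1e-12` times the diagonal scale are reported singular
rather than inverted. Unmapped columns — scatter, time — are never
touched.

## Gate evaluation

Gates form a forest; a gate's population is its own geometric
predicate intersected with its parent's population, recursively.
Dimension values are prepared by applying the dimension's compensation
first (none, the dataset's own `$SPILLOVER`, or an explicit spectrum
matrix from the gate file) and its transformation second. Because the
standards are silent on boundary behaviour, the package pins:
rectangles are min-edge inclusive and max-edge exclusive; polygon and
ellipsoid boundaries are inclusive. Consistency, not the particular
choice, is what matters for reproducibility.

Rectangles are evaluated in data space by inverse-transforming their
display-space bounds once — identical to transforming every event
(transforms are strictly increasing) but cheaper; the agreement of the
two routes is itself a test. Polygons use crossing-number (even-odd)
semantics with an explicit on-segment test for the inclusive boundary;
self-intersecting polygons are accepted and documented to mean their
even-odd interior, while zero-area polygons are rejected at
construction. Ellipsoids use the Mahalanobis form
`(x − μ)ᵀ C⁻¹ (x − μ) ≤ D²`. Boolean gates (AND/OR/NOT, with
per-operand complement) reference other gates; reference cycles are
reported with the cycle path. Quadrant gates, decision trees and
curly quadrants are deliberately unsupported (named errors) to keep
the geometry kernel small and fully testable.

The XML dialect is written under a single pinned namespace triple;
reading accepts any namespace under the common gate-description URI
prefix where element shapes coincide, since documents from the 2008
vocabulary differ mainly in namespace string. Numeric attributes are
serialized with 17 significant digits so structural round trips
preserve values to better than 1e-12.

## CLR tables

The classification-results layer is deliberately plain CSV: first row
class labels, one row per event, values in [0, 1] with 17 significant
digits (so every finite double round-trips bit-exactly), RFC 4180
quoting, and an optional leading `#source=<file>` comment carrying the
source FCS reference. Labels with leading or trailing whitespace are
quoted because bare CSV readers strip unquoted whitespace around
header fields. Row sums are *not* constrained by default — classes may
overlap — but a strict mode enforces sums ≤ 1 + 1e-9 for fuzzy
partitions. Hard assignment takes the argmax class when it reaches the
threshold (default 0.5), breaking exact ties by first label order, or
optionally refusing to assign ties.

## ACS containers

A container is a ZIP archive whose first member, `TOC.xml`, types
every member, records a checksum per entry, and relates members with a
small controlled vocabulary (`preprocessed-from`,
`gating-description-of`, `classification-results-of`,
`compensated-version-of`, `derived-from`); unknown terms validate as
warnings because relations are semantically open. Integrity is
checksum-based — SHA-256 per member, implemented in C — with an opaque
signatures block preserved verbatim through round trips as the
extension point for real digital signatures, which are out of scope.

The archive writer emits stored (uncompressed) entries with zeroed DOS
timestamps and no extra fields. This is a deliberate trade: stored
entries plus fixed metadata make packing a pure function of the member
bytes, so identical pipelines produce byte-identical `.acs` files —
a reproducibility property the tests rely on — while every ZIP tool
can still open the archive. Reading goes through R's bundled ZIP
extraction and accepts deflated members produced by other tools.
Validation checks the bidirectional closure (every entry has a member;
every non-ToC member has an entry, else an orphan warning), recomputes
digests, and vets relation endpoints; the four mutation classes
(member removed, entry removed, byte corrupted, relation dangled) each
produce at least one finding.

## The synthetic PBMC model

`simulate_sample()` draws events from a Gaussian mixture on a log10
latent scale (decades of a 10^5-count range), exponentiates to channel
units, applies spillover to the eight fluorescence channels, and clips
to the digitizer range. The ten channels are forward/side scatter,
four surface markers (CD123, CD11c, MHC-II, CD14) and four cytokines
(IL-6, IL-12, TNF-α, IFN-α). The seven default populations live in
`inst/extdata/pbmc_populations.csv` and encode qualitative marker
logic only: monocytes CD14-high, mDC CD11c-high/CD14-low, pDC
CD123-high, B cells MHC-II-high with low myeloid markers, debris/dead
cells low-scatter, plus two "novel" populations (one
intermediate-marker, one lineage-negative). Within the
antigen-presenting populations, each event is a stimulation responder
with probability 0.5, shifting its cytokine means upward by 0.5–2.4
decades — a bimodal structure that emulates a danger-signal response.
Latent standard deviations are 0.1 decades (0.18 for debris), placing
neighbouring populations ≥ 8 latent SDs apart on at least one marker.

These choices make the generator a *pipeline exercise*, not a
biological claim: real instrument data have heavier tails, correlated
channels, autofluorescence, doublets, acquisition-time drift and far
less separable populations. Passing tests therefore demonstrate that
the format layers, the gate engine, the clustering wrapper and the
container assembly are correct and self-consistent — not that the
analysis strategy would reach F ≈ 1 on real PBMC samples.

The default spillover decays geometrically with detector distance
(12% between neighbours, halving per step), a magnitude typical of
adjacent emission filters; it is comfortably invertible (condition
number ≈ 2).

## The example pipeline

`build_example_acs()` mirrors a standard two-sample workflow:

1. simulate two samples (seeds `seed` and `seed + 1`; 12 000 events
   each by default);
2. preprocess: scatter rectangle live gate (FSC ≥ 8 900, SSC ≥ 1 000 —
   ~6 latent SDs above the debris population and ~3.5 below the lowest
   live one), compensation with the file's own `$SPILLOVER`, and
   subsetting to scatter + surface channels;
3. "manual" gating: four population gates as children of the live
   gate, defined in log display space (`T = 1e5`, `M = 5`) —
   ellipsoids for monocytes (CD14/CD11c) and pDC (CD123/CD11c) with
   `D² = 20` (≈ 4.5 SD radius, 99.995% coverage of a 2-D Gaussian),
   polygons (±0.45-decade boxes, ≈ ±4.5 SD) for mDC (CD11c/CD14) and
   B cells (MHC-II/CD11c). The marker pairs were chosen so that every
   other population is ≥ 3 SD outside each gate on at least one axis;
4. clustering: a full-covariance Gaussian mixture with `k = 6` (the
   live populations, including the two novel ones) on
   `asinh(x/150)`-scaled events, fitted by EM with model-based
   hierarchical initialization on a seeded 1 500-event subsample, up
   to 5 reseeded restarts if a component degenerates. On the asinh
   scale the log-normal channel intensities are approximately
   Gaussian, which is why an off-the-shelf mixture fit suffices; the
   posterior responsibilities become the fuzzy CLR table (rows sum
   to 1);
5. matching: hard-assign both tables, build the cluster × population
   contingency table, and solve the maximum-overlap assignment with a
   Hungarian (shortest-augmenting-path) solver; clusters without a
   matched population are labelled "novel" — with `k = 6` and four
   reference populations, exactly the two engineered novel populations
   end up unmatched;
6. comparison: per-population precision, recall and `F = 2PR/(P + R)`
   (defined as 0 when `P + R = 0`), with unassigned events counted
   against recall;
7. packing: eight data members plus `TOC.xml`, with
   `preprocessed-from` / `gating-description-of` /
   `classification-results-of` relations encoding the workflow.

Byte-identical rebuilds from the same seed are guaranteed by seeding
every stochastic stage from the master seed and by the deterministic
archive writer. `verify_example_acs()` re-opens a container and
replays it: the shipped live gate applied to the shipped raw file must
select exactly the events of the shipped preprocessed file, and each
CLR table must have one row per preprocessed event.

## Problem sizes and tolerances used in the checks

The shipped test suite and `scripts/acceptance.R` use sizes chosen to
exercise every code path while keeping a full run in well under a
minute of compute: 200 FCS round-trip datasets of 1–50 000 events and
1–24 parameters across the three datatypes and both byte orders
(float32 round trips within 1.2e-7 relative, integer and double
exactly); 50 random star-shaped polygons × 1 000 points against an
independent scalar crossing-number oracle (zero disagreements
required); 100 random transform parameterizations (top-of-scale within
1e-12, inversion within 1e-9); 60 random spillover matrices with
off-diagonals up to 0.5 (recovery within 1e-8 relative); 30 CLR tables
(bit-exact round trips); the four container mutation classes; and the
full two-sample example with a mean F-measure threshold of 0.8 —
intentionally far below the ≈ 1.0 the well-separated defaults produce,
so the check fails only on genuine pipeline breakage, not on sampling
noise.

## Known limitations

* FCS: the ANALYSIS segment is preserved as offsets only; CRC trailers
  are not verified; vendor-specific keywords are carried verbatim but
  not interpreted; `$DATATYPE A` is rejected.
* Gating: no quadrant/decision-tree/curly gates; no ratio transforms;
  no data-driven estimation of the logicle `W` parameter.
* Compensation: spillover must be supplied (no estimation from
  single-stain controls, no autofluorescence model).
* ACS: checksums stand in for cryptographic signatures; the signatures
  block is an inert extension point. The ToC element vocabulary is
  this package's own pinned dialect, documented and self-consistent,
  as published schemas are not bundled.
* Synthetic data: no doublets, no time drift, no heavy tails — see
  above for why this bounds what the tests demonstrate.
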