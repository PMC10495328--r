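---
title: "Measuring virtual orthodontic setups: models, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring virtual orthodontic setups: models, conventions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthosetup)
```

`orthosetup` quantifies two properties of a virtual orthodontic setup —
adjacent-tooth root parallelism and root exposure from the alveolar bone —
and compares setup conditions with the repeated-measures statistics
customary in this literature. This vignette is the package's account of the
underlying models, the conventions and tolerances it fixes, and what its
synthetic validation data can and cannot show.

## The angular model

Every tooth is reduced to a landmark triplet: the most mesial point M, the
most distal point D, and an apex point A (the root apex of single-rooted
teeth, the furcation center of multi-rooted ones). The long axis is the
segment from the M–D midpoint to A. The shared reference is the occlusal
plane through the distobuccal cusp tips of the maxillary second molars and
the contact point of the maxillary central incisors; its unit normal
$\mathbf{s}$ is oriented toward the maxillary apices, using the centroid of
the maxillary apex points purely as an orientation witness.

Rather than projecting all long axes onto one common coronal or sagittal
plane, every tooth carries its own pair of projection planes:

* the *angulation plane* contains M and D and is perpendicular to the
  occlusal plane;
* the *inclination plane* passes through the M–D midpoint perpendicular to
  both the occlusal plane and the angulation plane.

Write $\hat d$ for the unit in-occlusal-plane direction obtained by
projecting $D - M$ (mesial-to-distal), $\hat n$ for the angulation plane's
unit normal, and $\hat a$ for the unit long axis. Then

$$\text{angulation} = \operatorname{atan2}(\hat a \cdot \hat d,\; |\hat a \cdot \mathbf{s}|), \qquad
  \text{inclination} = \operatorname{atan2}(\pm\, \hat a \cdot \hat n,\; |\hat a \cdot \mathbf{s}|),$$

in degrees. The absolute value in the second argument makes the measurement
agnostic to whether the axis points toward the maxillary or mandibular
apices, so one formula serves both jaws; `atan2` rather than an arccosine of
a clamped dot product keeps the computation well-conditioned near 0°.

Two sign conventions follow the clinical reading: angulation is positive
when the apex lies distal to the M–D midpoint (the distal direction is
always $D - M$; anatomy is carried by the landmark labels, so no
per-quadrant flip is needed and values are side-comparable), and inclination
is positive when the apex lies lingual/palatal. "Lingual" is not derivable
from a landmark triplet alone, so the package operationalizes it as the
in-occlusal-plane direction perpendicular to $D-M$ that points from the
tooth's midpoint toward the projected centroid of all arch midpoints (the
arch interior). This is the one genuinely open design point in the angular
model; the centroid rule is deterministic, symmetric under reflection, and
fails loudly (an error, not a guess) if a midpoint coincides with the
centroid projection.

When a patient has several setup conditions, all of them are measured
against the *same* occlusal frame — the one built from the bone-aware
root setup-2 model — so that angular values are comparable across
conditions. A standalone model is measured in its own frame.

**Degeneracy tolerances.** Coincident landmarks are rejected below
$10^{-6}$ mm, near-parallel M–D/occlusal-normal configurations below
$10^{-3}$ rad, and projected axes shorter than $10^{-9}$. These sit far
below anatomic scales (millimeters, degrees) and are configurable
arguments, not magic constants.

## Parallelism and the pooling gate

Root parallelism is summarized as the absolute difference of signed
angulations of adjacent teeth, per quadrant location (central–lateral
incisor "1–2" through first–second molar "6–7"). Missing teeth simply drop
the affected pairs. Per jaw and location, the three setup conditions are
compared with a one-way repeated-measures ANOVA (closed-form balanced
decomposition; each patient-side contributes one subject), Mauchly's test of
sphericity (reported, not auto-corrected; a Greenhouse–Geisser flag exists
for users who want it), and pairwise paired-t post-hocs with Bonferroni
multiplication, reported as direction labels (`a > b,c` with letters
assigned to the conditions in column order). Labels appear only when the
omnibus test is significant; an omnibus-significant row whose pairwise
comparisons all fail the Bonferroni hurdle is labeled `NA`, which is a
normal outcome of this reporting style.

The left/right pooling gate runs paired t-tests (left vs right within
patient) on the initial-scan angulations per tooth position. The gate is
reported with per-position flags. Note its multiplicity behavior: fourteen
uncorrected tests at $\alpha = 0.05$ flag at least one position in roughly
half of *null* datasets. `run_study()` therefore treats the gate as a
diagnostic and builds the comparison tables pooled, which is also the
analysis practice the package emulates.

## Root exposure from meshes

Inputs are a watertight composite-tooth mesh, a watertight trimmed
alveolar-bone mesh, and a planar per-tooth crest reference disc (origin at
the root/crest junction, normal pointing apically) from which dehiscence is
measured. The measurement pipeline is:

1. **Sampling.** The tooth surface apical to the disc plane is sampled
   deterministically: each face is recursively quadrisected until its
   longest edge is at most the sampling step $h = 1/\sqrt{\rho}$ and one
   sample is placed at each sub-triangle centroid. The default density is
   $\rho = 25$ points/mm² ($h = 0.2$ mm), chosen so that the cone fixtures
   below recover designed lengths within 0.05–0.2 mm and halve their error
   under density doubling. Deterministic sampling makes the whole
   measurement seed-free and exactly equivariant under rigid motion.
2. **Containment.** A sample is exposed iff it lies outside the bone mesh,
   by parity ray casting (Möller–Trumbore, fixed irrational ray direction to
   avoid grazing axis-aligned geometry). Watertightness (every edge shared
   by exactly two consistently oriented faces) is a hard precondition.
3. **Patch classification.** Exposed samples are clustered by single
   linkage at one sampling-step radius. A component whose minimal distance
   to the disc plane is within one step is dehiscence-type (continuous with
   the crest); otherwise it is fenestration-type.
4. **Side assignment.** Each sample is lingual when its displacement from
   the M–D midpoint has positive dot product with the tooth's lingual
   direction; a component takes the majority side of its samples (ties go
   buccal). Mesial/distal exposure is absorbed into whichever half wins the
   majority — the reporting scheme has exactly two sides.
5. **Lengths.** Dehiscence per side is the point-to-plane distance from the
   disc to the apical-most exposed sample of the disc-contacting components.
   Fenestration is each isolated component's extent between its uppermost
   and lowermost points measured along the disc normal, summed per side.
   The axial reading of "uppermost to lowermost" is deliberate: on a
   discretely sampled surface, the literal 3-D distance between the extreme
   samples is inflated by an arbitrary circumferential offset of up to the
   window's width, while the axial extent converges cleanly with sampling
   density. Combined exposure is the sum of the two, matching the rule of
   measuring dehiscence and fenestration separately and then combining.

For the frequency table, a tooth is categorized by the side whose combined
exposure *strictly* exceeds the 2 mm threshold (exactly 2.0 mm is "none");
when both sides exceed it, the larger side wins, with ties to buccal — the
categories are mutually exclusive, so some deterministic rule is required,
and this one is documented and overridable. The McNemar comparison of sides
uses the raw per-side indicators (so a both-sides-exposed tooth is a
concordant pair), not the exclusive categories.

## The statistics layer

Only the tests this evaluation design needs are implemented, with their
reporting shapes:

* paired t (closed form, two-sided; zero-variance differences give $p = 1$
  when the mean difference is zero and $p = 0$ otherwise, which is what the
  pooling gate needs on degenerate data);
* ICC for intra-rater reliability: two-way mixed-effects, single-measure,
  consistency form — ICC(3,1) $= (MS_R - MS_E)/(MS_R + (k-1) MS_E)$ — the
  standard choice when a single rater re-measures;
* one-way repeated-measures ANOVA with Mauchly's W (the p-value follows
  base R's Box expansion term for term, so the two agree to numerical
  precision) and Bonferroni paired-t post-hocs;
* Friedman on within-subject midranks with the tie correction. The reported
  p is the *exact conditional permutation p* — full enumeration of all
  $(k!)^n$ within-row orderings — whenever that enumeration is at most
  $10^5$ states, and the tie-corrected $\chi^2$ approximation otherwise.
  At the package's default study scale ($n = 64$ teeth per row) the
  asymptotic branch applies. Post-hocs are Wilcoxon signed-rank tests with
  zero differences dropped before ranking, exact null distribution up to 25
  nonzero pairs and the continuity-corrected normal approximation above,
  Bonferroni-adjusted;
* McNemar on discordant pair counts $(b, c)$: exact two-sided binomial
  ($\min(1,\, 2\,P(X \ge \max(b,c)))$, $X \sim \mathrm{Bin}(b+c, 1/2)$) up
  to 25 discordant pairs, continuity-corrected $\chi^2$ above. Both switch
  points are configurable constants.

A calibration subtlety worth stating: the exact McNemar test is discrete,
so its attainable size at $\alpha = 0.05$ is *below* 0.05 (about 0.02–0.04
at the discordance counts this design produces). The test suite therefore
calibrates the McNemar stage against its analytically enumerated expected
size under the null design rather than against the nominal $\alpha$; the
ANOVA and Friedman stages are calibrated against $\alpha$ directly.

## What the synthetic generator emulates — and what it does not

The generator exists to validate the measurement chain, so it is built for
*exactness*, not anatomic realism. Teeth are frustum-crown/cone-root solids
placed on a parabolic arch (vertex curvature radius 20 mm, per-position
mesiodistal widths 8.5/6.8/7.6/7.0/7.0/10.2/10.2 mm, crown height 8 mm,
root length 12 mm); M and D sit at the cervical level so the template's M–D
midpoint is exactly the cervical center and its long axis exactly the
template z-axis; molars place A at 35% of the root length to honor the
furcation-center rule without multi-cone meshing. Because every quantity
the package measures depends only on landmarks and surfaces, these simple
solids make analytic oracles exact.

Per tooth, designed angulation $\alpha$ and inclination $\gamma$ are
realized by an extrinsic rotation pair — first about the mesiodistal axis
by $\beta$ with $\tan\beta = \tan\gamma \cos\alpha$, then about the
buccolingual axis by $\alpha$ — solved so that the *measured* projected
angles equal the designed ones exactly. The occlusal landmarks are emitted
at canonical arch positions on the arch's occlusal plane rather than on the
(noise-tipped) posed molars; that is what makes ground-truth recovery exact
to $10^{-6}$ degrees rather than merely approximate under noise.

Alveolar bone is modeled as per-tooth closed blocks (disjoint, so parity
containment is exact) spanning from the crest 14 mm apically, split into
buccal and lingual halves at the tooth's tangent plane. A designed
dehiscence of depth $d$ lowers one side's crest by $d$; a designed
fenestration of height $w$ removes a window centered at mid-root. Ground
truth is therefore analytic.

Cohorts draw per-tooth angles as a shared anatomic component (SD 2.8°)
plus per-condition residuals; the default residual SDs (initial/crown 3.3°,
root setups 1.6°) were chosen so the implied mean adjacent-tooth
differences sit near 5° for the crown setup and 3.6–3.8° for the root
setups — the scale this kind of study reports. Exposure defects follow a
zero-inflated half-normal model (default defect probability 0.25/0.22/0.01
for crown/root-1/root-2, depth $|N(2.2, 1.2^2)|$ mm, 30% fenestrations),
mirroring the qualitative structure of interest: crown and root-1 alike,
root-2 nearly clean. The null configuration gives all conditions identical
continuous exposure distributions with ~50% of teeth beyond 2 mm per side,
which maximizes the information available to the McNemar calibration.

What the generator does **not** emulate, and what passing tests therefore
do not show: anatomic crown/root shape (no oblique cusps, no curved or
multiple root canals), scalloped rather than planar crest geometry,
left/right or buccal/lingual anatomical asymmetries (the side-specific
exposure patterns a clinical study reports are not built in), alveolar bone
remodeling under tooth movement, and segmentation error in the meshes
themselves. Results on real CBCT/intraoral data additionally depend on
landmark placement quality — which is why the ICC facility simulates
re-digitization noise (default 0.15 mm per coordinate) rather than assuming
perfect repeatability.

## Validation design and problem sizes

The test suite checks, among others: agreement of both signed angles with a
brute-force projection oracle over 1000 random tooth poses to $10^{-9}$
degrees; exact ground-truth recovery on generated arches in all four
quadrants; invariance of every angular and exposure output under common
rigid motions and midsagittal reflection; recovery of designed dehiscence
depths (0.5–5 mm) and fenestration heights (1–3 mm) on cone fixtures within
one sampling step, with convergence under density doubling; exactness of
the Friedman permutation p against exhaustive enumeration at $n = 5$,
$k = 3$ and of the McNemar p against binomial enumeration; type-I
calibration of all three table stages over 1000 seeded null cohorts of 16
patients; and detection of the designed effect structure (crown dispersion
up, root-2 exposure near zero) in at least 90% of 100 seeds. The
calibration and power studies run the cohort at landmark level — angles are
measured through the real geometry path; exposures come from the
generator's analytic ground truth, the mesh path having been validated
separately on the fixtures — which keeps the full suite within a desk-scale
compute budget without weakening any check.

## Known limitations

* A planar crest disc under a tipped tooth measures dehiscence along the
  tipped axis against a horizontal carve, so mesh-mode measurements under
  large designed tip angles carry an $O(1-\cos\theta)$ bias; oracle
  fixtures therefore use untipped poses.
* Fenestration extents are axial; a clinician measuring obliquely along the
  root surface would read up to a few percent more on strongly tapered
  roots.
* The exposure tables treat each tooth as the repeated-measures subject;
  within-patient correlation between teeth is not modeled in the Friedman
  stage, as in the emulated reporting practice.
* The mesh utilities are purpose-built for closed, consistently oriented
  triangle meshes; soup-like scan exports must be repaired upstream.
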