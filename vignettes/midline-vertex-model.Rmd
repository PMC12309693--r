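---
title: "A vertex model of coordinated midline-tissue elongation"
author: "midlinesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A vertex model of coordinated midline-tissue elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midlinesim)
```

## The biological question

During body-axis elongation in the zebrafish embryo, three slender midline
tissues — the floorplate (FP, the ventral-most row of the neural tube), the
notochord, and the hypochord (HC, a cell row ventral to the notochord) —
elongate together at the posterior end of the body. The notochord is the
*leader*: it elongates by cell divisions fed from the chordoneural hinge
(CNH) at the tailbud. FP and HC are *followers*: single-file cell rows that
migrate collectively toward the posterior along the notochord and divide
when stretched. The package implements a two-dimensional vertex model of
this system, asking two mechanistic questions:

1. How must collective migration be distributed along the
   anterior-posterior (AP) axis so that stretch-triggered proliferation is
   spatially unbiased, rather than confined to one end or tearing the
   tissue?
2. Can a purely mechanical posterior tether (a shared adhesion point at the
   CNH) keep follower length matched to leader length when their intrinsic
   elongation rates differ?

## The model

### Geometry

Each tissue is a chain of quadrilateral cells sharing vertices with their
neighbors. A mesh is the vertex set $V = \{r_j = (x_j, y_j)\}$ and cell set
$C = \{C_i\}$, with each cell's four vertices stored in the fixed cyclic
order anterior-basal, posterior-basal, posterior-apical, anterior-apical;
the basal pair $B_i$ is the first two, the apical pair $A_i$ the last two.
$x$ is the AP axis, $y$ the basoapical axis. Each tissue carries an *ECM
frame* — a basal reference line and an apical direction sign — so the same
potentials serve the notochord (apical up), the FP above it (apical up) and
the HC below it (mirrored, apical down). The $x$ coordinates of the two
anterior-most vertices of each tissue are fixed, representing attachment to
the anterior body; everything else is free.

### Energy

Vertices follow a gradient descent on

$$U = \frac{a}{2}\sum_i (V_i - V_0)^2 + \frac{b}{2}\sum_i L_i^2
    + c\sum_i \sum_{r_j \in B_i} f(|r_j - p_j|)
    + d\sum_i \sum_{r_j \in A_i} g(|r_j - p_j|),$$

with $V_i$ the cell area, $L_i$ the cell perimeter, and $p_j$ the foot of
vertex $j$ on the tissue's basal reference line, so $|r_j - p_j|$ is a
basoapical distance. The basal adhesion well is piecewise quadratic,

$$f(x) = \begin{cases}
 (x-h)^2/2 - (h_{th}-h)^2/4 & 0 \le x < (h_{th}+h)/2\\
 -(x-h_{th})^2/2 & (h_{th}+h)/2 \le x < h_{th}\\
 0 & x \ge h_{th},
\end{cases}$$

with minimum $-(h_{th}-h)^2/4$ at the ECM position $h$ and a smooth cutoff
at $h_{th}$; it is continuous and once-differentiable at both breakpoints,
which the tests verify numerically. Apical repulsion
$g(x) = (x-\ell)^2/2$ for $x \ge \ell$ (else 0) confines cells below the
external structure at distance $\ell$. Forces are the exact analytic
gradient $F_j = -\partial U/\partial r_j$, implemented once in compiled
code and cross-checked against central finite differences of the energy at
$10^{-6}$ relative tolerance.

### Dynamics

Vertex motion is overdamped Langevin dynamics,
$\tau \dot r_j = F_j + \sigma \xi(t)$, integrated by Euler–Maruyama with
increments $(F_j/\tau)\,dt + (\sigma/\tau)\sqrt{dt}\,N(0,1)$ per free
coordinate at $dt = 10^{-3}$. Migration enters as a per-cell force $v_i$
applied at the cell's posterior basal vertex, relaxing toward the
position-dependent activity with time constant $\eta$:
$\eta \dot v_i = -v_i + w_i(t)$, integrated by classical RK4 with $w_i$
frozen within a step and recomputed from centroids once per step. The
activity is graded along the axis:

$$w_i = v_{max}\left(\frac{x_i - x_{min}}{x_{max} - x_{min}}\right)^{\alpha}.$$

As printed, $\alpha \to 0$ makes every cell maximally active (uniform
migration) and $\alpha \to \infty$ confines activity to the posterior-most
cell. Scenario presets are therefore named by phenotype —
`uniform` ($\alpha = 0.01$), `graded` ($\alpha = 1$), `posterior_only`
($\alpha = 100$) — so that each preset reproduces the migration pattern its
name describes regardless of how one labels the exponent.

### Division rules

Followers divide under stretch. Each cell's apical and basal edges store
elastic energy $U_i = b\,(L_{i,apical}^2 + L_{i,basal}^2)/2$; when $U_i$
first exceeds $U_{th}$ the cell latches the time $T_i$, and after a latency
$S_i$ it divides at the exact midpoints of its apical and basal edges —
provided $U_i$ is still above threshold when the latency expires
(`latch-and-recheck`; a `latch-and-fire` variant divides regardless; the
recheck default was chosen because a cell whose stretch has relaxed has no
remaining mechanical cue to divide). Both daughters restart with migration
force 0, a fresh age and an unset latch. Division inserts vertices without
moving any existing vertex and conserves area exactly.

The notochord divides on a clock instead. The exposed operation supports
the literal per-cell rule (every cell divides when its age reaches $D$,
both daughters resetting), which is only meaningful at short horizons: with
every cell cycling at $D \approx 1$ the census doubles each period, which
is numerically and biologically absurd at the simulated horizons
($t \approx 50$–100 would give $2^{60+}$ cells). The assembly presets
therefore use a `posterior` clock mode in which only the posterior-most
notochord cell divides, one division per period — the model's abstraction
of elongation by posterior addition from the CNH progenitor pool. This
yields the steady, clock-limited leader growth the coordination scenarios
require, with period $D = 0.8$ (fast leader) or $D = 1.2$ (slow leader).

### Tethering

In tethered assemblies the basal posterior vertex of the posterior-most FP
cell and the apical posterior vertex of the posterior-most notochord cell
are one shared vertex (similarly HC to the notochord's basal posterior
vertex). Merging is a mesh operation: the two vertices are replaced by one
at their midpoint, after which the force on the shared vertex is
automatically the sum of both tissues' energy gradients. Because division
inserts daughters at edge midpoints and never moves existing vertices, the
shared vertex remains the posterior-most vertex of both chains after
posterior divisions — the bond re-attaches itself without special
handling.

## Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $a$ | area stiffness | 5 | see calibration below |
| $b$ | perimeter contraction | 0.02 | see calibration below |
| $c, d$ | basal adhesion / apical repulsion | 5, 5 | strong surface pinning |
| $V_0$ | target area | 1 (0.5 notochord) | unit cell; notochord cells half-width |
| $h, h_{th}$ | ECM position, adhesion cutoff | 0.05, 0.5 | thin ECM gap, short-range adhesion |
| $\ell$ | apical confinement | 1.2 | just above the resting apical surface |
| $\tau, \sigma$ | drag, noise | 1, 0.01 | sets the time unit; weak thermal jitter |
| $dt$ | time step | 0.001 | resolves the stiffest mode comfortably |
| $\eta$ | migration-force relaxation | 1 | same order as shape relaxation |
| $v_{max}$ | migration strength | 2 (single tissue), 0.5 (followers in assemblies) | see below |
| $U_{th}, S$ | division threshold, latency | 0.15, 0.05 | see below |
| $D$ | notochord clock | 0.8 / 1.2 | fast / slow leader presets |
| $m$ | initial cell count | 32 (single tissue), 8 + 8 + 16 (assembly) | canonical study sizes |

Two constraints anchor the mechanical calibration, chosen once from the
energy's structure and then frozen. First, a rest shape must exist: for a
square cell of side $s$, stationarity of the area and perimeter terms gives
$s^2 = V_0 - 8b/a$, so $8b < aV_0$ is required at all and $8b/a \ll V_0$
keeps resting cells near their target area ($a = 5$, $b = 0.02$ give rest
area $0.97\,V_0$). Second, elongation must be clock-limited, not
growth-limited: after a notochord division the daughters must re-expand
toward $V_0$ faster than the clock fires again, which requires the area
stiffness to dominate the viscous drag of the tip region; at $a = 5$ the
measured leader rates differ cleanly between $D = 0.8$ and $D = 1.2$
(about 0.34 vs 0.24 length/time), whereas softer choices make the two
clocks indistinguishable.

$U_{th} = 0.15$ places symmetric division at edge length
$\sqrt{U_{th}/b} \approx 2.7$, i.e. cells divide before their basal edge
reaches the rupture proxy (3 $\times$ the built edge length) when
stretched *slowly* — quasi-static stretching keeps apical and basal edges
comparable. Under *fast* localized stretching (the anchored anterior cell
in uniform migration) the basal edge runs ahead of the apical edge and
crosses the rupture proxy before the elastic threshold fires: this
separation of slow-stretch division from fast-stretch rupture is what makes
the uniform preset flag anterior gaps long before the graded preset does.
The follower $v_{max} = 0.5$ in assemblies sits between the two leader
rates, so followers lag the fast leader and outpace the slow one — the two
regimes the tether has to reconcile. The single-tissue $v_{max} = 2$ gives
a posterior-end speed that produces one to two division waves within
$t = 100$.

## Observables

* `tissue_length`: posterior-most minus anterior-most vertex $x$.
* `uniformity_statistic`: Kolmogorov–Smirnov distance between relative
  division positions (centroid normalized by tissue extent at division
  time) and $U(0,1)$; 0 is perfectly unbiased. The default graded preset
  at default seeds stays below 0.25, the package's operationalization of
  "spatially unbiased proliferation"; the reference phenotypes sit near
  0.88 (posterior-only) and 0.93 (uniform).
* `gap_flag`: a shared-vertex chain cannot literally open a gap, so rupture
  is proxied by basal edges exceeding 3 $\times$ their built length.
* `length_mismatch_series`: per-frame $|L_{follower} - L_{leader}| /
  L_{leader}$.
* `export_kymograph`: rasterized boundary positions over time, 256 bins
  with linear interpolation, closing the loop with the kymograph
  velocimetry in the quantification module.

## Quantification formulas

The measurement formulas used on real embryos are implemented as pure
functions over extracted profiles and ROI statistics (image segmentation
and microscopy I/O are out of scope): the Golgi position index
$(a + b)/2L$; the apical/basal signal ratio over the end 30% fractions of
a membrane profile's arc length; kymograph velocity
$\tan(\theta)\, s_{px}/t_{row}$ with the angle measured from the time axis
(0° = stationary — the convention a kymograph operator would use);
nuclear/cytoplasmic ratio; positive-count fractions; and the paired-profile
normalization: running-minimum baseline extraction from the reference
channel (window 11 samples — wider than any membrane peak, narrower than
the gradient's scale), pointwise division, 20 equal-width AP bins
(half-open, last closed), per-bin means, max-rescaling to 1. Synthetic
generators (`make_kymograph`, `make_paired_profile`, `make_roi_table`)
produce inputs with known ground truth so every formula is tested as a
closed loop: generate with known truth, measure, compare.

## What the synthetic data do and do not show

The generators emulate the *structure* of the measurement data — a moving
front in a position-time raster, a two-channel profile with a shared
depth-decay baseline and narrow membrane peaks, per-cell ROI statistics —
with Gaussian intensity noise and Bernoulli counts. They do not emulate
microscope noise statistics, segmentation error, or optical distortion, so
passing recovery tests demonstrates correctness of the formulas and
pipeline, not robustness to real imaging artifacts. Similarly, the vertex
model abstracts FGF signaling and Yap mechanotransduction into the
activity gradient and the division threshold; it makes no claim about
their molecular dynamics.

## Numerical choices and degenerate inputs

* Determinism: all stochastic steps draw from R's RNG (also inside the
  compiled engine), so a seed fixes a run bit-identically.
* The first branch of $f$ extends naturally to negative basoapical
  distances, so a vertex crossing the basal line feels a smooth restoring
  force rather than a discontinuity.
* Nonpositive oriented cell areas and self-intersecting quadrilaterals
  abort a run with the failing cell and time stamp: they signal a
  parameter regime outside model validity, and continuing would silently
  produce nonsense.
* Degenerate migration gradient ($x_{max} = x_{min}$, e.g. a single cell):
  every cell receives $v_{max}$, since the degenerate gradient carries no
  positional information.
* Simultaneous division triggers are processed in ascending cell index —
  a deterministic tie-break.
* $S_i$ is a single constant (default 0.05) for all cells; per-cell
  latencies exist in the data structures but no scenario sets them.
* The apical confinement distance $\ell$ is measured from the same basal
  line as $h$; nothing in the model requires a separate reference for the
  external structure, and one line per tissue keeps frames minimal.
* Whether notochord cells receive vertex noise: yes (they share the vertex
  dynamics); they receive no migration force.
* HC uses parameters identical to FP; the assemblies are symmetric about
  the notochord.

## Problem sizes

The canonical runs are $m = 32$ single-tissue chains to $t = 100$ and
$8+8+16$-cell assemblies to $t = 60$, both at $dt = 10^{-3}$ — a few
seconds each with the compiled engine. The test suite's stochastic checks
use 5 seeds for the phenotype ordering, 3 seeds $\times$ 4 exponents for
the gradient-shape sweep, and $\geq 10^4$ pooled free coordinates for the
noise-law check.

## Known limitations

* The chain topology is fixed: no T1 transitions, neighbor exchange, cell
  death, or extrusion; the model cannot literally rupture, hence the
  basal-overextension proxy for gaps.
* Cells are quadrilaterals; curved or higher-order cell shapes are out of
  scope.
* The per-cell clock rule (`mode = "all"`) is only sensible at horizons
  shorter than a few periods; long-horizon leader growth requires the
  posterior clock mode.
* The $\alpha$-exponent labels in the migration law are interpreted by
  phenotype, as described above; presets, not raw exponents, are the
  stable interface.
* Follower/leader rate differences are produced by scaling $v_{max}$; the
  model does not represent the upstream signaling that would set those
  rates in the embryo.
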