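---
title: "Methods: signed descending-neuron network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed descending-neuron network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(descnet)
```

# The scientific problem

Descending neurons (DNs) carry motor commands from the insect brain to the
ventral nerve cord (VNC). In *Drosophila*, activating a handful of
"command-like" DNs suffices to drive complete behaviours such as forwards
walking, antennal grooming or backwards walking — yet population recordings
show many DNs co-active during the same behaviours. A resolution of this
tension is that command-like DNs recruit networks of further DNs through
direct synaptic connections inside the brain, and that these networks form
behaviour-specific, mutually inhibiting clusters.

`descnet` implements the computational side of that analysis: building a
signed, directed DN–DN graph from connectome tables, quantifying per-neuron
connectivity and multi-hop reachability, comparing the degree distribution
against shuffled nulls with exponential and power-law fits, detecting
consensus communities with a signed Louvain procedure, and relating clusters
to annotations. A second arm of the package handles the experimental side:
ΔF/F normalisation of trial-structured calcium recordings,
stimulus-triggered response statistics with confidence-interval masking, and
a heuristic behaviour classifier for treadmill and pose data. All of it is
exercised end to end on synthetic data with planted ground truth.

# The DN graph

## Ingestion and naming

Connectome tables arrive in the Codex CSV dialect. Column names drift
between snapshots, so `read_codex_tables()` maps them through a configurable
`codex_columns()` table. Two details matter:

* **Root IDs are 64-bit integers** (about 7.2×10^17), beyond exact double
  precision, so the package carries them as character strings throughout.
* **Self-loops are dropped at load** with a logged count; autapses play no
  role in any downstream analysis.

DNs are the rows with `super_class = "descending"`. Names are assigned by a
fixed precedence: a small manual override list (the four MDN, two aDN1 and
two aDN2 cells, which carry community labels rather than usable type
attributes); then an identical Namiki-format name (`DN` + one lowercase
letter + two digits, e.g. `DNp16`) in both the hemibrain-type and cell-type
attributes; then a Namiki-format hemibrain type; then a Namiki-format cell
type; then a consensus-format cell type (`DN` + letters + digits, e.g.
`DNge078`); otherwise the cell is marked as needing manual intervention.
Conflicting Namiki names in the two attributes also fall into the manual
bucket. Cells without an automatic name keep their root ID as display name
so that graph operations have total naming. A DN is a **GNG DN** (soma in
the gnathal ganglia, the caudal brain region housing most DNs) when the
third letter of its consensus cell type is `g`.

## Edges, signs, thresholds

Two DNs are *connected* when the synapse count summed over all neuropil rows
of the ordered pair reaches `min_synapses = 5`, the convention of the Codex
explorer. The threshold applies to the pair total, not per neuropil row. The
edge's neurotransmitter is a synapse-count-weighted majority vote across the
pair's rows; ties break by the fixed priority ACH > GABA > GLUT > others
(the data source does not specify a tie rule, so the package uses a
deterministic one and logs when it fires).

Signs follow the transmitter under a `sign_policy()`: acetylcholine is
excitatory (+1) and GABA inhibitory (−1). Glutamate can be either depending
on the receptor; the policy therefore offers `inhibitory` (the convention
used for clustering), `distinct` (kept as its own class for display) and
`excluded`. Neuromodulators (dopamine, serotonin, octopamine) and unknown
transmitters are always excluded from signed analyses, though their edges
still count as connections for degree and reachability — connectivity is a
synapse-count question, sign a transmitter question.

## Reachability and degree statistics

Hop reachability uses boolean matrix products on the thresholded adjacency:
the hop-*k* set is the union of the hop-(*k*−1) set and its out-neighbours,
and counts exclude the source cells themselves. Edge weights beyond the
threshold are deliberately ignored: "how many DNs are accessible" is a
count, not a flow. The same machinery yields per-node curves and their
median over all DNs, the population reference against which the command-like
cells' curves are drawn. The unit tests pin this implementation to an
independent breadth-first-search oracle on random digraphs.

Degree histograms use constant bins of five neurons, with zero-degree DNs
included in the first bin (the population statements about weakly connected
DNs count them). The default degree is the out-degree (number of downstream
DNs), the quantity used to order DNs from "broadcasters" (dozens of
downstream DN partners) to "standalone" DNs (none); in- and total-degree
variants are exposed by a flag since the figure source does not name the
direction.

## Shuffled null and distribution fits

`shuffle_connections()` preserves the node count and directed edge count
exactly, reassigning edges to uniformly drawn distinct ordered slots with no
self-loops (rejection-free: slots are sampled without replacement from the
n(n−1) possibilities). In the synapse-preserving mode each edge's count and
sign travel with it — the null used for the clustering comparison; the
binary mode carries only connectivity — the null used for the degree
distribution.

Exponential (`a·e^(−bx)`) and power-law (`a·x^(−b)`) models are fit to the
binned counts at bin centres by nonlinear least squares **on the linear
scale**, with starting values from a log-linear regression. Fit quality is
the plain linear-regression R² on counts, `1 − SS_res/SS_tot`, which is the
only scale on which a negative R² (as reported for real-versus-shuffled
comparisons) is possible. `compare_distributions_r2()` applies the same
definition treating one histogram's counts as predictions of the other's.

# Signed Louvain consensus clustering

## The signed modularity

For clustering, the directed graph is collapsed to an undirected signed one:
reciprocal synapse counts are added with their signs (glutamate inhibitory,
neuromodulators excluded, per the explicit clustering convention). Pairs
whose excitation and inhibition cancel exactly keep a flagged zero-weight
edge. Left/right data are not mirrored.

Modularity on signed weights uses the two-layer decomposition: the positive
and negative subgraphs are scored separately with the standard formula and
combined as `Q = (w⁺Q⁺ − w⁻Q⁻)/(w⁺ + w⁻)`, so within-cluster excitation
raises Q and within-cluster inhibition lowers it. The source text says only
that weights are scaled by synaptic strength and transmitter identity; the
two-layer form is the standard generalisation and is the package default,
with the naive form (negative weights pushed through the standard formula)
available for comparison. On purely positive graphs the signed form reduces
to the standard one, which the tests verify against `igraph::modularity()`.

## The Louvain procedure

`louvain_signed()` is authored in the package (no installed R package
provides signed Louvain): greedy local moving followed by graph aggregation,
iterated to a fixed point. Two refinements matter on signed graphs. First,
the best move for a node can be into a community it shares **no** edges
with — the negative-layer degree term makes unlinked communities attractive —
so besides neighbouring communities the candidate set includes the community
with the best degree-penalty "field" and an empty community; on small levels
(≤ 64 super-nodes) every community is scored exactly. Second, a wall-clock
restart rule would be hardware-dependent, so non-convergence is detected by
a sweep-count cap with reseeded retries. Node sweep order is randomised and
everything is deterministic given the seed. A `restarts` argument runs
best-of-k for single-partition use; the consensus machinery instead keeps
every run. On all test graphs small enough for exhaustive partition
enumeration (≤ 8 nodes, Bell-number search) the returned Q is within 2% of
the global maximum.

## Consensus, ordering, extraction

The Louvain landscape has many local optima, so the pipeline runs it 100
times (resolution γ = 1) and records, for every DN pair, the fraction of
runs in which the two co-clustered — the co-clustering matrix, with unit
diagonal. Ward agglomeration (`ward.D2`) on the distance `1 − co-membership`
gives the final DN ordering; the distance transform is the package's choice
since the source clusters "this matrix" without naming one. Clusters are
then read off in a single left-to-right pass: a DN joins the current cluster
iff its co-membership with the *immediately preceding* DN is at least 25%
(the boundary value joins), otherwise it opens a new cluster; clusters with
fewer than ten members are dropped and their DNs marked unclustered. The
"previous DN" is read as the adjacent DN in leaf order, following the
procedure's verbatim description, rather than as a running-cluster average.

Between-cluster structure is summarised by the signed synapse count from
cluster *i* to cluster *j* divided by the size of the receiving cluster *j*.
The real-versus-shuffled contrast uses one-sided Welch *t*-tests on the
per-run total size of the five largest clusters (and on per-run modularity),
real greater than shuffled — a conservative comparison since runs are
treated as independent points.

## Annotation

Cluster annotation takes user-supplied tables of known DNs: VNC projections
(a DN projects to a neuropil when at least 5% of its presynaptic sites are
there) and behaviour links, both expressed as fractions of the known DNs in
each cluster; brain-input fractions come from the graph's own neuropil
breakdown of synapses received by cluster members. Clusters with fewer than
five known DNs are flagged low-evidence.

# Trial-based calcium analysis

## ΔF/F with a resting baseline

Raw ROI fluorescence is median-filtered (width 3 samples ≈ 0.185 s at
16.23 Hz) then Gaussian-filtered (σ = 3 samples), with reflected edges.
Normalisation is `ΔF/F = (F − F₀)/(F_max − F₀)` per ROI: `F_max` is the 95%
quantile over the whole recording; `F₀` is a *resting baseline* — rest
onsets are moments where at least 75% of the following second is classified
as resting, at least one second after the previous accepted onset and
outside stimulation; the across-onset median trace is minimised over the two
seconds after onset. Without usable rest onsets (e.g. non-behaving
preparations) the 5% quantile stands in. So 0 means resting-level activity
and 1 the 95% activity quantile, making responses comparable across neurons
with different indicator expression. ROIs with `F_max = F₀` are flagged
degenerate and excluded rather than producing non-finite values.

## Stimulus-triggered statistics

Trials qualify when the majority behaviour in the second before stimulation
is walking, and a fly needs at least ten qualifying trials. Aligned windows
run from 5 s before onset to 5 s after offset; each trial's mean activity in
the second before onset is subtracted. The 95% confidence interval of the
across-trial mean is `1.96·SD/√n` (the source does not name its CI
estimator; the normal approximation is used for both the time-course and the
response window, and this shared choice is deliberate). Samples whose |mean|
falls below their CI are masked to 0 — rejecting neurons without consistent
trial-to-trial responses.

A single response value per ROI is the mean over one second centred on the
peak |masked response| within the first 2.5 s of stimulation; ties in the
peak (flat plateaus) resolve to the latest sample so the window sits on the
plateau. The ROI is responsive only if |mean| exceeds the CI during at least
half of that second. Fly-level metrics are the number of activated ROIs
(positive responses), the fraction among visible ROIs, and the summed
positive ΔF/F — negative responses are excluded from the sum because
reduced indicator fluorescence must not be read as inhibition. Flies are
compared with two-sided Mann–Whitney U tests on per-fly means (technical
replicates averaged, biological replicates compared); with three flies per
group in an extreme ordering the attainable two-sided p is exactly 0.1,
a known property of rank tests at such sizes. Multi-fly density maps
register each fly by scaling/shifting y to align the most dorsal and ventral
ROIs and shifting x to the most lateral ROI, then blur with a Gaussian whose
kernel is 1 at its centre, preserving ΔF/F units, and average over flies.

# Behaviour from kinematics

Spherical-treadmill velocities (100 Hz) are median-filtered (width 5 =
0.05 s) then Gaussian-filtered (σ = 10 = 0.1 s); wheel velocities get a
single σ = 20 Gaussian. Motion energy is the frame-to-frame Euclidean
keypoint displacement, averaged over 0.5 s. Front-leg height is the
tibia–tarsus y minus the median coxa y; pixel y grows downward, so lifted
legs are negative.

The classifier is deterministic: backwards walking at ≤ −1 mm/s, forwards
at > +1 mm/s, anterior grooming as a logical OR of a high front leg or a
fast-moving front leg, rest at near-zero speed and motion energy, otherwise
undefined. The walking thresholds are from the study design; the grooming
and rest cutoffs live in supplementary material not reproduced here, so they
are named parameters of `behaviour_thresholds()` with defaults (height
< −5 px; windowed ME ≥ 3 px/frame; rest |v| < 0.3 mm/s and ME < 3) chosen
once to sit far from the synthetic generator's planted episode values —
they are calibration constants a laboratory would tune to its own rig. The
precedence backward > forward > grooming > rest is likewise a package
decision; the conditions are mutually exclusive in intent but not in
arithmetic. The grooming OR-branches take separate thresholds.

Kinematic metrics (abdomen contraction: anal-plate-to-posterior-stripe
distance; front-leg approach: tibia–tarsus-to-neck distance; abdomen dip:
anal-plate height; turn magnitude: absolute undirected turn velocity) are
raw per-frame series; the "change in" framing subtracts the 1-s
pre-stimulus mean at trial alignment in `stim_window_compare()`, which then
averages the first 2.5 s of stimulation per trial, averages trials within
fly, and runs the across-fly Mann–Whitney test.

# The synthetic generators

The generators exist to verify machinery, not to imitate fly biology.

**Connectome** (`generate_connectome()`): a planted partition of 120 DNs in
4 clusters with predominantly cholinergic within-cluster connections
(p = 0.25, transmitter mix 88% ACH) and predominantly GABAergic
between-cluster connections (p = 0.04, 80% GABA), mirroring the
excitatory-within / inhibitory-between cluster organisation; synapse counts
are shifted negative binomial (mean 12, size 4), so a realistic minority of
connections falls below the 5-synapse threshold; 5% of DNs are broadcaster
hubs with Pareto-tailed extra out-degree; connections are split across one
to three neuropils from a small fixed vocabulary (GNG, leg and wing
neuropils with hemisphere suffixes) with a 70% GNG synapse share; a few
non-descending neurons with DN contacts exercise the super-class filter; and
the naming attributes cover every branch of the assignment rules. What it
does **not** emulate: the real degree sequence, cell-type census, spatial
synapse positions or hemispheric symmetry — so passing tests demonstrate
correct machinery on clustered signed graphs, not biological fidelity. One
visible consequence: the default generator's out-degree histogram is
bell-shaped rather than decaying, so decaying model families fit it poorly;
the fits' correctness is instead pinned by closed-form tests in which data
generated exactly from each model family are recovered with R² = 1.

**Trials** (`generate_trial_recording()`): 60 ROIs, 40 stimuli of 5 s with
10-s intervals at 16.23 Hz. Recruited ROIs (30%) respond through a calcium
kernel with fast rise (τ = 0.3 s) and slow decay (τ = 1.5 s) — rise much
faster than decay, decay of order seconds, as for slow indicators; the
constants are configuration, not claims. Planted amplitudes are in
normalised ΔF/F units, which only makes sense if each ROI's 95% quantile
reflects its own full range: every ROI therefore shows full-range
spontaneous plateau bouts placed mid-interval (seconds 4–7 after offset,
clear of the pre-stimulus baseline window) plus a lead-in bout, together
exceeding the 5% duty cycle that pins `F_max` to the plateau. Behaviour
labels rest mid-interval and walk before 90% of stimuli, guaranteeing both
rest onsets for the baseline and enough qualifying trials. Noise is Gaussian
(SD 0.03 ΔF/F). With 30 trials the planted amplitudes are recovered within
10% and responder identity at ≥ 95% — verified in the acceptance tests.

**Kinematics** (`generate_kinematics()`): piecewise 2-s episodes of forward
(5 mm/s), backward (−3 mm/s), grooming (static lifted front leg) and rest,
with keypoint geometry consistent with the classifier's definitions and
planted velocities far from the thresholds. Landmark pairs used by the
change metrics share a y coordinate so a planted displacement changes the
distance by exactly its amplitude. On noise-free series the classifier is
exact **on the raw features**: the velocity filters exist to denoise real
measurements, and smearing a noise-free step through them would
misclassify transition frames by construction, so the noise-free check
bypasses filtering while the noisy check (SD 0.15) applies the full
filter chain and still exceeds 95% accuracy.

# Numerical choices and limitations

* Seconds convert to samples by rounding to the nearest sample; sampling
  rates are explicit arguments everywhere.
* All stochastic steps (generators, shuffles, Louvain sweeps) take explicit
  seeds; consensus runs derive per-run seeds from one master seed.
* Fit starting values come from log-linear regression on non-empty bins;
  non-convergence raises an error carrying the starting point.
* The Mann–Whitney wrapper uses exact enumeration for small untied samples
  and the normal approximation otherwise, returning the maximal p = 1 when
  the pooled sample is fully tied.
* Problem sizes in the test-suite and the acceptance script (120-node
  connectomes, 100 Louvain runs per arm, 30-trial recordings, 60-s
  kinematic series) are the package's chosen desk-scale study conditions;
  the same code runs unchanged on full-size connectome tables.
* Known limitations: the optional disynaptic-via-interneuron count needs the
  full non-DN connection table and is not validated against a printed value;
  no maximum-likelihood (Clauset-style) power-law tail estimation — the fits
  are least-squares by design; no Leiden/Infomap backends; no pose
  estimation, motion correction or ROI segmentation — inputs begin at
  extracted traces, velocities and keypoints.

# A worked miniature

```{r example, message = FALSE, warning = FALSE}
sim <- generate_connectome(connectome_sim_spec(n_dns = 60, seed = 1))
graph <- build_dn_graph(sim$neurons, sim$connections)
cc <- consensus_coclustering(symmetrize_signed(graph),
                             n_runs = 20, seed = 2)
clusters <- extract_clusters(cc)
glance(cc)
clusters
```
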