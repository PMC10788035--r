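---
title: "Local structural replacement search: methods and design"
author: "lsrsearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local structural replacement search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A recurring task in medicinal chemistry is to replace a moiety of a lead
compound -- a catechol, an amide, a phosphate -- with a *bioisostere*: a
chemically different group that occupies the same space in the binding site
and preserves the interaction pattern with the protein. `lsrsearch`
mines a corpus of protein--ligand complexes for such *local structural
replacements* (LSRs): ligand substructures from other complexes of the same
(or a homologous) protein that, after the binding sites are brought into a
common frame, sit where the reference moiety sits.

The search has six stages:

1. **Corpus and reference selection.** Complexes are read from PDB-format
   files. Every het group except water becomes a ligand instance; metal
   ions are kept as single-atom ligands, because cations can themselves
   take part in a local replacement. A *reference ligand* is any ligand
   containing the query moiety as a substructure.
2. **Homologue selection.** The chain holding the reference ligand is
   globally aligned (BLOSUM62, affine gaps, open 11 / extend 1) against
   every chain of every other complex; targets with at least 90% identity
   over at least 50 aligned residues are retained, one best chain per
   complex.
3. **Superposition.** The mapped C-alpha pairs are fitted by least squares
   (Kabsch); the resulting proper rotation and translation are applied to
   every atom of the target, ligands included. No reflection is ever
   admitted.
4. **Probe capture.** Every atom of the matched reference moiety becomes
   the centre of a probe sphere of radius 2.5 Angstrom. A target-ligand
   heavy atom is captured iff it lies inside (or exactly on) any sphere:
   membership is a closed ball, because the boundary convention must be
   fixed somewhere and the closed choice makes the monotonicity property
   (larger radius never captures less) exact.
5. **Fragment induction and fitness.** Captured atoms are induced into
   connected components; every bond to an uncaptured neighbour is cut and
   capped with a wildcard attachment atom. Components smaller than 3
   heavy atoms are dropped (single metal ions are exempt). Each fragment
   is scored against the reference moiety on a [0,1] shape +
   electrostatics scale and discarded below 0.2; the boundary value 0.2
   itself survives.
6. **Post-processing.** Surviving fragments are deduplicated by canonical
   SMILES (best-fitness representative, provenance pooled), categorized by
   ring/element composition, fingerprinted (2048-bit circular), clustered
   with a tuned unsupervised algorithm and embedded in 2-D by PCA.

## The fitness score

External shape/ESP overlay programs treat the score as a black box with
three contractual properties: range [0,1], the value 1 for a perfect
match, and a practical acceptance floor near 0.2. `lsrsearch` implements a
scorer with exactly these properties from first principles:

* **Shape** is the Gaussian-volume Tanimoto
  \(V_{AB} / (V_{AA} + V_{BB} - V_{AB})\). Each heavy atom carries an
  isotropic Gaussian of width \(\sigma_i = s \cdot r^{vdw}_i\) with
  \(s = 1/\sqrt2\) by default, so a carbon Gaussian decays to \(1/e\) at
  1.7 Angstrom -- its van der Waals radius. All pair integrals are closed
  form, so self-similarity is exactly 1.
* **Electrostatics** is the Hodgkin index
  \(H = 2\langle\psi_A\psi_B\rangle / (\langle\psi_A^2\rangle +
  \langle\psi_B^2\rangle) \in [-1,1]\) of Gaussian-smeared charge fields
  (width 1.0 Angstrom), mapped to \((H+1)/2\). Partial charges come from an
  electronegativity-equalization (EEM) solve on the heavy atoms: all
  atomic chemical potentials equal, total charge zero, Coulomb
  off-diagonals screened at short range by the Louwen--Vogt interpolation
  so the system stays diagonally dominant at bonding distances. Two
  fragments whose fields are identically zero (pure-carbon fragments, for
  instance) are electrostatically indistinguishable and score 1; a
  fragment against its charge-negated copy scores exactly 0.
* **Combination** is the arithmetic mean (weight 0.5), so the combined
  self-score is exactly 1 and every component lives in [0,1].

Scoring never re-aligns the fragments: positions come from the
superposition stage, which is the whole point of a geometry-first search.
The score deliberately does not distinguish hydrogen-bond donors from
acceptors; it measures conservation of the interaction locus, not its
polarity direction.

## Chemical perception

PDB het groups carry no bond orders. Connectivity is the union of
deposited CONECT records with a distance rule: two heavy atoms bond iff
their distance is at most the sum of their covalent radii plus 0.4
Angstrom (atoms closer than 0.5 Angstrom are a hard error). Bond orders
and aromatic flags are then completed by OpenBabel's valence perception
on the same coordinates. Because geometric order perception is brittle
under coordinate noise -- a flat six-ring with 0.1 Angstrom noise is
occasionally read as saturated -- a geometric ring-aromaticity pass runs
afterwards: a 5- or 6-ring of C/N/O/S atoms, each with at most three
heavy neighbours, whose atoms deviate from their least-squares plane by
at most 0.25 Angstrom (about 2.5 times a typical coordinate uncertainty)
and whose mean ring bond length lies in 1.25--1.47 Angstrom (saturated
rings sit near 1.54), is flagged aromatic. Substructure matching compares
elements, aromatic flags, and the aromatic/non-aromatic bond class;
exact orders beyond aromaticity are not compared, because PDB-derived
orders are perception artifacts. Stereochemistry is ignored throughout:
deposited ligand stereo is unreliable without hydrogens.

Hydrogens are dropped on input everywhere (deposited structures mostly
lack them); implicit hydrogens are restored by the SMILES writer. Of
alternate locations the highest-occupancy conformer is kept, ties going
to altloc A. Only the first model of a multi-model file is read, and the
asymmetric unit is used as deposited.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `probe_radius` | 2.5 | Angstrom | sphere radius around each reference-fragment atom |
| `fitness_threshold` | 0.2 | -- | empirical acceptance floor of shape/ESP overlay scores |
| `min_identity` | 90 | % | "very close or identical" homologues; configurable |
| `min_aligned` | 50 | residues | guards against spuriously high identity on short overlaps |
| `min_atoms` | 3 | atoms | suppresses noise fragments; metal ions exempt |
| `shape_sigma` | 0.707 | -- | vdW-radius multiplier for shape Gaussians |
| `esp_sigma` | 1.0 | Angstrom | charge-smearing width |
| `esp_weight` | 0.5 | -- | arithmetic mean of shape and ESP |
| fingerprint `n_bits` | 2048 | bits | folded circular fingerprint length |
| fingerprint `radius` | 2 | bonds | circular environment radius (ECFP4) |

The homology cutoffs are declared assumptions, not literature values: the
protocol this package implements only says the homologues should be very
close or identical, so both are exposed as configuration.

## Clustering post-processing

Fingerprints are OpenBabel ECFP4 circular environments (radius 2), folded
by OR from 4096 to 2048 bits. The Tanimoto distance matrix
\(D_{ij} = 1 - |fp_i \wedge fp_j| / |fp_i \vee fp_j|\) (zero diagonal;
two empty fingerprints are at distance 0 by convention) is the common
yardstick: the silhouette coefficient of *every* algorithm is evaluated
on it, while vector-space algorithms operate on the raw binary vectors
with Euclidean geometry. Eight algorithms are available: k-means
(multi-restart, 20 starts, fixed seed), agglomerative (average linkage by
default), spectral (Gaussian kernel, bandwidth = median pairwise
distance), mean-shift, DBSCAN, OPTICS (reachability ordering with
DBSCAN-style extraction), affinity propagation (damping 0.9), and a
simplified BIRCH (incremental leader pass with a radius threshold, then
Ward merging of subcluster centroids; no CF-tree rebalancing).

Cluster-count selection uses both the elbow (SSE vs k) and silhouette
curves. The selected k is the silhouette argmax, with one guard: k = 2
often wins the silhouette by trivially splitting the data in half while
leaving the within-cluster scatter large, so k = 2 is rejected whenever
SSE(2) exceeds half of the total (k = 1) scatter, and the next-best
silhouette is taken. The 0.5 ratio is this package's operationalization
of "the SSE is still relatively large"; it is a configuration argument
(`sse_ratio`). For bandwidth-style algorithms the silhouette is scanned
over a quantile grid of pairwise distances and the argmax reported;
candidates that collapse to fewer than two clusters are excluded, and an
all-degenerate scan is an error listing the cluster counts seen.

PCA embeds the centred fingerprint vectors in 2-D or 3-D. The embedding
is deterministic including sign: each component is flipped so its
largest-magnitude loading is positive. Rank-deficient inputs are padded
with zero coordinates rather than erroring.

Composition categories partition the fragments: a single heavy atom is
labelled by its element ("F"); otherwise the label is the ordered heavy
element set ("C+O+N", priority order C, O, N, S, ...), prefixed with
"cycle " when the fragment contains a ring, with unlisted element sets
pooled into "cycle other" / "acyclic other". The predefined set list is
configuration (`category_vocab()`), since how fine to slice the
vocabulary is a presentation choice, not a property of the method.

## The synthetic fixture generator

`generate_fixture_corpus()` builds the study conditions under which the
pipeline is tested: one reference complex whose ligand is a
3-methylcatechol (the 3-substituted catechol query
`Oc1cccc([R])c1O` matches its catechol core, with the methyl standing at
the attachment position), plus three homologous targets by default. Each
target is the same 60-residue C-alpha-trace chain -- long enough for the
50-aligned-residue homology floor -- under a random rigid motion with
0.1 Angstrom Gaussian coordinate noise, a magnitude typical of
well-refined crystal structures, and carries a planted pyridine ligand
whose ring centroid coincides with the reference catechol ring before
the motion. Ligand placement is clash-checked against the chain at 1.5
Angstrom. Everything is deterministic under one seed.

What the fixtures emulate: homologous binding sites in arbitrary frames,
coordinate noise, a replacement fragment spatially coincident with the
reference moiety, PDB round-tripping (3-decimal coordinates, CONECT
connectivity without orders). What they do not emulate: side chains and
backbone atoms beyond C-alpha, binding-pocket flexibility, crystal
contacts, multiple ligand copies, and the chemical diversity of a real
corpus. A passing planted-recovery test therefore demonstrates the
geometric and chemical plumbing end to end, not retrieval performance on
deposited structures.

## Numerical choices and degenerate inputs

* Kabsch fitting requires at least 3 point pairs and rejects collinear
  sets (second singular value below 1e-8 of the largest).
* Probe capture is a closed ball; ties at the boundary are inclusions.
* Ranking ties break by smaller heavy-atom count, then lexicographic
  SMILES, making result tables fully deterministic.
* Fragments whose aromatic ring is cut open are emitted with single
  bonds (a broken aromatic system is not aromatic); their wildcard caps
  are placed at the coordinates of the lost neighbours.
* k-means is fitted on distinct fingerprint rows (duplicates inherit
  their row's cluster) so duplicated fingerprints cannot break centre
  sampling; k equal to the number of points yields SSE 0 by assignment.
* Silhouette: singleton clusters score 0; fewer than two clusters is an
  error.
* EEM charges: a single atom is assigned charge 0; the linear system is
  deterministic, so charges are reproducible to the last bit.

Test problem sizes were chosen to exercise every code path at
interactive scale: 200 randomized capture fixtures, 10 end-to-end
corpora of 4 complexes each, planted fingerprint blob sets of about 200
points for g = 2..6, and brute-force silhouette checks on up to 12
points. The full suite runs in about a minute on one CPU.

## Known limitations

* The fitness scorer is a self-contained shape/ESP model with the
  contractual properties of overlay indices; its absolute values are not
  interchangeable with any external program's output.
* Homologue detection is sequence-only; structure-based detection of
  remote homologues is out of scope.
* Fragments are reported as replacement ideas; re-merging them into
  complete ligands (attachment-compatible synthesis planning) is
  deliberately not attempted.
* Multimeric assemblies are not expanded; the best single chain pair is
  used per target complex.
* Captures from different reference hits are pooled and deduplicated
  globally after per-reference extraction.

## A worked call

```{r, eval = FALSE}
library(lsrsearch)
corpus <- generate_fixture_corpus(fixture_spec(seed = 1))
res <- run_search("Oc1cccc([R])c1O", corpus, search_config(seed = 1))
res$table[, c("smiles", "fitness", "category", "self_replacement")]
```

On the default fixtures this reports the planted pyridine
(`c1cccnc1`, category `cycle C+N`) with a combined fitness around 0.7,
well above the 0.2 acceptance floor.
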