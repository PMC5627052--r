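---
title: "Mining and annotating neuropeptide precursors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and annotating neuropeptide precursors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmine)
```

# The problem

Neuropeptide precursors (preprohormones) share a stereotyped architecture:
an N-terminal signal peptide, then one or more bioactive peptides released
by prohormone convertases at single or paired basic residues (K/R), often
with a C-terminal glycine that is converted into an amide on the preceding
residue, and frequently with an N-terminal glutamine that cyclises to
pyroglutamate (written `pQ`). Many precursors carry *multiple copies* of
identical or related peptides, and the number of copies per precursor is a
heritable, comparable trait: across related species it is often conserved
for tens of millions of years, with occasional clade-specific gains and
losses traceable to point substitutions in cleavage sites or amidation
donors.

`npmine` implements this entire analysis surface: finding candidate
precursors in transcript data by translated similarity search, partitioning
a precursor into signal peptide / cleavage sites / mature peptides,
counting copies under explicit peptide predicates, comparing copy numbers
across species grouped into clades, explaining losses at alignment level,
and clustering whole precursors by all-vs-all similarity. A seeded
synthetic-precursor generator with exact ground truth closes the loop: every
stage is testable without any external download.

# Precursor annotation

## Signal peptide

The built-in call combines the two classical signatures of a signal
peptide. For each candidate cleavage position $p$ (the 0-based index of the
first mature residue, scanned over `min_signal_cleavage = 15` to
`max_signal_cleavage = 35`):

$$\mathrm{score}(p) = 0.7\,H(p) + 0.3\,S(p)$$

where $H(p)$ is the mean Kyte–Doolittle hydropathy of residues
$[p-13, p-3)$ — the h-region window — rescaled linearly from $[-4.5, 4.5]$
to $[0,1]$, and $S(p)$ encodes the von Heijne $(-3,-1)$ rule: 1 if both
positions $p-1$ and $p-3$ hold small residues (A, G, S, C, T, V), 0.5 if
exactly one does, 0 otherwise. Cleavage is called at the argmax (ties go to
the smallest $p$, making the call deterministic) and a signal peptide is
present when the score reaches `signal_threshold`.

The default threshold of **0.34** is deliberately *sensitive*: when mining
transcriptomes, a missed precursor is costlier than a false signal call,
and downstream evidence (cleavage sites, peptide structure) filters false
positives. The corollary, visible in the tests, is that random open reading
frames are frequently "signal-positive" at this threshold — specificity is
the job of the E-value cut-off and the architecture checks, not of the
signal stage. Units: the score is dimensionless in $[0,1]$; positions are
residues.

Externally computed SignalP calls (short format) can be parsed with
`read_signalp()` and passed to `annotate_precursor(signal_override=)`,
replacing the heuristic while keeping the rest of the pipeline identical.

## Cleavage sites

Maximal runs of K/R at or after the signal cleavage point are candidate
sites: runs of length 2 are dibasic (accepted when the pair is in
`dibasic_motifs`, default {KR, RR, KK, RK}), longer runs are polybasic
(one site, cleaved C-terminally), and single residues are monobasic sites,
with R enabled and K disabled by default — monobasic K processing is rare
and the evidence for it in this family of pipelines is thin, so it is a
flag, not a default.

A single basic residue is only an *independent* site when no other basic
run lies within `monobasic_min_gap = 2` residues. This context rule is what
lets the package have monobasic R cleavage on by default and still annotate
a peptide such as `pQGPRamide` correctly: in `...QGPRG KR...` the internal
R sits two residues before the dibasic site, inside the processing context,
and releasing a free glycine by cleaving there would be spurious. The rule
is positional and deterministic; it never consults peptide content.

## Mature peptides and PTM flags

Segments between the signal end, the sites and the sequence end become
mature peptides. A segment ending in G immediately before a site is
amidated — the glycine is the amide donor, removed from the processed
sequence but kept in the segment coordinates. A processed sequence starting
with Q is flagged pyroglutamated (a convention, not a probabilistic
prediction: N-terminal Q cyclises readily and the field writes such
peptides `pQ...`). The final segment has no following site, is flagged
`c_terminal_fragment`, and can never be amidated. Display notation is
`pQ` + rest + `amide`, so a processed `QGPR` with both flags prints as
`pQGPRamide`; the peptide length *includes* the pQ residue (pQGPR is a
tetrapeptide) and excludes the donor glycine.

Every annotation satisfies a reconstruction invariant, asserted on every
call: signal region + unprocessed segments + site motifs, concatenated in
coordinate order, reproduce the input exactly. Segments that look like
acidic spacers are *retained* in the peptide table — there is no formal
peptide-vs-spacer rule, so classification is left to the caller's
predicate; rendering marks a segment as a spacer when its D/E fraction
exceeds `spacer_max_acid_fraction = 0.5`, a display decision only.

## Peptide predicates

Copy counting is always relative to an explicit, serialisable predicate
(`parse_predicate()`): atoms for length, prefix/suffix/substring, amidation,
pyroglutamation and residue counts, combined with and/or/not. C-terminal
fragments are excluded from counts unless a predicate opts in with `cterm`,
because a trailing fragment is an artefact of truncation, not a peptide
copy. The synthetic generator's default family predicate
(`spec_predicate()`) is "contains the family's diagnostic core motif, and
is amidated if the family is": under this definition a peptide fused across
a destroyed cleavage site counts once (one longer peptide instead of two
copies) and a copy that lost its amidation donor drops out of the family
count — which is exactly how copy-number loss manifests in cross-species
comparisons.

# The translated search

The desk-scale search stage is an affine-gap Smith–Waterman (Rcpp) over the
six-frame translations of the transcripts, with a Karlin–Altschul E-value
$E = K m n e^{-\lambda S}$ using conventional ungapped constants per matrix
(BLOSUM62: $\lambda = 0.3176$, $K = 0.134$; BLOSUM45: $\lambda = 0.2291$,
$K = 0.0924$); $m$ is the query length and $n$ the total residue count of
all six frame translations. Two cut-off regimes are first-class presets:
`discovery` ($E \le 1000$ — find anything resembling a known precursor) and
`crossspecies` ($E \le 10^{-6}$ — pull orthologues of established
precursors out of many species). No score-level reproduction of a seeded
heuristic search is attempted; the contract is threshold-respecting
behaviour, determinism (tie-breaks: diagonal > up > left, earliest maximal
cell in row-major order), and exact agreement with an exhaustive
path-enumeration oracle on short sequences plus an independent aligner on
longer ones.

ORF extraction takes a hit's frame and amino-acid interval and extends to
the nearest stop codon or sequence end on both sides; stop-to-stop
stretches are accepted *without* requiring an initiator methionine
(transcriptome contigs are frequently 5'-truncated), with a `require_met`
flag for the stricter convention. Coordinates are 0-based, half-open,
reported on the forward strand with the frame sign carrying the strand.

# Copy-number evolution

The species × family matrix stores a non-negative count or an explicit
missing value; a cell is missing (never zero) when the annotation is absent
or partial, because a truncated precursor's count is a lower bound, not a
measurement. Clade summaries report mean, median and mode; the median is
the *lower middle* value for even group sizes so statistics over small
integer counts stay integers, and the mode takes the smallest value among
ties. Outliers are deviations from the clade *mode* rather than mean ± sd:
on near-constant small-integer data the mode is the natural reference and
matches how such exceptions are described qualitatively (16 copies against
a clade otherwise at 19).

`explain_copy_loss()` maps the reference precursor's functional residues —
every K/R of every cleavage site, every amidation donor glycine — through
the alignment and reports, per species, the columns where the residue
leaves the allowed set; gap columns report `-`. A companion summary
distinguishes *destroyed* sites (every basic substituted) from *weakened*
ones (one basic left, still cleavable under the monobasic rule), because
the two support different biological conclusions.

# Similarity clustering

The clustering stage builds the complete graph of pairwise local-alignment
scores (BLOSUM45 by default — full precursors are often highly divergent)
with p-value `min(1, E)`, extracts connected components at a p-value
cut-off, and embeds the graph with a seeded force-directed layout:
attraction $a_{ij}(x_j - x_i)$ on edges with $p \le$ `pvalue_cutoff`
($10^{-3}$ default), $a_{ij} = \min(-\log_{10} p, 20)$ — the cap prevents
identical-pair singularities — and repulsion
$(x_i - x_j)/\max(\lVert x_i - x_j\rVert^2, 10^{-6})$ between all pairs,
with damping 0.9 and a per-iteration step cap of 0.1 over 1000 iterations.
Displacements are computed synchronously from the current coordinates, so
the trajectory is a deterministic function of (edges, seed, parameters) and
translation-invariant. These defaults are declared package choices; no
published parameterisation of the original interactive tool is being
reproduced, and no exact layout is promised — the tested claims are
determinism, component correctness against a union-find oracle, and
statistical separation of planted families.

# The synthetic generator

`generate_precursor()` builds `signal + [template(+G) + site (+ spacer +
site)]×n + tail` with: a signal of M + a hydrophobic core (L/A/V/I, final
residue fixed to L so the argmax of the signal score lands exactly on the
designed boundary) + `ASA`; separators KR, RR, monobasic R, or alternating
(mixed); optional acidic spacers, each flanked by its own cleavage site as
in real multi-copy precursors; and a short non-matching C-terminal tail.
The transcript wraps the coding sequence in random UTRs with uniformly
sampled synonymous codons; the 5' UTR ends with an in-frame terminator so
the CDS is recoverable as one clean ORF.

The generator's contract — `annotate_precursor()` with the default
configuration reproduces the expected signal boundary, sites and peptides
*exactly* — is asserted at construction time. Architectures that cannot be
recovered (a template as hydrophobic as a signal core; a template with an
internal basic residue next to a monobasic separator) are rejected with an
error instead of emitting misleading truth. Knockout operations emulate the
substitutions behind copy-number loss: `basic_to_X` destroys a site (the
flanking peptides fuse), `glycine_to_X` removes one amidation donor.

Clade datasets derive every species from a single master architecture —
species with fewer copies lack the trailing copy slots — so the multiple
alignment exists by construction and no aligner is needed. Background
divergence is 5% random substitutions confined to template residues after
the diagnostic core motif and to the tail; functional residues (signal,
separators, donors, template cores, N-terminal glutamines) are never
touched by background mutation, which is what keeps the ground truth
recomputable without re-annotating. Substitutions never introduce K, R or
G (no spurious sites or donors) and avoid strongly hydrophobic residues
(no second signal-like stretch).

What the generator does *not* emulate: expression levels, sequencing error,
assembly fragmentation or misassembly, alternative splicing, and real
inter-family sequence homology. Passing tests therefore demonstrate that
the algorithms are correct on clean architectures with known truth — not
that the pipeline is robust to assembly artefacts in real transcriptomes.

# Stand-in datasets and problem sizes

The supplementary sequence sets behind the published per-precursor
descriptions are external deposits, so the packaged worked examples run on
*generated stand-ins* (`synthetic_repertoire()`,
`synthetic_clade_datasets()`) whose architectures mirror those
descriptions: 21 pQXXXamide tetrapeptides on one TRH-type precursor; two
pQGPRamide copies plus two longer GPRamide peptides on a second; four LFWVD
copies with a cysteine-rich tail; seven or eight amidated GW-motif
peptides; three-, four- and two-peptide precursors for the CCK-type,
tachykinin-type and kisspeptin-type examples; clade copy numbers 13/12/11
for the F-type SALMFamide-like family (with one mild exception per clade
that leaves the medians untouched), a 16-versus-mode-19 TRH outlier, and a
3-versus-4 kisspeptin outlier. Sequences are synthetic; only the annotated
architecture is modelled. Clade sizes (9/13/17, 8/10/14, 8/10/12 species)
were chosen once as plausible for a multi-species transcriptome survey in
which most, but not all, species yield a complete precursor.

Test problem sizes are package choices made for tight, deterministic
verification: copy-number recovery runs the full grid of 1–25 copies ×
{dibasic, monobasic, mixed} × {spacer, none} × 20 seeds (3000
architectures); the Smith–Waterman oracle comparison enumerates all
alignment paths for every pair of sequences up to length 3 over a
four-letter alphabet plus a seeded sample of longer pairs, with an
independent aligner (`Biostrings::pairwiseAlignment`) covering lengths up
to 40; clustering separation uses two 20-member families at 10%
divergence and five layout seeds.

# Numerical and degenerate-input decisions

* Coordinates are 0-based half-open everywhere; reverse-strand features are
  reported in forward-strand coordinates with the frame sign carrying the
  strand.
* Standard genetic code only; codons containing N translate to X; a
  leading CTG/TTG is *not* treated as an initiator.
* Signal-score ties go to the smallest cleavage position; traceback
  tie-breaks in the aligner are fixed (diagonal > up > left; gap chains
  close in preference to extending on equal score).
* Records shorter than the minimum signal length annotate as partial with
  sites scanned from position 0 — peptides are still derived, but the
  annotation is excluded from copy matrices.
* A clade with no non-missing counts reports absent statistics, never
  zeros; conflicting duplicate (species, family) counts are an error, not
  a silent overwrite.
* The repulsion denominator is floored at $10^{-6}$; attraction weights are
  capped at 20; non-finite layout coordinates abort with the iteration
  index.
* Manual curation of alignment colours is supported only as an explicit
  overlay table, never as silent edits.

# Known limitations

* The signal heuristic is a two-feature approximation tuned for recall; it
  is not a replacement for a trained signal-peptide predictor on real data
  (use the SignalP adapter for that).
* Monobasic K sites, non-standard convertase motifs, and
  cleavage-probability models are out of scope; the monobasic context rule
  is a deterministic approximation of processing context.
* The E-value uses ungapped Karlin–Altschul constants with affine-gap
  scores; it is a ranking/threshold device, not a calibrated significance
  estimate.
* Disulfide connectivity (e.g. cystine-knot or N-terminal bridges) is not
  modelled; cysteine counting is available through the generic residue
  predicate.
* Copy-number evolution is summarised descriptively (medians, modes,
  outliers, knockouts); ancestral-state reconstruction and rate tests are
  non-goals.
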