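---
title: "Characterizing long modular metallothioneins with modmt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing long modular metallothioneins with modmt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modmt)
```

# The problem

Metallothioneins (MTs) are small cysteine-rich proteins that coordinate
Zn(II), Cd(II) or Cu(I) through metal--thiolate bonds. Fungal Cu-thioneins
span an extreme size range: from 26-residue proteins with seven cysteines up
to multi-hundred-residue polypeptides built by tandem amplification of a
basic 7-Cys unit. `modmt` implements the computational side of
characterizing such a protein: deciding whether a candidate sequence is
MT-like, dissecting it into its repeated Cys-box modules, reconstructing the
exon/intron structure of its gene from a cDNA-versus-scaffold comparison,
assigning deconvoluted native ESI-MS peaks to metal stoichiometries, turning
ICP-AES element concentrations into metal-per-protein ratios, predicting
Cu(I)-binding capacity from the module architecture, and normalizing
Cu-tolerance growth assays. A set of seeded generators produces synthetic
proteins, genes, peak lists and growth tables with machine-readable ground
truth, so every analysis stage is validated by parameter recovery.

# MT-likeness and composition

`summarize_composition()` reports residue counts, the Cys fraction, His/Met
counts, aromatics (F/W/Y) and the number of Cys in CXC motifs. A Cys at
position $i$ is "in a CXC motif" when position $i-2$ or $i+2$ is also Cys;
the intervening X may be any residue, Cys included (the motif notation
places no exclusion on X, so `CCC` contains one CXC window).

`is_mt_like()` applies two rules: Cys fraction at least `min_cys_fraction`
(default 0.15, well below the ~25% seen in clear MT candidates, so the
screen is permissive) and zero aromatic residues. Histidine is counted
separately and never disqualifies: it is a plausible metal ligand, not an
aromatic in the sense of the screen.

`average_mass()` computes the average (not monoisotopic) molecular mass.
All mass arithmetic uses one pinned atomic-weight table (IUPAC 2005 values:
H 1.00794, C 12.0107, N 14.0067, O 15.9994, S 32.065). Two routes are
provided: a residue-mass table derived from residue elemental formulas, and
a full elemental accumulation over the sequence. They share only the atomic
weights, so their agreement (asserted to 0.01 Da in the tests) checks the
residue table against the elemental bookkeeping. The
`n_term_extension` argument covers constructs such as the Gly--Ser pair left
by thrombin cleavage of GST fusions.

```{r}
rec <- read_protein_fasta(system.file("extdata", "fungal_mts.fasta",
                                      package = "modmt"),
                          source = "in_paper")[["Ncrassa_MT"]]
summarize_composition(rec)
```

# Cys-box decomposition

The repeating unit of long modular fungal MTs is a 7-Cys box with consensus
`CXCX3CSCPPGXCXCAXCP`. `modmt` represents it as a *gap signature*: the
residue spacings between consecutive mandatory cysteines, here
$(1,3,1,4,1,2)$, matched with a per-gap tolerance of $\pm 2$. Tolerance is
required because homologous boxes differ in spacing -- the classic 26-aa MT
arrangement is $(1,5,1,3,1,2)$, alignable to the consensus -- while $\pm 2$
still rejects unrelated Cys runs. A strict regular expression would not
admit this flexibility.

Scoring: each placed mandatory Cys contributes one base unit; conserved
residues add bonuses of 1 (Ser after the third Cys; Pro-Pro-Gly in the
four-residue gap; Ala after the sixth Cys; a Pro closing the box) and
charged residues (K/R/E/D) immediately flanking the box add 0.5 each,
reflecting the predominance of small residues between the cysteines and the
conservation of charged residues at the module boundaries. A perfect box
scores 13 before flanking bonuses.

Six-Cys boxes are modelled as *degenerate* variants of the 7-Cys profile:
exactly one mandatory Cys dropped, at a penalty of one base unit. Dropping
an interior Cys merges its two flanking gaps; conserved-residue bonuses from
the right-hand gap are carried into the merged gap at their nominal offset,
so a genuine 6-Cys box keeps credit for its Ser/Pro-Pro-Gly/Ala residues.
(Without this carry-over a true 6-Cys box can be outscored by a spurious
placement bridging two boxes.)

`decompose()` selects the score-maximal set of non-overlapping placements by
weighted-interval dynamic programming over all candidates from
`scan_boxes()`. Ties are broken leftmost-start first, then higher score,
then shorter box, deterministically. Cys conservation holds on every input:
matched box Cys plus unassigned Cys always equals the sequence total. On
sequences up to 80 residues the DP total is tested against exhaustive subset
enumeration.

Coordinates are 1-based inclusive on the protein (the convention in which
biologists read domain diagrams); `to_half_open()` converts to 0-based
half-open for interop. Box termini are anchored on cysteines: the box starts
at its first mandatory Cys and ends at the last Cys, extended by one residue
when the closing Pro is present. Leading residues of the consensus region
are deliberately unscored, since whether termini belong to the repeat is
ambiguous in the source alignments.

# Gene-model reconstruction

`spliced_align()` reconstructs exon/intron structure by exact-seed anchoring
(default k = 12), collinear chaining, and mismatch-tolerant extension;
genomic gaps between consecutive exon blocks become introns. Internally all
coordinates are 0-based half-open; GFF3 export is 1-based inclusive -- the
conversion is stated explicitly to prevent off-by-one drift. Both strands
are searched and the better-scoring one is returned; aligning the
reverse-complemented scaffold yields the mirrored model on the opposite
strand (a tested invariant).

Intron boundaries are often ambiguous when the bases at the junction repeat;
the boundary is slid left-to-right to the *first* placement whose intron
starts `GT` and ends `AG` (canonical donor/acceptor). With enforcement on, a
gap with no GT..AG placement raises a `non-canonical splice` error naming
the gap; with enforcement off the leftmost minimal-mismatch split is used.
The synthetic generator re-draws intron interiors until each planted
boundary admits a unique GT/AG placement, mirroring the "unambiguous
exon/intron limits" situation the method targets; on real scaffolds a
genuinely ambiguous junction would be resolved to the leftmost canonical
placement.

Defaults: `max_mismatch_rate` 0.02 (comfortably above the ~1% strain
polymorphism typical of cDNA-versus-reference comparisons), intron length
40--5000 bp, minimum seed coverage 0.5. N bases never seed but are
mismatch-neutral in extension.

`check_coding()` verifies the ORF arithmetic: first codon ATG, final codon a
stop, coding length $3 \times (\mathrm{aa} + 1)$ with the initiator Met
counted among the aa. The failure diagnostics (no in-frame ATG, no stop) are
exactly the symptoms that betray a 5'-truncated gene annotation.

`scan_promoter()` matches IUPAC-degenerate motifs on both strands of the
upstream region. Offsets use the convention A of ATG = +1 with no position
0, so a motif whose 5'-most base lies n bases before the start codon has
offset $-n$. The default motifs are the canonical TATA box `TATAWAW` and the
standard metal-response-element core `TGCRCNC`; neither consensus is
universal, so both are overridable and reproduction of particular published
offsets is consensus-dependent.

# Metal stoichiometry from deconvoluted masses

Native-MS neutral-mass bookkeeping: each bound metal ion displaces as many
protons as its charge, so the holo mass is

$$ M_\mathrm{holo} = M_\mathrm{apo} + \sum_i n_i\,(m_i - z_i \times 1.00794), $$

giving increments of 63.364 Da per Zn(II), 110.395 per Cd(II) and 62.538 per
Cu(I); sulfide (S$^{2-}$) is an opt-in ligand adding 32.065 Da with no
proton displacement. `assign_peaks()` enumerates stoichiometries within
bounds exhaustively (species counts here stay below ~50, so brute force is
exact and fast) and keeps candidates within a relative tolerance of the peak
-- default 0.1%, the stated accuracy class of deconvoluted ESI-TOF masses.
The default cap on total metals is $\lceil 5/7 \times \mathrm{Cys} \rceil +
10$, the per-box Cu capacity bound plus slack.

Because the Zn and Cu increments differ by only 0.826 Da per ion, Zn- and
Cu-routes for the same total loading are indistinguishable at this tolerance
for the protein masses involved. When the best Zn-only and best Cu-only
candidates fall within tolerance of each other, the assignment is flagged
and reported as the composite `M<n>`. Peaks are assumed already deconvoluted
to neutral masses; charge-state processing of raw m/z is out of scope.

`metal_per_protein()` implements sulfur-based protein quantitation:
$[\mathrm{protein}] = [\mathrm{S}] / N_\mathrm{S}$ with $N_\mathrm{S}$ the
Cys + Met count of the construct (supplied by the caller -- the Met count is
construct-specific), then metal-to-protein ratios per element.

# Cu(I) capacity and the loading series

The capacity model is additive per box: a 7-Cys box hosts a Cu$_5$ cluster
and a 6-Cys box a Cu$_4$ cluster, consistent with the [Cu$_4$S$_6$] and
[Cu$_5$S$_7$] cores of classical Cu(I)-thiolate model chemistry. Cys outside
any box contribute between 0 and 1 extra Cu(I) each -- one-per-Cys is the
loosest bound consistent with Cu:S $\le$ 1 in those cores -- so a 6x7-Cys +
2x6-Cys + 3-Cys architecture predicts a base capacity of 38 and a maximum of
41. `capacity_consistency()` treats one Cu beyond the maximum as still
compatible (a loosely bound ion).

`loading_series()` reproduces the stepwise-titration pattern of predominant
species: doublets $(4k, 4k+1)$ for $k = 1..3$, then +5 per step --
(4,5), (8,9), (12,13), (17,18), (22,23), (27,28), (32,33), ... The series is
modelled as architecture-independent; the interpretation (4 matching a
6-Cys box filling, 5 a 7-Cys box filling) is carried in the rule text only.
Published observations list a lone Cu$_{33}$ species after (27,28); the
generator follows the +5 rule and emits the full doublet (32,33), leaving
the lone-species reading to the analyst.

# Growth-assay normalization

`normalize_growth()` converts endpoint OD600 readings to percent of the
zero-Cu control per strain: $100 \times \overline{OD}_c / \overline{OD}_0$.
The percent SD propagates the replicate spread of the treated condition
against the control mean -- the convention used for error bars in
endpoint-OD tolerance plots -- rather than a ratio-distribution correction.
Concentration units are carried through as entered, never converted.

# The synthetic generators, and what passing tests show

* `make_protein()` instantiates boxes from the consensus with inter-Cys X
  residues drawn from {G,A,S,T,K,Q,E,P} weighted toward Gly/Ala; 6-Cys
  boxes drop one mandatory Cys at a seeded position; linkers are Cys-free
  with length 3--8 (the observed spacers are short, around 4). The
  N-terminal segment spaces its prefix Cys four residues apart so they
  cannot be absorbed into a box match under the $\pm 2$ tolerance. Box
  order (6-Cys boxes before 7-Cys boxes) is an arbitrary fixed choice.
* `make_gene()` reverse-translates with seeded-uniform synonymous codons
  (no species codon-usage table is claimed), prepends an ATG-free 5' UTR
  (default 69 bp), inserts GT..AG introns of 48--204 bp between coding
  pieces of 63--105 bp, embeds the gene in GC-50% random flanks, and
  plants promoter motifs at requested offsets (defaults: TATA at -38, MRE
  at -1457), propagating UTR edits into the transcript.
* `make_peaklist()` perturbs theoretical holo masses with Gaussian relative
  error (default 0.02%, below the 0.1% assignment tolerance).
* `make_growth()` scales a saturating control OD (default 2.0) by a Hill
  inhibition factor (default IC50 10 uM, Hill 2) with Gaussian noise
  (SD 0.05), in triplicate over the dose ladder 0--30 uM.

These generators emulate the *structure* the analyses assume -- clean
modular repeats, substitution-only cDNA/genome divergence, single-locus
scaffolds, well-separated single-metal species, endpoint growth. They do not
emulate low-complexity genomic repeats, indels, UTR introns, overlapping
isobaric species mixtures, adduct peaks, or plate effects. Passing the
recovery suite therefore demonstrates correctness of the algorithms under
their stated assumptions, not robustness to every artifact of real data.

# Numerical choices and problem sizes

Deterministic tie-breaks are documented where they matter: DP segmentation
(leftmost start, then higher score, then shorter box), intron placement
(first GT/AG left-to-right), candidate ranking (smaller |mass error|, then
fewer metals). All generators take explicit seeds and restore the caller's
RNG state.

The test suite exercises 200 seeded architecture round trips, 100 seeded
spliced alignments (1--5 introns, proteins sized so coding pieces fit the
exon-length range), 1000 noisy peaks, and brute-force cross-checks on
sequences up to 80 residues -- sizes chosen to give the property checks
real coverage while keeping a full run in tens of seconds.

# Known limitations

* The spliced aligner assumes substitutions only (no indels) and one locus
  per scaffold run; it is a reconstruction tool for a known transcript, not
  an ab initio gene finder.
* Box scoring is a fixed-weight scheme, not a trained profile HMM; it is
  designed for the 7-Cys family and close relatives, not general repeat
  discovery.
* Validation against the published full-length MT gene/protein records
  requires downloading those database records (see
  `?tmmt_accession_files`); the package ships only sequences short enough
  to be transcribed from a printed table.
* Capacity prediction is stoichiometric bookkeeping, not thermodynamics:
  it predicts favored loadings, not affinities or kinetics.
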