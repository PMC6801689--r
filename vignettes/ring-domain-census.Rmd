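---
title: "Grammar-based RING domain discovery and the gene-family census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grammar-based RING domain discovery and the gene-family census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A RING (Really Interesting New Gene) domain is a compact zinc-binding
fold of roughly 40–60 residues in which eight conserved cysteine or
histidine positions — the metal-ligands ml1..ml8 — chelate two zinc ions
in a cross-brace arrangement: ligand pairs 1&3 bind one ion, pairs 2&4
the other. RING domains confer E3 ubiquitin-ligase activity, so a
genome-wide census of RING genes is effectively a census of a plant's
substrate-recruiting ubiquitination machinery.

`ringcensus` models a RING type as a *variable-gap consensus grammar*:
eight allowed-residue sets (one per metal-ligand) plus seven allowed-gap
sets (the number of residues strictly between consecutive ligands). The
seven built-in grammars (`builtin_specs()`) cover the types observed in
tomato: RING-H2, RING-HCa, RING-HCb, RING-v, RING-C2, RING-S/T and
RING-G. They are distinguished chiefly by the (ml4, ml5) residue pair —
(H,H) for H2, (H,C) for HC, (C,H) for v, (C,C) for C2, (H,G) for G — by
the ml7–ml8 spacing for HCa (2) versus HCb (3–4), and by the mandatory
serine of RING-S/T. Every grammar fixes exactly two residues between
ml1–ml2 and between ml5–ml6; the ml2–ml3 and ml6–ml7 loops are the
variable ones (up to 33 and 64 residues). These choices make the seven
grammars *pairwise exclusive*: no single octet of residues and gaps can
satisfy two of them, which the test suite asserts by exhaustive
enumeration of all 19,523 allowed gap combinations.

Two readings of the RING-S/T row are possible: the consensus table
prints C/S at ml2 and S at ml6, while the accompanying description says
the type carries a serine "at ml2 or ml6". We honour both: ml2 and ml6
each admit {C, S}, and at least one of the two must be serine.
Similarly, the RING-v ml4–ml5 gap set is taken from the table
({4,5,6,7,9}), a superset of the range quoted in the prose (4–7).

## Scanning and overlap resolution

`enumerate_octets()` lists *every* position octet satisfying some
grammar — including overlapping alternatives — by depth-first search
pruned on residue membership and gap windows. This exhaustive
enumeration doubles as a brute-force reference: the test suite contains
an independently written flat-loop enumerator and checks equality on
1,000 cysteine-enriched random sequences.

`scan_protein()` reduces the candidate set to a maximal mutually
non-overlapping set with a deterministic greedy rule: repeatedly keep
the candidate with the leftmost ml1 (ties: smaller span ml8−ml1, then
registry order) and discard everything sharing a residue index with it.
The rule favours compact, early, canonical domains; the source
literature never states its own resolution rule, so determinism was the
deciding criterion. A protein may carry any number of domains; multiple
non-overlapping domains are reported in positional order.

### Incomplete domains

An *incomplete* domain is a candidate octet satisfying some grammar's
gap constraints and all but exactly one residue constraint (the
violated ligand is reported). A "lacking" ligand is modelled as a
residue substitution, never as a deleted position — gap constraints stay
strict. Candidates with two or more violations are suppressed by
default (`max_violations = 1`): an octet with two free positions matches
background sequence too promiscuously to be a meaningful call without
structural corroboration; the knob exposes the looser reading.

One subtlety is documented rather than hidden: when the knocked-out
ligand sits at the edge of the octet (ml1, ml2, ml7, ml8), the damaged
sequence often still satisfies the grammar in a *shifted frame* — for
example the true ml7 can serve as ml8, with a flank residue standing in
as the "violated" ml7 over a still-legal ml6–ml7 gap. Both frames are
legitimate single-violation candidates, and the greedy rule may select
the shifted one. Recovery tests therefore compare incomplete reports to
planted decoys by location (one report per decoy, overlapping the
planted octet); the violated index is asserted exactly only for interior
knockouts, where no aliasing is possible.

## Spacing and conservation statistics

`spacing_histogram()`, `modal_spacing()` and `spacing_fraction()` tally
inter-ligand spacings over any match set, with exact integer ratios and
ties broken toward the smaller gap for deterministic reporting. Two
spacings are analytic invariants of the grammar itself — every emitted
domain has exactly two residues at ml1–ml2 and ml5–ml6 — and the
acceptance suite checks that the scanner's output satisfies them at
100.0%.

`conservation_profile()` measures residue frequencies at signed offsets
(default −2..+4) around each metal-ligand. Because the loops vary from
6 to 64 residues, a global alignment frame is ill-defined; the profile
is instead anchored per-domain on the actual ligand indices, and an
offset cell is skipped for a domain whenever it would cross into an
adjacent ligand position. `information_content()` converts a frequency
vector into logo-ready bits, log2(20) − H(p).

## The genome census

`build_census()` aggregates matches and gene models into per-protein,
per-type and per-chromosome tables with conservation identities that
hold on every input (type totals sum to the complete-domain count,
chromosome totals sum to the grand total, single- plus multi-domain
proteins sum to the RING-protein count). Genes on pseudo-chromosome "0"
or without a placement are tallied but flagged excluded from downstream
analysis. `count_intronless()` counts single-exon RING genes.

`protein_stats()` reports length, molecular weight (average residue
masses plus one water; non-standard letters contribute the alphabet
mean and are flagged) and the isoelectric point, computed as the unique
zero of the Henderson–Hasselbalch net-charge function by bisection over
pH 0–14 to |charge| < 1e-4. The pKa constants are the EMBOSS set,
pinned in one table; other published sets shift pI by a few tenths of a
unit, which matters only if comparing against tools using different
constants.

`find_tandem_clusters()` is a deliberate, parameterised simplification
of collinearity tools (MCScanX is out of scope): RING genes on one
chromosome are grouped when consecutive members are separated by at most
one intervening non-RING gene *or* at most 100 kb, and every pair in the
group has global protein identity ≥ 0.7 (Needleman–Wunsch, match +1,
mismatch 0, gap −1). Within a proximity run, clusters grow greedily:
the next gene joins only if it clears the identity threshold against
all current members. Reproducing any particular published event count
is explicitly not a goal of this rule.

## Ka/Ks by Nei–Gojobori (1986)

The duplicate-pair selection analysis uses NG86 with Jukes–Cantor
correction, chosen over richer maximum-likelihood models because it is
closed-form and checkable by exhaustive enumeration — and the downstream
claim (purifying versus positive selection) only needs the Ka/Ks < 1
versus > 1 distinction. Per codon, each position contributes
(synonymous single-nucleotide changes)/3 to the synonymous site count S
(changes to stop codons count as nonsynonymous); site counts are
averaged over the two sequences. Differences in codons differing at
2–3 positions are averaged over all orderings of the changes, excluding
pathways through stop codons (if every pathway is blocked, all pathways
are used — a documented, rarely reached fallback). Proportions are
corrected by K = −(3/4)·ln(1 − 4p/3); a proportion at or beyond 3/4
yields a saturation flag and an NA rate instead of a failure. The
Ka/Ks ratio is defined only when Ks > 0. Sequences must be pre-aligned
and stop-free: the implementation rejects *any* stop codon, including a
terminal one, so callers strip terminal stops — this keeps the
S + N = length identity exact.

## The synthetic world

`generate_proteome()` emulates the population a plant RING census runs
on, and its defaults *are* the stated conditions: 500 proteins, 300
planted domains (five proteins carry two), 50 single-knockout decoys,
protein lengths log-uniform over 60–1888 residues (the printed range,
without asserting its interior shape), 12 chromosomes, and an
intronless-gene fraction of 98/469. Domain types are drawn with weights
248/142/21/40/20/2/1 — the observed tomato type counts. Because a
weighted draw of 300 would omit the singleton RING-G type about half the
time, `ensure_all_types` (default on) plants one domain of each type
before sampling the remainder; planted-recovery tests require all seven
grammars exercised. The two-domain protein count defaults to
min(5, n_domains/2): five at the stated scale, feasibility-capped for
tiny test configurations.

The default background alphabet excludes C, H, S and G, so a planted
domain is provably the unique grammar-satisfying octet in its
neighbourhood and recovery tests can demand exact coordinates.
`hostile_background = TRUE` re-admits those letters at background
frequency to stress overlap resolution; hostile output is checked only
against the brute-force oracle, never against planted truth. Every
planted domain keeps at least five background residues on each side.

What a green recovery test does establish: the scanner finds every
grammar-satisfying octet and resolves overlaps exactly as documented.
What it does not establish: performance on real proteomes, where
cysteine-rich regions (other zinc fingers, disulfide-bonded domains)
produce near-miss octets the clean generator never creates, and where
the published census additionally used homology searches and manual
curation that this package deliberately replaces with the grammar alone.

`mutate_cds()` plants exact counts of verified synonymous and
nonsynonymous single-nucleotide changes, never two in one codon — so
NG86 pathway counting is exact and the realised Sd/Nd equal the planted
counts, making parameter-recovery tests sharp rather than statistical.

## Numerical and formatting choices

Percentages print with one decimal (`format_percent()`); modal ties
break toward the smaller gap; report tables have fixed column and row
orders so reruns are byte-identical; coordinates in every file and
report are 1-based inclusive (GFF3 convention), which is also the
internal convention. The RNG kind is pinned in `generate_proteome()` so
a (config, seed) pair is byte-deterministic across sessions.

## Known limitations

- The grammar arm is the only identification arm: no homology search,
  no HMM profiles, no external domain-database confirmation.
- Table-derived gap ranges describe domains *observed* in one proteome;
  scanning a different clade may need widened ranges via a custom
  profile file (`read_ring_specs()`).
- The tandem rule approximates, but does not reproduce, collinearity-
  based event detection; segmental/whole-genome duplication detection is
  out of scope.
- NG86 underestimates rates at high divergence relative to ML methods;
  saturated pairs are flagged, not corrected.
- RING-D ships as a disabled stub only (`ring_d_spec()`).
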