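---
title: "Methods: standardized IG domain numbering, junction decomposition and repertoire statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized IG domain numbering, junction decomposition and repertoire statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igkit)
```

## The model: one position scheme for every IG domain

Immunoglobulin variable (V) and constant (C) domains share the
immunoglobulin fold: a sandwich of two beta sheets. The IMGT unique
numbering assigns every residue of such a domain a position from 1 to 128,
so that structurally equivalent residues carry the same number across
domains, chains and species. A V domain has nine strands (A, B, C, C', C'',
D, E, F, G) and three loops (BC, C'C'', FG), which in a rearranged V-DOMAIN
are the complementarity-determining regions CDR1 (27–38), CDR2 (56–65) and
CDR3 (105–117); the strands form the frameworks FR1–FR4. A C domain lacks
the C' and C'' strands (positions 32–33 and 46–76 do not exist there); a
transversal CD strand (sub-positions 45.1–45.9) replaces the C'C'' loop,
and short turns (15.1–15.3, 84.1–84.7/85.1–85.7, 96.1–96.2) absorb length
variation. Six anchor positions flank the loops — 26/39, 55/66 (V) or
45/77 (C), 104/118 — and five hallmark residues characterize the fold:
1st-CYS 23, CONSERVED-TRP 41, a hydrophobic residue at 89, 2nd-CYS 104 and,
in V-DOMAINs, J-PHE or J-TRP 118 opening the F/W-G-X-G motif.

`assign_numbering()` implements this scheme: the caller supplies the
occupied length of each region (V) or segment (C), and the function binds
residues to positions under the gap rules (A-strand gap at 10, C'' gap at
73, D-strand gaps at 81/82 (V) or 82 (C), loop gaps from the apex, CDR3
insertions between 111 and 112, ascending turn sub-positions). The numbered
domain is the package's central data structure; delimitation, hallmark
verification, identity, Collier de Perles layout and allotype calling all
consume it.

### Variable-length loops

Loops shrink and grow from their apex. For the FG loop (CDR3) the two
orders are explicit: below 13 residues, gaps are created in the order 111,
112, 110, 113, 109, 114, ...; above 13, sub-positions are inserted in the
order 112.1, 111.1, 112.2, 111.2, ... Within the insertion block the total
order is 111 < 111.1 < ... < 112.2 < 112.1 < 112, so a block reads up one
flank and down the other, as at the top of the loop in the published
tables.

```{r}
cdr3_position_sequence(11)
cdr3_position_sequence(15)
```

For the BC and C'C'' loops the canonical gap order is maintained by the
same apex-alternation scheme with apex pairs 32|33 and 60|61 and removal
order 33, 32, 34, 31, ... This order is our reading of the scheme (the
reference chart enumerates it only for the FG loop); it is data, isolated
behind `loop_position_sequence()`, and can be corrected without touching
any caller.

Two further ordering decisions were genuinely open and are therefore made
explicit here. First, the DE turn of C domains (84.1–84.7, 85.1–85.7) is
filled from both ends — 84.1..84.k then 85.m..85.1 — mirroring the
111/112 block; the published tables give only the ranges. Second, FR1
sequences shorter than 25 residues (beyond the documented gap at 10) drop
N-terminal positions, reflecting leader-truncated sequences; this case is
outside the documented rules and is flagged as a convention.

### Numbering by alignment

`infer_boundaries()` transfers numbering from a numbered reference to a
query by global alignment (identity scoring +5/−4, affine gaps 12/2,
via `Biostrings::pairwiseAlignment`). The alignment is a vehicle, not a
result: only the transferred region lengths and identity percentages are
reported. The scoring was chosen once as a conventional identity scheme;
the output the method is specified by (a gapped alignment and per-region
identities) does not depend delicately on it for genuine domain sequences.
If no cysteine aligns to position 23 or 104 the result is refused as
low-confidence rather than returned. Identity percentages divide by the
positions occupied in *both* sequences, so gaps never count against
identity; values are reported to one decimal.

## Amino-acid classes and change grading

Amino-acid changes are graded on three axes — hydropathy (3 classes),
side-chain volume (5 classes), chemical characteristics (11 classes) — and
the per-axis agreement pattern maps to four change types: `+++` very
similar, one disagreement similar, two disagreements dissimilar, `---`
very dissimilar. The hydrophobic hydropathy class is pinned to
{I, V, L, F, C, M, A} (positive hydropathy index; tryptophan is neutral
and highlighted separately in displays). The remaining memberships are
packaged as an editable fixture (`extdata/aa_classes.tsv`): volume uses
the standard five bands (very small A/G/S through very large F/W/Y), and
the 11 chemical classes are the package's own defensible partition
(aliphatic, glycine, proline, aromatic, thiol, thioether, hydroxyl, amide,
acidic, basic, histidine). Under this table the pattern `-++` (same volume
and chemistry, different hydropathy; e.g. F vs W) is reachable although
the canonical enumeration lists only seven patterns; it is graded
"similar" by the agreement count. Non-standard letters (X, B, Z, `*`) are
rejected rather than guessed so change statistics stay well defined.

## Junction decomposition

A V-(D)-J junction (codon 104 through codon 118) is decomposed into
3'V + P + N1 + P + D + P + N2 + P + 5'J against germline references. The
biological constraints are hard invariants: trimmed nucleotides and P
nucleotides are mutually exclusive at each coding end; a P segment is 1–3
nt and equal to the reverse complement of the intact coding end; the
concatenation of all segments reproduces the junction exactly.

The objective is parsimony in reverse: maximize the germline-matched
nucleotides `v_len + d_len + j_len`, breaking ties by total P length
(germline-derived explanations preferred over N), then longer D match,
then D gene order. The search enumerates maximal exact matches (runs)
between the junction and each D gene; for each run the optimal V and J
extents are determined analytically (the objective is separable in
`v_len` and `j_len` once a run is fixed), so the candidate set provably
contains the optimum without quadratic enumeration. The test suite
cross-checks this against an independent exhaustive oracle over all
`(v_len, j_len)` pairs on hundreds of simulated junctions. A D call
requires at least 5 matched nucleotides (configurable); below that the
junction is explained V-J-style with a single N region. D inversion and
multiple-D rearrangements are out of scope.

The decryption string puts germline lengths in parentheses, N lengths in
braces and signed end marks (trims negative, P positive, zeros omitted),
e.g. `(7){3}(5){2}-4(15)`; `parse_decryption()` recovers the lengths-only
form.

## Clonotypes and set comparison

A clonotype (AA) is keyed by the V and J calls, the CDR3 amino-acid
sequence and conserved anchors C104 and W/F118; records failing anchor
conservation are excluded with a reason, never dropped silently. Because
real annotations often carry several alleles ("or" calls), keying defaults
to the gene level with allele ambiguity retained as metadata; allele-level
keying is a switch. Within a clonotype (AA), nucleotide children are
grouped by CDR3 (nt); the three per-clonotype counts are members whose
CDR3 (nt) is seen once, members in multi-copy groups, and the total. The
representative member is chosen by highest V identity, then longest
sequence, then lexicographic id — a deterministic rule where the displays
we emulate show a representative without stating one.

Diversity tables count clonotypes, expression tables count sequences, per
V gene, J gene and CDR3 length. `compare_clonotype_sets()` tests each
category with a pooled two-proportion z test and an unpooled 95%
confidence interval on the difference — conventional choices, stated
because the source material names neither — and adjusts p-values with
seven procedures: Bonferroni, Holm, Sidak (single-step, closed form),
Hochberg, Hommel, Benjamini-Hochberg, Benjamini-Yekutieli (all but Sidak
via `stats::p.adjust`). Rows are classed by agreement count:
`non-significant`, `rawp` (raw only), `Only_BH` (exactly one adjusted
procedure — in practice BH, the most liberal), `Min_2p` (two to six) and
`All_p` (all seven). The class is monotone in the agreement count by
construction.

## Allotypes, Eu correspondence, engineered variants

Marker rules are conjunctions of residues at C-domain IMGT positions,
shipped as a row-per-residue fixture with per-row provenance tags: Km
alleles from the IGKC pair (45.1, 101); the lambda isotype markers
Mcg/Ke/Oz from positions 1, 3, 45, 100; G1m/nG1m from CH1 103/120 and CH3
12/14/101/110/115/116, with the allele map translating allotype
combinations into G1m allele labels (provisional, not-yet-sequenced
alleles flagged); G2m23 determined by CH2 M45.1 with CH1 T92 reported
only as corroborating linkage evidence; and the thirteen G3m allotypes as
independent conjunctions, with the haplotype-level G3m5* combination in
the allele map. A marker is reported only when every rule residue
matches; rule positions absent from the input are listed as unresolved,
and a residue set matching nothing yields an explicit no-call with the
mismatching positions. Isoallotypes are reported in their own field.

The Eu↔IMGT correspondence table contains every printed pair (hinge, CH2,
CH3) and is bijective per domain, so the round trip is the identity;
unmapped queries fail with the nearest mapped neighbours. Engineered
variants are named by exact change-set match against the catalogued
variants (changes as `domain:AAposition` tokens, relative to the *01
allele); unmatched sets get a deterministic `vNEW-<hash>` label (FNV-1a
over the canonical change string) plus the nearest catalogued variant by
overlap.

## Locus gene tables

The packaged gene tables carry one record per gene (subgroup, CDR lengths
for V genes, allele counts by functionality, CNV tags, cluster, gene
order) plus per-group totals. The V-gene tables list only subgroups with
at least one functional or ORF allele, so totals validation is restricted
to the groups whose detailed table is complete (IGHD, IGHC, IGKJ, IGKC,
IGLJ, IGLC); printed cluster totals (40 proximal / 36 distal IGKV genes)
are carried separately. Combinatorial diversity is the raw product of
functional gene counts — no junctional multiplier, which is why potential
repertoire figures quoted with junctional diversity included are not
reproducible from these tables alone and are not attempted. Haplotype
ranges ("38 to 46 functional") are stored as bounds, not collapsed to one
number.

## The simulator and what passing tests mean

`simulate_repertoire()` emulates the biology the analysis modules assume:
D-to-J then V-to-DJ joining (the 12/23 rule honoured structurally, i.e.
only those pairings are formed), geometric exonuclease trims, P
nucleotides only at untrimmed ends (1–3 nt, reverse complement of the
end), template-independent N regions with a configurable g bias, and
per-site Bernoulli somatic hypermutation with hotspot motifs
((a/t)a, t(a/t), (a/g)g(c/t)(a/t), (a/t)(a/g)c(c/t)) upweighted by a
multiplier and transitions favoured 2:1 over transversions — a modeling
choice, not a calibrated rate. Defaults (4 V / 5 D / 3 J toy genes, trim
mean 2 nt, N mean 4 nt, g bias 0.4, 50 clones of mean size 3) are one
realistic-scale choice for exercising the machinery; trim and N length
distributions are not quantified in the source material, so they are
config-exposed and arbitrary by construction. N2 is padded by 0–2 nt so
junctions stay in frame (productive rearrangements); the raw-join mode is
available for tests of the pure joining arithmetic.

Every record carries its full ground truth. A junction is flagged
*degenerate* when chance resemblance admits an alternative germline
explanation scoring at least as well as the planted one (accidental V/J
extensions, a competing or extendable D match, an ambiguous P
assignment). Exact truth recovery is asserted on non-degenerate records;
on degenerate ones only the defensible weaker property holds — the
decomposition never scores below the truth. Toy germline genes are short
and synthetic: hallmarks and the J motif are planted, codon usage is
fixed per amino acid, and there is no allelic series, no SHM-vs-allele
confusion, and no sequencing error. Passing tests therefore demonstrate
the correctness of the algorithms under the stated generative model, not
performance on real repertoire data with mutated junctions or ambiguous
germline assignment.

Problem sizes used by the checked-in test suite were chosen to exercise
the statistics at meaningful scale while staying desk-sized: ~500
oracle-verified junctions, a ~1,000-record repertoire for truth recovery
and partition checks, ~10^5 sites for the hotspot-enrichment interval and
a few thousand N nucleotides for the binomial g-bias check.

## Numerical and degenerate-input conventions

Position comparison is structural (base, then sub under the mirror rules),
never lexical or floating-point string parsing. Identity and proportion
outputs are rounded only at the reporting edge (one decimal for identity,
two for percentages in tabular output). Empty inputs are values, not
errors, where a value makes sense (zero records yield zero clonotypes; an
empty change set names the reference allele); malformed structure is an
error with the offending offset or positions named. All randomness flows
from a single integer seed; the same seed reproduces simulator output
byte for byte, and SVG rendering is deterministic by stable element
ordering.

## Known limitations

* CDR1/CDR2 gap order and the DE-turn fill are provisional readings of
  the reference chart (documented above, isolated as data).
* No nucleotide-level germline gene identification: records arrive
  annotated or from the simulator.
* No SHM-tolerant fuzzy matching inside the junction; one D segment, no
  inversion.
* The ">50% of analysed sequences" hydrophobicity shading of published
  domain plots is population-derived; the Collier layout approximates it
  with the fixed hydrophobic set plus tryptophan.
* Hydrogen bonds in two-layer plots are accepted as input, never
  computed from structure.
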