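---
title: "Design rules and numerical choices in knockinDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design rules and numerical choices in knockinDesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

knockinDesign automates the three design problems of an HDR-based
insertional knock-in experiment: choosing a guide RNA, constructing the
HDR donor, and designing genotyping primers. This vignette documents the
models the package implements, the tunable parameters with their defaults
and units, the algorithmic and numerical choices made where the problem is
genuinely open, and what the synthetic-fixture test bed does and does not
demonstrate.

## Coordinates and sequence conventions

All user-facing and internal coordinates are 1-based inclusive on the
genome + strand, matching Ensembl GFF3 and R's own string/IRanges
conventions (a deliberate choice: R has no native 0-based containers, and
mixing conventions is the classic source of off-by-one defects). Two
left-base conventions localize events *between* bases: an insertion site
`p` means the payload is placed between `p` and `p+1`, and a cut site `p`
means the nuclease cuts between `p` and `p+1`. The cut coordinate for
SpCas9/SpCas9-VQR is the canonical blunt cut between spacer positions 17
and 18 (3 bp 5′ of the PAM); enAsCas12a's staggered cut is collapsed to a
single nominal coordinate after spacer position 18 on the protospacer
strand — only a single coordinate is needed, because the only consumer is
the cut-to-insert distance. Spacer length is 20 nt for all three enzymes,
including enAsCas12a, so one mismatch/weight table geometry serves all.

## Guide scoring

Candidate protospacers are enumerated on both strands within ±50 bp of the
insertion site; the Gaussian distance weight `exp(-d²/110)` is below 1e-9
beyond 50 bp, so a wider window cannot change a ranking. Three weights
multiply into the composite score:

* **Specificity.** All genomic sites within 4 mismatches of the spacer and
  flanked by a permissive off-target PAM (SpCas9: NGG/NGA/NAG; VQR:
  NGA/NGG; Cas12a: TTTN) are scored with the published 20-position MIT/Hsu
  single-hit formula (vendored weight table in
  `inst/extdata/mit_position_weights.csv`) and aggregated as
  `100·100/(100 + Σ hits)`. The raw aggregation lies in [0, 1]; it is
  scaled ×100 so that the weighting thresholds (0 below 45, 1 above 65,
  linear between) act on the same 0–100 scale on which those thresholds
  are defined. The search is an exhaustive vectorised shift-and-compare
  scan over every FASTA record — at the package's intended scale
  (fixtures and small custom references) this needs no external aligner,
  and the test suite pins it against a naive substring oracle.
* **Distance.** `exp(-d²/110)` of the absolute cut-to-insert distance in
  bp (≈0.27 at 12 bp).
* **Position** (optional, on by default). A cut inside a 5′ UTR is
  weighted 0.4; a cut within 2 bp (exon side) or 6 bp (intron side) of a
  splice junction is weighted 0.1, ramping linearly back to 1 over the
  next 10 bp; penalties combine by minimum. The *shape* of this penalty
  (punish 5′ UTR and junction-proximal cuts, spare CDS/3′ UTR/deep
  introns) is the established rule; the numeric values are this package's
  calibration, chosen to penalize without hard-excluding, and are exposed
  as arguments of `position_weight()`. 3′ UTR cuts are deliberately not
  penalized; a config override can add it.

Ties in the composite break deterministically: distance ascending, then
specificity descending, then leftmost start, then strand.

## CFD model and re-cut recoding

Re-cut potential is the product of per-position mismatch factors and a PAM
factor (the CFD framework). The SpCas9 PAM-factor table uses the widely
reproduced published values (GG = 1, AG = 0.259, CG = 0.107, …). The
per-position mismatch tables shipped here are **synthetic model tables**
(filenames say so): factors decline from PAM-distal (~0.9) to PAM-proximal
(~0.15) positions with wobble-pair mismatches (rG:dT, rT:dG) most
tolerated, matching the qualitative structure of the measured tables
without claiming their numbers. Every algorithmic property the package
relies on — perfect match scores 1, factors in [0, 1], proximal mismatches
more disruptive, a destroyed PAM ≤ 0.03 — holds by construction and is
asserted in tests. SpCas9-VQR reuses the SpCas9 mismatch geometry with its
own (synthetic) NGA-canonical PAM table; enAsCas12a has a 4-nt 5′ PAM
table with TTTV = 1 and TTTT = 0.15.

The re-cut planner seeks the fewest single-base mutations bringing the
donor-wide maximal CFD (every window, both strands, payload and junctions
included) below the threshold (default 0.03):

1. scan the donor; if the maximum is already below threshold (the payload
   itself often splits the protospacer) the plan is empty;
2. enumerate every allowed single-base mutation inside the worst window —
   in CDS only substitutions that keep the codon synonymous and non-rare,
   elsewhere the complement transversion (A↔T, G↔C, chosen to preserve GC
   content and purine/pyrimidine alternation); protected positions
   (splice windows, payload) are excluded;
3. apply the candidate minimizing the donor-wide maximum — preferring PAM
   window candidates whenever one improves the score (PAM-first default) —
   and repeat.

Because step 3 evaluates every single mutation by its *global* effect,
one-mutation plans are provably minimal; for plans of three or more, an
exhaustive search over candidate pairs restores minimality where the
greedy path overshot. If the threshold is unreachable under the
constraints (all of the window protected, or no silent option — the
genome-scale analogue of the small percentage of undesignable loci), the
best-effort plan is returned flagged `residual above threshold`, never
silently accepted. The rare-codon rule excludes synonyms with usage below
7×10⁻³ or below half the median usage of the synonym group (vendored human
codon-usage fractions); stop codons form their own synonym group, and in
practice never recode.

Splice protection masks 3 exonic and 6 intronic bases around every
junction — wide enough to cover the invariant GT/AG dinucleotides and
their immediate context — and is configurable; the exact width used by any
particular published pipeline is not part of the contract here.

**Ordering.** Full recoding applies repair-track mutations *first* and
re-cut planning *second*. A repair-track substitution can coincidentally
restore similarity to the guide (a transversion may turn a mismatch back
into a match), so the re-cut planner must have the last word; with this
ordering the final donor-wide CFD re-scan always equals the plan's
residual, which the test suite audits on every randomized design.

Repair-track recoding covers the region between the cut and the payload
junction: codons fully inside it receive the maximally divergent non-rare
synonym (ties broken toward the highest-usage codon — deterministic and
conservative); non-coding stretches receive complement transversions at no
more than one of every three bases, implemented strictly as ≥ 2 unmutated
bases between consecutive mutations scanning from the cut toward the
payload. The payload itself is user cargo and is never mutated.

## Donor formats

dsDNA donors default to 500/500 bp arms. Synthesis screening flags exactly
three families: homopolymer runs (≥ 10 A/T, ≥ 6 G/C — boundaries are
exact: 9 A and 5 G never flag), extreme global GC (> 65% or < 25%,
boundaries exclusive), and window skew (> 52% GC difference between any
two 50-bp windows, stride 1; "any given 50 bp stretches" read literally).
Optional trimming shortens each arm from the distal end inward, one
offending feature (homopolymer or user motif) at a time — the cut lands
1 nt past the feature's payload-proximal edge, then the arm is re-screened
— halting when the arm is clean or the minimum length (default 100 bp)
would be crossed, whichever comes first; flags that survive are always
reported. GC flags are report-only and never drive trimming: shortening an
arm changes its GC content unpredictably, and a homopolymer is the one
feature removal provably eliminates.

ssODN donors are capped (default 200 nt) by symmetric distal trimming that
never touches the payload and never drops the cut site out of the donor
(the cut-to-insert region must stay templated). Strand polarity in `auto`
mode follows the strand-annealing polarity rule: cut 5′ of the insert on
the + strand → minus-strand donor; cut 3′ → plus strand; cut == insert →
the guide's non-target strand (common practice; configurable). The rule is
centralized in `select_ssodn_strand()` and covered by a mirror-antisymmetry
property test, so if a user's empirical convention differs it is a one-line
change. `transcribed` means the transcription template strand (the
complement of the mRNA-sense strand); both transcript modes require
transcript context and error without it. dsDNA sequences are always
reported on the genome + strand; ssODNs on their chosen strand with the
strand recorded.

Recoded stretches do not count as homology: the effective arm length runs
from the arm's distal end to the most payload-proximal recoded base.

## Genotyping primers

Short-read mode extracts 430 bp centred on the edit (4000 bp for
long-read), enumerates 18–25-mers outside a 100 bp (1000 bp) exclusion
zone on each side, and filters on Tm 57–63 °C (optimum 60), GC 20–80%,
ΔTm ≤ 3 °C, product size 250–350 bp (3300–3700 bp), and
complementarity-run caps (≤ 4 nt of 3′-anchored and ≤ 8 nt of anywhere
complementarity) standing in for thermodynamic dimer alignment scores.
Melting temperatures come from the package's unified nearest-neighbour
implementation (SantaLucia parameters, entropy salt correction, von Ahsen
divalent conversion; 50 nM primer, 50 mM monovalent, 1.5 mM Mg²⁺, 0.6 mM
dNTPs). A frozen reference panel computed once with an independent
nearest-neighbour implementation pins the engine to within 0.5 °C.

Candidates per side are capped to the best 60 by penalty
(|Tm−60| + 0.2·|len−20|) before pairing; the cap is an argument (`beam`)
and the relaxation-superset property is verified uncapped. Off-target
vetting finds all annealing sites with ≤ 3 mismatches (`fast`; 4 in
`sensitive`) and an exactly matching 3′-terminal base, then rejects a pair
if any convergent opposite-strand site pair — over fwd+rev, fwd+fwd and
rev+rev — predicts a product ≤ 6 kb, the intended amplicon excluded by
coordinate identity (not by size, so a same-size off-target product still
rejects). Up to three passing pairs are returned, ranked by penalty, with
an advisory annealing temperature of min(pair Tm) − 1 °C.

The six-attempt relaxation ladder reads the overlapping schedule
cumulatively: ΔTm grows 1 °C per attempt over attempts 1–3 (3→6 °C) and
the product ceiling grows one step (80 bp short / 300 bp long) at attempts
2, 4 and 6, with the locus re-extracted 40/150 bp wider per step. Each
attempt's candidate set is a superset of the previous one's, so verdicts
are cached across attempts. Exhaustion of all six attempts is a reported
failure — the characteristic case being a locus duplicated verbatim on
another chromosome, where every conceivable pair amplifies the duplicate.

## Synthetic fixtures

`generate_fixture()` builds seeded mini-genomes: uniform-ACGT background
at a configurable GC fraction with homopolymer runs ≥ 5 nt squashed (so
planted homopolymers are the only flaggable runs), then genes (valid
ATG…stop CDS, GT…AG introns, optional explicit UTR features — omitting
them exercises the exon-minus-CDS derivation), then planted features
(protospacer copies with chosen mismatch counts and PAMs, homopolymers, GC
blocks, duplications, arbitrary sequences), with any footprint overlap a
hard error. The manifest of planted coordinates is the ground truth for
every search test. Identical seed and spec give byte-identical FASTA,
GFF3 and manifest.

What passing on fixtures does *not* show: real genomes have repeat
families, biased composition and alternative transcripts; specificity
scores on a 20 kb fixture are near-saturated (few off-targets exist to
find), and the genome-wide percentages reported for real references
(recoding success rates, homopolymer prevalence, primer success rates) are
properties of those genomes, not of this code, and are out of scope here.

## Problem sizes and runtime

The test suite uses 12–20 kb two-chromosome fixtures for module tests, a
90 kb fixture for the search-oracle comparisons, a 50-design randomized
panel for recoding (seed fixed in the test), and a 1 kb cross-chromosome
duplication for the primer failure mode; the whole suite completes in a
few minutes on one CPU. These sizes were chosen as the smallest at which
each property is non-trivially exercised (e.g. the duplication must exceed
the maximally extended primer locus of 670 bp, otherwise late relaxation
attempts can legitimately escape it).

## Known limitations

* CFD mismatch tables are synthetic models (see above); absolute CFD
  values are comparable within this package, not to published CFD scores.
  Swapping in measured tables is a drop-in CSV replacement.
* On-target activity (cutting efficiency) is deliberately not scored.
* Primer dimer screening uses complementarity-run caps, not full
  thermodynamic alignment; borderline dimers may pass that Primer3 would
  reject.
* One codon-usage table (human) is vendored; other organisms can be
  supplied as CSVs with the same schema.
* N/C-terminal insertion assumes the annotated CDS has intact start/stop
  codons; incomplete CDS models are flagged, not repaired.
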