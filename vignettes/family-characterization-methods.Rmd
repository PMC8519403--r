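---
title: "Methods: gene-family characterization with famchar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterization with famchar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famchar)
```

famchar re-implements, as tested reusable code, the analytic core of a
genome-wide survey of a basic helix-loop-helix (bHLH) transcription-factor
family: where the domain sits in each protein, how conserved each domain
position is, whether the basic region licenses DNA binding and which DNA
element (E-box `CANNTG`, or its G-box variant `CACGTG`) it can contact, the
ProtParam-style physicochemical panel, tandem duplication with Ka/Ks and
molecular-clock dating, and low-temperature expression screening. This
vignette records the models, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical conventions.

## Domain location: a PSSM instead of a profile HMM

Family surveys typically locate the domain with a profile-HMM search
against a curated domain model at an E-value cutoff. famchar deliberately
replaces that with a **gapless position-specific scoring matrix** over a
fixed 61-residue core:

$$\mathrm{score}(p, a) = \log_2\frac{c(p,a) + \tau\, b(a)}{(n + \tau)\, b(a)}$$

with per-position counts $c$, pseudocount mass $\tau$ (default 1), and
background $b$ (default uniform, 1/20). A window score is the sum of its
per-position scores, which makes the scanner exactly checkable against a
per-letter accumulation oracle. Everything downstream needs only a located,
frame-mapped domain, and a PSSM needs no external profile download. Users
with real HMMER output can inject hits with `read_domain_hits()`.

**Threshold.** The default `DEFAULT_MIN_BIT_SCORE = 25` bits was calibrated
once by Monte-Carlo (internal seed 20210762): across 200 random background
proteins of length 500 the maximum window score was about −98 bits, while
planted near-template domains score above +75 bits. The threshold sits in
the middle of a >170-bit gap, so localization is insensitive to its exact
value. Raising it can only remove hits (a tested monotonicity property).

**One domain per protein.** Whether multi-hit proteins should count once or
several times is a judgment call the underlying survey never states;
famchar defaults to the best (highest-scoring, leftmost-on-tie) hit, with
`best_only = FALSE` to keep all non-overlapping hits.

## The 61-position reference frame

The domain is partitioned into basic 1–17, helix1 18–31, loop 32–45, helix2
46–61. No published coordinate table fixes these boundaries; they were
chosen so that every canonically conserved residue lands in its named
region — His-8 … Arg-16 in the basic region, Ile-19 … Pro-31 in helix 1,
Lys-44/Asp-45 in the loop, Ala-48 … Leu-61 in helix 2 — and they are
overridable in `reference_frame()`.

Because the loop is the variable-length part of the domain ("two α-helices
connected by a loop of variable length"), hits shorter or longer than 61
(within a ±6 slack) are reconciled **inside the loop only**: gaps for short
hits, trims for long ones, placed by exhaustively scoring every
order-preserving placement against the anchor PSSM's loop columns and
keeping the best (first in lexicographic order on ties). Confining
indels to the loop keeps the classifier's basic-region positions stable;
exhaustive placement keeps the fit oracle-checkable. This is a
*replacement* for whatever multiple-alignment trimming a real survey used,
not a reproduction of it.

Consensus ratios are modal-residue fractions over non-gap entries, ties
broken alphabetically for determinism. Conservation calls use strict
inequalities — ratio > 0.5 "conserved", > 0.9 "highly conserved" — so a
ratio of exactly 0.5 is *not* conserved, matching the ">50%" convention.

## DNA-binding residue rules

`classify_binding()` applies a fixed decision tree to the framed domain:

1. count basic-region residues in {Arg, Lys, His} (gaps count 0); fewer
   than 6 ⇒ **non-DNA-binding**. The literature says both "less than six"
   and "greater than five", which agree on the threshold ≥ 6. The set
   {R, K, H} is the standard "basic residues" reading and is configurable,
   since the source never enumerates it.
2. Glu-12 and Arg-15 both present, else **non-E-box**.
3. His or Lys at 8, Glu-12, Arg-16 all present ⇒ **G-box**, else
   **non-G-box E-box**.

Positions are in the package frame; the equivalent Arabidopsis-frame
numbering (9/13/16/17) is the same residues offset by one and is *not*
separately encoded — renumber the `rule_config()` if your frame differs. A
gap at a rule position fails that rule: an absent residue cannot contact
DNA. Percentages in `summarize_categories()` are rounded half-away-from-
zero at two decimals, which reproduces printed category tables exactly
(e.g. 2/95 → 2.11, where banker's rounding would print 2.10).

## Physicochemical panel

All conventions follow the ExPASy ProtParam tool, since that is what
family surveys report: average (not monoisotopic) residue masses plus one
water; the Bjellqvist pKa set for pI (N-terminal pKa specific to the first
residue, C-terminal adjustments for terminal Asp/Glu; side chains D, E, C,
Y, H, K, R), solved by bisection of the net-charge equation on [0, 14] —
the default tolerance is 1e-6 pH so the residual net charge at the
returned pI is far below 1e-3, and the result agrees with an independent
1e-4 grid search to within 2e-3 pH (a tested property); Kyte–Doolittle
GRAVY; the Guruprasad instability index with the complete 400-entry DIWV
dipeptide table shipped in `inst/extdata/diwv_guruprasad.tsv` (provenance
in the file header), stability called strictly below 40; Ikai's aliphatic
index; charged counts Asp+Glu and Arg+Lys with histidine excluded.

One nuance: the panel is permutation-invariant *except* the instability
index (dipeptide order matters) and, strictly, the pI terminal-pKa
adjustments, which depend on the identity of the first and last residue.
The property tests permute interior residues.

## Tandem duplication, Ka/Ks, dating

**Tandem criteria.** Surveys rarely print their tandem definition. famchar
uses the common practice default — same chromosome, at most 1 intervening
gene, start-to-start distance ≤ 100 kb — with both knobs in
`tandem_criteria()` and echoed in the output. Detection is tested equal to
a brute-force all-pairs filter on random maps.

**Ka/Ks.** Nei–Gojobori (1986): per codon, synonymous site fractions by
enumerating the nine single-base mutants, with mutations to stop codons
excluded from the count (so N + S is slightly below 3 per codon — the
spec-stated convention; some implementations instead fold stop mutants
into N); differences averaged over all minimal mutational pathways,
excluding pathways through stop codons (if every pathway is blocked, all
are used with stop steps counted nonsynonymous — a rare, documented
fallback); Jukes–Cantor correction $d = -\tfrac34\ln(1 - \tfrac43 p)$
applied to pN and pS. Saturation ($p \ge 3/4$) leaves the rate undefined
(NA), mirroring real duplicate pairs reported with "only a Ka value";
such pairs get the selection label `undetermined` — the package does not
adopt the stronger evolutionary reading sometimes attached to them.
Model-based estimators (YN00, codon ML) are out of scope.

**Dating.** $T = K_s / (2\lambda)$ with $\lambda = 1.5\times10^{-8}$
substitutions/site/year for dicots, reported in Mya ($K_s = 0.03$ ⇒ 1.0
Mya). The printed form of this equation in the source material is
typographically garbled ("2λ × 106"); this is its only dimensionally
coherent reading, and it reproduces the published upper tandem estimate
(~64 Mya at $K_s \approx 1.92$).

## Expression screening

"Effective expression" is FPKM strictly greater than 1 — exactly 1.0 does
not count. Tissue specificity is tallied from that boolean matrix.
Fold-change screening uses $(x + \varepsilon)/(x_{ctrl} + \varepsilon)$
with pseudocount $\varepsilon = 0.1$ FPKM (zero FPKM is common; the source
is silent on zero handling), selects genes with any ≥2× change in either
direction, annotates — rather than enforces — the 2–5× band (the "2–5
times" phrasing describes observed magnitudes, not an exclusion rule), and
requires effective expression in an involved condition. Profile clustering
is average-linkage on 1 − Pearson of log2(FPKM + 0.1), the procedure
behind the usual heat-map row dendrogram; constant profiles fall back to a
scaled Euclidean distance with a message. qPCR relative expression is
2^−ΔΔCt against a reference gene (PP2A in the motivating study), with
replicate Ct values averaged (≥3) before ΔΔCt and the ΔCt SD carried for
error bars.

## Promoter motif scanning

Exact IUPAC consensus matching only, both strands, all overlapping
occurrences, with `N` in the promoter matching nothing. The shipped motif
TSV cites primary literature per motif and is meant to be edited; famchar
does **not** reproduce PlantCARE's curated matrix models, and motif
consensus strings for most named plant elements vary across the
literature — treat the file as a starting point.

## The synthetic-data generator: a stated world

`generate_family()` produces the package's entire test world. Defaults
mirror the cohort shape of a real woody-plant bHLH survey: 95 genes;
binding categories 24/13/3/55; 78 genes on 8 chromosomes (18 on the
largest, 2 on the smallest) plus 17 on scaffolds; 9 tandem pairs on
chromosomes 1, 5, 6, 7 and a scaffold (most on chromosome 6); five tissues
with 53 genes expressed in all, 2 in none, 2 fruit-only, 7 root-only; a
low-temperature series (control, 4 °C × 8 h, 4 °C × 5 d, −5 °C × 1 h)
with 62 effectively expressed genes of which 6 rise 2–5× and 4 fall;
1500-bp promoters with planted cis-elements.

Design choices worth knowing:

* **Domains are planted at exactly 61 residues** in the family bundle, so
  the gapless scanner recovers every start exactly and classification
  recovery is a sharp end-to-end test. Variable-loop domains are exercised
  separately in the frame-fitting tests. Category-determining residues are
  never touched by domain noise.
* **CDSs are uniform-synonymous back-translations** of the proteins (plus
  a TAA stop). No codon-usage model — nothing downstream needs one.
* **FPKM noise is log-normal (sdlog 0.2) truncated at class boundaries**:
  expressed cells stay above 1.5, silent cells below 0.8, treated/control
  fold ratios inside [2.2, 4.8] (regulated) or [0.6, 1.7] (flat). Without
  truncation, unbounded noise would produce ~2 spurious fold-band
  crossings per bundle, and the generator's contract — planted truth holds
  for *every* seed — would be false. The truncation was fixed before any
  acceptance run; it means the bundle cannot be used to study borderline
  fold-change behavior, which real data certainly has.
* **Promoter truth counts** are recorded by a generator-internal naive
  position-by-position matcher, independent of the regex-based scanner it
  tests, after scrubbing the random background of accidental motif hits
  and planting instances. Motif definitions overlap (a G-box *is* an
  E-box), so truth is the verified count on the final sequence.
* **`evolve_codon_pair()`** draws a uniform sense-codon ancestor and
  applies Poisson-proposed single-base changes, rejecting stops and
  accepting nonsynonymous changes at relative rate ω. NG86 recovers the
  planted ω to ±0.1 at 500 codons (tested at ω = 0.3 and 1.0).

What a green test does **not** establish: the generator has no introns,
no isoforms, no phylogenetic correlation between family members, no codon
usage bias, no compositional bias in promoters, and planted domains are
far closer to the seed consensus than a divergent real family would be.
Green means the *rules* are implemented exactly as stated, not that the
pipeline's statistical behavior on messy genomes has been measured.

## Numerical conventions and degenerate inputs

* Percentages: half-away-from-zero at 2 decimals, everywhere.
* Strict thresholds: FPKM > 1, consensus ratio > 0.5 / > 0.9,
  instability < 40, bit score ≥ threshold (hits), all as stated.
* Ties: modal residue alphabetical; best hit leftmost; loop placement
  lexicographic-first.
* Coordinates 1-based inclusive (GFF3 convention) throughout; strand is
  carried as metadata and used by no computation.
* Ambiguity codes are rejected by default; a permissive flag maps them to
  a sentinel (`X`/`N`) that every downstream score must exclude
  explicitly (`ignore_x = TRUE` in the physchem functions).
* Empty inputs error early and by name (empty FASTA, empty label set,
  zero comparable codons); saturated Jukes–Cantor corrections return NA
  rather than erroring.

## Scale limitations and the external validation path

The genome-scale counts of the motivating survey — 95 family members
found in a real genome, 78 placed on chromosomes, 7 intron-less genes,
41/59 cross-species syntenic ortholog pairs — cannot be reproduced from
synthetic data and are **not** asserted anywhere in the test suite. They
remain an optional validation path: run the pipeline on the *Prunus mume*
genome annotation and the associated transcriptome, inject the real HMMER
domain hits with `read_domain_hits()`, and compare the category table,
tandem pairs, and expression tallies against the published supplementary
tables. Phylogeny construction, subfamily assignment against the
Arabidopsis reference set, MEME motif discovery, synteny mapping,
subcellular-localization and interaction-network prediction are outside
this package's scope by design.
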