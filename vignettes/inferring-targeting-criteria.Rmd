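---
title: "Inferring plant miRNA targeting criteria from degradome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring plant miRNA targeting criteria from degradome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parecrit)
```

## The problem

Plant miRNAs direct cleavage of near-complementary mRNA targets; the cut
falls between the target nucleotides paired to miRNA positions 10 and 11.
Degradome (PARE) sequencing captures the 5′ ends of the resulting
downstream fragments, so a degradome read's 5′ position is direct,
quantitative evidence for a cleavage site. Target-prediction practice,
however, still filters candidate duplexes with one fixed rule set tuned on
a historical collection of *A. thaliana* interactions. `parecrit` treats
those rules as parameters to be estimated: it collects the duplexes that
the degradome itself supports with high confidence, profiles their
properties, and returns the loosest rule set that keeps a user-chosen
fraction of them.

This vignette documents the model, the tunable parameters, the numerical
choices, and what the synthetic fixtures do and do not demonstrate.

## Degradome peaks and confidence classes

Degradome reads are matched to transcripts exactly, full-length, on the
sense strand; a read adds its full abundance at the 5′ position of *every*
occurrence (multi-mapping reads are not apportioned — the simplest
reproducible convention, stated rather than hidden). Positions with more
than one read are categorized relative to their transcript's signal:

| category | definition |
|---|---|
| 0 | the unique maximum on the transcript |
| 1 | a maximum attained more than once |
| 2 | above the mean abundance |
| 3 | at or below the mean |

Two choices deserve note. The mean is computed over positions with
observed signal, not over all transcript positions — a length-normalized
mean would push essentially every position above it and drain category 2/3
of meaning. Equality with the mean is assigned to category 3 so that the
four categories partition all eligible positions. Peaks below 5 reads are
discarded (`min_peak_abund`): at that depth genuine cleavage cannot be
told apart from random degradation. Categories 0/1 form the
high-confidence (HC) class used for inference; 2/3 are low-confidence
(LC).

## Duplex geometry, alignment and scoring

A confident peak at coordinate `t` anchors the duplex: miRNA position 10
pairs the degradome 5′ nucleotide, so the target nucleotide pairing miRNA
position `p` sits at `t + 10 − p`, and the candidate site spans
`[t − (L − 10) − g, t + 9 + g]` for a miRNA of length `L` and bulge budget
`g`. The aligner minimizes the Allen-style score over all alignments with
at most `max_gaps` single-nucleotide bulges on either strand, keeping the
anchor fixed:

* penalties: match 0, G:U wobble 0.5, mismatch 1, bulge 1;
* position weight 2 inside the core region (positions 2–13), 1 elsewhere;
* ties prefer fewer bulges, then bulges closest to the miRNA 3′ end;
* a bulged target nucleotide is reported at the adjacent miRNA position
  (per-position states must be a function of miRNA coordinates, so a
  convention is required; it is declared, not biologically meaningful);
* positions that fall off a truncated site (peaks near transcript ends)
  are reported as mismatches, reserving the gap state for bulges.

Because the bulge budget is small the optimum is found by an exact
memoized search over the two arms flanking the anchor; the test suite
checks it against an independent closed-form enumeration of every bulge
placement (500 randomized sites per run).

## Hybridization strength: the MFE ratio

Each duplex is summarized by MFE(duplex) / MFE(perfect duplex of the same
miRNA), a scale-free number in (0, 1]. The default backend is a
nearest-neighbor model over the fixed alignment using the published
Turner 2004 constants: stacking energies for the six pair types, duplex
initiation (+4.10 kcal/mol), terminal AU/GU penalties (+0.50), bulge and
internal-loop initiations with an asymmetry term, 1×1 loops at their
typical tabulated value (+0.55), and exterior-mismatch stabilization from
the first unpaired nucleotides outside the duplex. Two deliberate
departures from the raw tables keep the ratio well-behaved:

* the few destabilizing (positive) G:U-on-G:U stacks are clamped at 0, so
  introducing a defect can never *lower* the duplex energy — the ratio is
  monotone in the number of interior defects;
* the energy is minimized over short terminal trims (up to three outermost
  pairs per end), since a folding engine would leave a weak extension
  beyond a defect unpaired.

ViennaRNA's `RNAduplex` is pluggable behind the same contract
(`mfe_backend = "vienna"`). On duplexes typical of accepted interactions
the two backends agree to about 0.01–0.02 in the ratio; an unconstrained
folding engine can occasionally slip the whole pairing register on heavily
edited duplexes, which the anchored model intentionally does not do — the
degradome fixes the register. The cross-backend test therefore bounds the
mean and median disagreement (0.05) rather than the worst case.

## Criteria inference and the retain rate

The criteria family mirrors standard practice: boolean mismatch
allowances at positions 10 and 11 (a G:U there counts as a mismatch),
caps on total and core mismatches, adjacent-mismatch occurrences (a run
of k mismatches counts k−1) overall and in the core, G:U pairs, bulges,
the alignment score, and a lower MFE-ratio cutoff.

Only the contract — retain at least a fraction `r` of the observed HC
duplexes, default `r = 0.85` — fixes the estimator, so the estimator
itself is a design choice of this package, made deterministic and
order-invariant:

1. each count cap is the smallest integer covering ≥ r of the duplexes
   (lower empirical quantile, type 1 — thresholds must be achievable
   values);
2. the score cap is the r-quantile rounded up to 0.5, the scoring atom;
   the MFE cutoff is the (1−r)-quantile rounded down to 0.01 (the
   precision in which such cutoffs are conventionally reported);
3. the position-10/11 allowances are granted only if a duplex within the
   retained quantile (the ⌈rn⌉ duplexes of lowest score, then highest MFE
   ratio) is non-Watson–Crick there, so a single extreme outlier cannot
   unlock the cleavage-critical positions;
4. if the assembled rules jointly retain less than r — marginal quantiles
   do not compose — single thresholds are relaxed greedily, each step
   taking the relaxation that recovers the most failing duplexes (ties
   resolved in the fixed field order of the criteria family), bounded by
   the envelope of the observed duplexes, where retention is 100% by
   construction.

Retention ≥ r is therefore guaranteed for any input, and `r = 1` returns
the envelope itself. Criteria inferred at a higher retain rate pass a
superset of the duplexes in all tested populations; in principle the
greedy stage could break that nesting on adversarial inputs (it stops as
soon as its own contract is met), which we accept as a known limitation.

The retain-rate default is justified by a sweep: infer criteria at
0.50, 0.55, …, 1.00, record sensitivity and precision against validated
interactions, and compute |ΔSe|/|ΔPPV| per increment. The selected value
is the lower endpoint of the first increment where the ratio drops below
1 — the point where precision loss starts outweighing sensitivity gain.

Evaluation uses the loose classes appropriate to degradome data: TP =
predictions with experimental validation, FP = predictions without,
P = validated interactions with HC peaks and expressed miRNAs;
Se = TP/P, PPV = TP/(TP+FP). Specificity is not computed — no
comprehensive true-negative class exists for interactions. Predicted and
validated sites are matched on (miRNA sequence, transcript, cleavage
coordinate ± 1 nt); the tolerance absorbs the two conventions for which
side of the cleaved bond a table records, and is configurable.

## Statistics for subset comparisons

Property profiles (per-position proportions of mismatch, G:U, gap, match)
of two duplex subsets — e.g. conserved vs species-specific miRNAs — are
compared with:

* an offset χ² goodness-of-fit test per position (reference proportions ×
  observed total as expected counts; 0.5 added to empty expected cells
  that have observations, cells empty in both sets dropped — so identical
  distributions give exactly p = 1); a pooled all-positions variant is
  also provided;
* two-sided Fisher exact tests per position and property, each position
  against the sum of the remaining positions;
* a Kolmogorov–Smirnov test on MFE-ratio distributions after seeded
  subsampling of the larger set to the smaller's size (without
  replacement), making the p-value reproducible.

Raw p-values are reported (a Benjamini–Hochberg adjustment is available
via `p.adjust` but off by default, matching how such per-position tables
are conventionally read); 0.05 is the reporting threshold, applied by the
reader, not baked into the computations.

## miRNA candidates and conservation

Candidates are sRNA reads with abundance ≥ 5 matching a known mature
miRNA with at most two mismatches, no gaps, sense strand only; G:U counts
as a mismatch here because this is sequence identity, not pairing. Length
variants of up to 2 nt are handled by sliding the shorter sequence along
the longer and taking the minimum Hamming distance — discarding a 20-nt
isomiR of a 21-nt annotation over a length difference would be wrong, and
gaps remain forbidden. A candidate whose homology matches span more than
one clade is called conserved; matches confined to one clade, or no
matches at all, make it species-specific. The species→clade map ships
with the package and is user-replaceable.

De-novo miRNA discovery (hairpin validation etc.) is out of scope; the
user-supplied list (still subject to the abundance floor) covers miRNAs
that external predictors would add.

## The synthetic fixtures

`generate_fixture()` builds a complete paired experiment with known
truth: random transcripts (default 30, 500–1500 nt), 21-nt miRNAs, and
planted target sites realized as the reverse complement of each miRNA
with planned per-position edits, laid into the transcript in the anchored
geometry. Degradome reads of 20 nt start at each planted cleavage
coordinate with planned abundance (default 10–80, comfortably above the
5-read floor); optional background degradation plants reads at random
positions with abundance 1 + Geometric(0.5), mimicking the low-abundance
noise floor of real degradomes. The sRNA sample contains each miRNA at
20–200 copies plus sub-threshold random reads. Defect plans keep the two
3′-terminal positions clean so the planted alignment is also the optimal
one, giving exact ground truth for recovery tests. A two-subset mode
plants 3′-biased edits for one half of the miRNAs and 5′-core-flexible
edits (positions 5, 8, 9, 10) for the other, with matching one- vs
two-clade annotations, to exercise the subset-portability analyses.

What passing on fixtures shows: the bookkeeping is right — peaks are
categorized as designed, planted duplexes are recovered exactly, the
retention contract holds, statistics match their oracles. What it cannot
show: performance on real data, where transcript composition is biased,
degradation is structured rather than geometric, miRNA families share
near-identical sequences, and validated-interaction tables are incomplete.
The problem sizes in the tests (tens of transcripts, 10–20 planted
interactions, duplex sets of 10–60 for the randomized contract trials)
were chosen to keep the full suite fast while still exercising every code
path; all thresholds in the tests are the method's own defaults, not
tuned values.

## Defaults at a glance

| parameter | default | meaning |
|---|---|---|
| `min_peak_abund` | 5 reads | degradome peak confidence floor |
| `min_mirna_abund` | 5 reads | sRNA abundance floor for candidates |
| `retain_rate` | 0.85 | fraction of HC duplexes the criteria must keep |
| sweep grid | 0.50–1.00 by 0.05 | retain-rate sweep |
| homology | ≤ 2 mismatches, no gaps | candidate ↔ annotation matching |
| core region | positions 2–13 | doubled score weight, core caps |
| permissive first pass | score ≤ 7, mm ≤ 5, G:U ≤ 4, gaps ≤ 1, adjacent ≤ 2, MFE ≥ 0.5 | strictly looser than anything inference can return |
| cleavage match tolerance | ± 1 nt | evaluation key matching |

The permissive first-pass values are deliberately generous stand-ins:
inference can only tighten them, so their exact values only need to be
loose enough not to censor the duplex population.
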