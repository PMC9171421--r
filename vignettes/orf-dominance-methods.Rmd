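---
title: "ORF dominance: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ORF dominance: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfdominance)
```

## The model

The package rests on one structural observation about transcripts: in
protein-coding RNAs the major ORF dwarfs the incidental ORFs that arise
by chance in the other reading frames, whereas in sequences without
coding constraint all ORFs are chance ORFs of comparable (short)
length. ORF dominance turns this into a score. With $l_{\mathrm{pORF}}$
the amino-acid length of the longest ORF across the three forward
frames and $l_{\mathrm{secORF},i}$ the lengths of all others,

$$\mathrm{dominance} = \frac{l_{\mathrm{pORF}}}
  {l_{\mathrm{pORF}} + \sum_i l_{\mathrm{secORF},i}} \in (0, 1].$$

The motivating hypothesis is translational: every secondary ORF is a
potential ribosome sink that reduces translation of the major ORF, so
coding transcripts are expected to have purged them over evolutionary
time. The score needs no alignment, no codon-usage model and no
training set, which is what makes it applicable uniformly from bacteria
to vertebrates and to viral genomes.

Ties for the longest ORF need no tie-breaking rule: the numerator is
the shared maximum and the denominator the sum of all ORF lengths, so
the score is unique regardless of which ORF is called "primary". A
transcript with no ORF at all has an undefined score and is excluded
from every population statistic.

### ORF definition

An ORF starts at `AUG`, ends at the first in-frame stop codon, and its
length in amino acids excludes the stop. An `AUG` that runs off the 3′
end without meeting a stop is not an ORF. Only the three forward frames
are scanned — ribosomes read 5′→3′, so the reverse complement is
irrelevant for a transcript. Two decisions here were genuinely open:

* **Nested ORFs.** Whether an `AUG` inside an already-open ORF starts a
  second, nested ORF ending at the same stop is not dictated by the
  definition. This package scans non-nested: after a stop closes an
  ORF, scanning resumes at the next codon, so ORFs within a frame are
  disjoint. This matches the reference ORF counts for the NCYM
  transcript (one ORF in its pORF frame, three in another), which are
  inconsistent with nested enumeration. The alternative would inflate
  the secondary-ORF sum of every long coding sequence and systematically
  depress the dominance of exactly the transcripts the score should
  rank highest.
* **Ambiguity codes.** IUPAC ambiguity codes are accepted and retained;
  a codon containing one matches neither `AUG` nor a stop. This keeps
  real database sequences scorable and deterministic, at the price of
  occasionally missing an ORF whose start or stop is masked. Whether
  the original analyses tolerated ambiguity codes is unknown; the rule
  chosen is the conservative one.

### Coverage

ORF coverage — the fraction of the transcript the pORF spans — is a
conventional feature of coding-potential tools and is carried alongside
dominance. No published formula pins down whether the stop codon
counts; here coverage is $(3\,l_{\mathrm{pORF}} + 3)/L$ for transcript
length $L$, capped at 1, i.e. the stop codon is included. The choice is
isolated in one place in `profile_transcripts()`, so the other
convention is a one-line change.

## Population statistics

Scores of a labeled set are binned into ten equal-width classes
represented by their medians $x \in \{0.05, 0.15, \dots, 0.95\}$.
Relative frequencies $f(x)$ (coding) and $g(x)$ (noncoding) each sum
to 1. Three derived quantities:

* **Coding potential** $F(x) = f(x)/(f(x)+g(x))$, the probability that
  a transcript with dominance $x$ is coding. Empirically $F$ is close
  to linear for $x \le 0.65$ in human and mouse, so the package fits
  ordinary least squares of $F(x)$ on $x$ over that range (`x_max`
  configurable).
* **Overlap** $O = \sum_x \min(f(x), g(x))$, a bounded $[0,1]$ measure
  of how separable the classes are; 1 means identical histograms.
* **Negative selection** $h(x)$: among transcripts with an orthologous
  sequence and a precomputed Ka/Ks, the per-bin fraction with
  $K_a/K_s < 0.5$. Computing Ka/Ks itself (PAML etc.) is out of scope;
  the package consumes a table.

### Filters and guards, with defaults

| parameter | default | role |
|---|---|---|
| `min_nt` | 200 nt | noncoding transcripts shorter than this are small RNAs, not lncRNAs, and are excluded |
| `min_porf_aa` | 20 aa | noncoding transcripts with a shorter pORF are excluded (such peptides lack clear significance) |
| `x_max` | 0.65 | upper dominance bound of the linear regime of $F(x)$ |
| `min_bin_count` | 5 | bins with fewer noncoding transcripts are dropped from the regression ($F$ is unstable there) |
| `min_noncoding` | 3 | minimum noncoding class size for the overlap score |
| Ka/Ks outliers | $K_a > 1$ or $K_s > 1$ | excluded before computing $h(x)$ |

Both exclusion thresholds are strict inequalities: a 200-nt transcript
with a 20-aa pORF is kept. Filters apply to the noncoding class only —
the coding labels are taken as curated truth. Records with $K_s = 0$
have an undefined ratio and are dropped with a warning; imputing a
ratio for them would manufacture signal.

### Numerical choices

* Bin edges are half-open $[0.1k, 0.1(k{+}1))$ with the last bin closed
  at 1.0, and a score exactly on an internal edge goes to the higher
  bin. Any fixed convention would do; this one is deterministic and
  keeps dominance 1 (single-ORF transcripts, a large class) in the top
  bin.
* Undefined $F(x)$ bins are excluded from the regression, not imputed.
* The regression is unweighted OLS on the bin medians. Whether the
  original fits weighted bins by count is unstated; unweighted is the
  simpler assumption and is what the closed-form checks in the test
  suite verify against, to $10^{-9}$.
* Scores are reported to three decimals with round-half-up (so
  $109/192 = 0.5677\ldots$ prints as 0.568); full precision is kept
  internally.
* `predict_potential()` clamps predictions to $[0,1]$ — the fit is a
  probability model — and warns above `x_max`, where the linear regime
  demonstrably ends.

## Null controls and the synthetic fixture

Two null models accompany the score, mirroring the two standard
sequence randomizations: i.i.d. uniform A/C/G/T sequences of matched
length, and per-transcript shuffles that preserve the exact base
multiset. Controls are generated one per input transcript with
per-transcript length matching (the stronger, deterministic pairing;
matching only the length distribution would add an arbitrary coupling
choice). All generators take a mandatory seed and are bit-reproducible.

`synthesize_fixture()` generates labeled test sets: coding-like
transcripts carry one clean embedded ORF (`ATG`, a stop-free codon run,
a stop) spanning 50–90% of the transcript inside otherwise uniform
random sequence; noncoding-like transcripts are entirely uniform
random. Defaults — lengths uniform on 500–3000 nt, ORF span fraction
uniform on 0.5–0.9 — were chosen once as a realistic mRNA/lncRNA scale.
The fixture reproduces the qualitative structure the method relies on:
a right-shifted coding dominance distribution, a left-shifted noncoding
one, and left-shifted random controls.

What the fixture does *not* emulate: real base composition and
isochore structure, UTR/CDS architecture, upstream ORFs, splice
variants, or the long tail of borderline bifunctional transcripts.
Passing the fixture-based tests therefore shows the machinery is
correct and directionally faithful, not that the numerical values of
$F(x)$ fits or overlap scores on real transcriptomes are reproduced —
those depend on genome-scale database downloads that are deliberately
outside this package. The worked-example anchors (the NCYM dominance
0.568, $F(0.15) = 0.183$, and the published human regression
coefficients) are checked exactly, from their printed inputs.

## Viral ORF score

For (+)ssRNA viral genomes the single-pORF logic does not apply —
genomes legitimately encode several proteins — so the bona fide ORFs
(vORFs) from an annotation replace the pORF:

$$\mathrm{vORF\ score} = \frac{\sum_i l_{\mathrm{vORF},i}}
  {\sum_i l_{\mathrm{vORF},i} + \sum_i l_{\mathrm{secORF},i}}.$$

The annotation-to-prediction match uses the shared frame and stop-codon
position, because annotated CDSs may start at an internal `AUG`
relative to the scanner's first-`AUG` convention but must share the
stop; lengths-only annotations fall back to amino-acid-length matching.
An annotated ORF that matches nothing still contributes its length to
the vORF sum (it is bona fide by assumption) and triggers a warning.
Viruses using frameshifting, RNA editing, or other exceptional
translation mechanisms are out of scope, as are spliced viral
transcripts.

## Problem sizes in the test suite

The suite validates the scanner against a brute-force oracle on 1,000
random sequences of 6–600 nt, the dominance range property on another
1,000, and the directional class separation on a 500 + 500 fixture with
Mann–Whitney tests at $p < 0.01$; regression checks run on the ten-bin
scale of the method itself. These sizes give stable verdicts for every
property tested while keeping the suite fast enough to run on every
change.

## Known limitations

* First-`AUG`, standard-code scanning only: no non-standard genetic
  codes, no splice-aware genomic scanning, no reverse strand.
* The score is blind to everything but ORF structure — conservation,
  expression, and peptide evidence are complementary, not replaced.
* $F(x)$ fits from small or strongly imbalanced transcript sets are
  unstable; the bin-count guards refuse the worst cases but cannot make
  a small set informative.
* The synthetic fixture is a correctness instrument, not a simulator of
  real transcriptomes (see above).
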