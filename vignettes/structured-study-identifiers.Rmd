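---
title: "Structured, layered study identifiers: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured, layered study identifiers: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortid)
```

## The identifier model

A study identifier in `cohortid` is a fixed-width string assembled from an
ordered sequence of blocks: study center `[C]`, study track `[T]`, a unique
random number `[N]`, study visit `[V]` and a check digit `[X]`. Only `[N]` is
mandatory; the order is free and preserved. Fixed widths — the configured
code lengths for `[C]` and `[T]`, `k` digits for `[N]`, one character each
for `[V]` and `[X]` — make every identifier parseable without delimiters,
which is what allows a study directory to be fully reconstructed from its
key-pair files alone.

Each participant carries identifiers in several *layers*. The k-digit number
range is split into three fixed thirds: the personal-data layer ID-P owns
$[1\cdot10^{k-1},\,4\cdot10^{k-1})$, the study-data layer ID-S owns
$[4\cdot10^{k-1},\,7\cdot10^{k-1})$ and the temporary linkage layer ID-T owns
$[7\cdot10^{k-1},\,10\cdot10^{k-1})$. The split buys three properties at
once: the three IDs of one participant can never collide, the layer of any
number is recoverable from its value, and each layer has a known capacity of
$3\cdot10^{k-1}$ numbers. Personal and study data are linked only through
two key-pair files, (ID-P, ID-T) and (ID-S, ID-T); the (ID-S, ID-T) file is
written in randomized row order so that row position alone cannot
re-associate the two sides. External identifiers ID-E (one per data-sharing
project) use the full $(k{+}1)$-digit range, one digit longer than any
internal number, and each project draws from its own independent pool so two
external partners cannot link records through their IDs.

ID-P always renders visit "0": personal data do not vary by visit. ID-S and
ID-T render the configured visit at creation; later visits change only the
visit character of ID-S (plus its check digit) and never re-issue ID-P or
ID-T.

## Parameters that matter

* `k` (2–9), the random-number length in digits. It fixes the per-layer
  capacity $3\cdot10^{k-1}$; validation requires the total requested sample
  size to stay *strictly below* that capacity (the wording of the capacity
  rule is strict, and we follow it), while the drawing machinery itself can
  fill a pool completely when batches are extended.
* The visit code: one character, a digit 1–9 or a letter excluding `i`, `e`,
  `o` (kept verbatim from the original tool's constraint; we found no stated
  rationale, but suspect confusability with digits and with each other in
  handwriting). Case sensitive, so `I` is allowed.
* The check algorithm: `PARITY`, `WEIGHTED_PARITY`, `DAMM_2004` or
  `GUMM_1986`. The schemes trade implementation simplicity against the error
  classes detected; the table below is verified exhaustively in the test
  suite.

| scheme          | single substitutions | adjacent transpositions | non-adjacent |
|-----------------|----------------------|-------------------------|--------------|
| parity          | if value shifts mod 10 | no                    | no           |
| weighted parity | if weighted shift ≠ 0 mod 10 | yes (distinct digits) | some missed |
| Damm (quasigroup) | all                | all                     | not guaranteed |
| Gumm-style mod-11 | all                | all (length ≤ 9)        | all (length ≤ 9) |

## Numerical and design choices

**Interval exponent.** The thirds are defined with exponent $k-1$: a k-digit
number lies in $[10^{k-1}, 10^k)$, so for $k=5$ the P interval is
[10,000; 40,000). This matches the printed capacity figures (30,000 at
$k=5$, 300,000,000 at $k=9$).

**Uniqueness machinery.** Issued numbers are kept in a hash environment, so
each candidate costs O(1) to test regardless of pool size. Drawing uses
rejection sampling while the request is below half of the remaining
capacity, and switches to sampling without replacement from the enumerated
residual set beyond that — rejection sampling degrades sharply as a pool
fills, while the residual-set path stays uniform over the unissued numbers
and fast. Both paths produce draws uniform on the unissued set, so the
switch is invisible in the output distribution (a chi-square sanity test in
the suite guards this).

**Seeding and streams.** Draws are reproducible from an explicit integer
seed. Number draws and key-file row shuffles use separately labelled RNG
streams derived from the same seed, so publishing a seed for audit does not
let the shuffled (ID-S, ID-T) row order be replayed against the draw order.
Without a seed, streams initialize from R's own entropy and runs are
intentionally irreproducible. Each source carries its own RNG state and
never disturbs the global RNG.

**Gumm scheme and REDRAW.** The 1986 mod-11 construction is implemented as a
power-of-two-weight scheme: the check digit $c$ satisfies
$\sum_i 2^i v_i + c \equiv 0 \pmod{11}$. Since 2 generates the
multiplicative group mod 11, all substitutions and all transpositions within
9 positions are detected. The cost is that roughly 1 in 11 payloads needs
$c = 10$, which is not a single digit; such candidate numbers are discarded
and redrawn so every emitted ID keeps a fixed width. Two consequences are
documented rather than hidden: (a) discarded numbers stay marked as used —
they would fail again, and keeping them issued preserves the uniqueness
audit trail; (b) a later `add_visit()` cannot redraw a number, so a visit
substitution that lands on check value 10 raises an error suggesting a
different visit code. Studies planning follow-up visits should prefer
`DAMM_2004`, which never redraws.

**Letters in check digits.** Parity schemes value letters by their ASCII
code (65 for "A"). The table-based schemes operate on the digit domain, so
letter values are reduced mod 10 before entering the Damm quasigroup or the
mod-11 sum; this keeps the tables valid and is a documented package choice.

**Check-digit position.** `[X]` may sit anywhere in the layout; it is always
computed over all other rendered characters in their rendered order and
substituted into its own position. This honors the free block ordering
without making the check value depend on where the check sits.

**Code 128B serialization.** Barcode companions store, per ID, the font
string of the symbol sequence `[104, ASCII−32 data, mod-103 checksum, 106]`.
The font mapping (values 0–94 → codepoints 32–126, 95–106 → 195–206) is the
de-facto convention of Code 128 barcode fonts and is exactly invertible;
no raster images are produced.

**File conventions.** Key-pair files are two tab-separated columns without
header — unambiguous and spreadsheet-importable. Writes go to a temporary
file renamed into place, and all drawing happens before any file is touched,
so a failed task never leaves partial output. Superseded batches are renamed
`.txt` → `.old` (never deleted; a numeric suffix avoids collisions), and the
reconstruction in `load_study()` treats `.old` archives as part of the
issued-number record while exempting them from the cross-file duplicate
check that current files must pass. Every task appends a timestamped audit
line; audit logging can be disabled where byte-identical reproducibility is
wanted (the fixture generator does this).

## What the fixture generator emulates

`make_fixture_study()` builds study directories in code. The `small` profile
(one implicit track, layout `N`, $k=3$, $n=10$) is the minimal end-to-end
study. The `augur_like` profile emulates a three-track elderly-cohort
recruitment: layout `T,N,V,X`, $k=5$, Damm check digits, baseline visit "1",
and tracks "1"/"2"/"3" with $n = 100/20/20$ — a roughly 100-fold scale-down
of a realistic recruitment campaign (tens of thousands of IDs printed for a
response fraction well below 50%), with the registry-based track dominating.
The scale-down keeps the fixture fast while exercising every block type;
capacity and uniqueness behavior at full scale follows from the same code
paths, since the drawing strategy depends only on the request-to-capacity
ratio.

What passing tests on these fixtures do **not** show: operational aspects of
real deployments (concurrent operators, transfer of key files to a linkage
unit, deletion workflows at study end) are out of scope, and wall-clock
performance at $k \ge 6$ with millions of requested IDs is not measured by
the suite — the test problem sizes (hundreds of IDs, pools up to a few
thousand) were chosen to exercise every code path, including pool
exhaustion, at desk scale.

## Known limitations

* One study center per run: multi-center studies run one configuration per
  center, distinguished by the `[C]` block.
* Visit and check blocks are one character wide; center and track codes may
  be longer but must share one width per study (fixed-width parsing).
* The Gumm-style scheme is this package's documented construction of a
  mod-11 check; other historic variants of that family exist.
* No encoding of participant characteristics beyond free-form track codes —
  encoding sex or age groups into IDs invites re-identification and is
  deliberately unsupported.
* Serial (sequential) numbering is deliberately not offered: consecutive
  IDs would let one known key pair predict its neighbors, defeating the
  layered-ID separation.
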