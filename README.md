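# cohortid

Guaranteed-unique, block-structured, multi-layer study identifiers for
epidemiologic and clinical studies.

## The problem

Epidemiologic studies need identifiers that do more than label a participant.
Good practice requires **separating personal data from study data**, which
means each participant carries several linked IDs: one for personally
identifiable information (ID-P), one for the scientific record (ID-S), a
temporary ID (ID-T) used only to link the two through key-pair files held by a
linkage unit, and per-partner external IDs (ID-E) so that two outside
collaborators can never merge their datasets. On top of that, studies want
**structured** identifiers that encode the study center, recruitment track and
visit, a **check digit** to catch manual entry errors, and the ability to
issue **new batches** later that are guaranteed distinct from everything
already issued.

`cohortid` implements this identifier model end to end, for study personnel
and data managers who need key-pair files on disk, not a database.

## The model

An identifier is a fixed-width concatenation of blocks in a user-chosen
order — `[C]` center, `[T]` track, `[N]` random number, `[V]` visit, `[X]`
check digit — with only `[N]` mandatory. The k-digit number range
`[10^(k-1), 10^k)` is split into three fixed thirds:

| layer | interval                          | example (k = 5)    |
|-------|-----------------------------------|--------------------|
| ID-P  | `[1·10^(k-1), 4·10^(k-1))`        | [10,000; 40,000)   |
| ID-S  | `[4·10^(k-1), 7·10^(k-1))`        | [40,000; 70,000)   |
| ID-T  | `[7·10^(k-1), 10·10^(k-1))`       | [70,000; 100,000)  |

so each layer owns `3·10^(k-1)` numbers (30,000 at k = 5; 300,000,000 at the
maximum k = 9) and a number's layer is recoverable from its value alone.
External IDs draw from the full `(k+1)`-digit range and so can never collide
with internal numbers. Numbers are drawn uniformly and checked against a
hash set of everything already issued in the study, so uniqueness is a
guarantee, not a probability.

Four check-digit schemes are available, differing in the entry-error classes
they detect: plain parity (sum mod 10; no transpositions), weighted parity
(position-weighted sum mod 10; adjacent transpositions), the Damm quasigroup
method (all single-digit errors and adjacent transpositions) and a mod-11
Gumm-style scheme with power-of-two weights (all transpositions up to length
9; candidate numbers whose check value would be 10 are discarded and
redrawn). Letters contribute their ASCII code (65 for "A") in the parity
schemes and their value mod 10 in the table-based ones. Every ID is also
emitted as a Code 128B barcode symbol sequence (start code 104, data values
ASCII−32, mod-103 weighted checksum, stop code 106) rendered as a
barcode-font string.

## Worked example

```r
library(cohortid)

cfg <- study_config("DEMO", layout = "T,N,V,X", k = 5,
                    tracks = c("1" = 4, "2" = 2), visit = "1",
                    check_algorithm = "DAMM_2004", seed = 42)
res <- create_ids(cfg, root = tempdir())
res
#> # A tibble: 6 × 7
#>   track idp         np ids         ns idt         nt
#> 1 1     13148605 31486 15187614 51876 18619112 86191
#> 2 1     13108504 31085 14640916 46409 19533719 95337
#> 3 1     13514006 35140 15622915 56229 18368616 83686
#> 4 1     11920906 19209 15832914 58329 17220117 72201
#> 5 2     21689305 16893 24166713 41667 29371916 93719
#> 6 2     21883001 18830 25502516 55025 27652218 76522
```

Reading `13148605`: track `1`, random number `31486` (from the ID-P third
[10,000; 40,000)), visit `0` (ID-P always renders visit 0), Damm check digit
`5`. The matching study ID `15187614` carries its own number `51876` from the
ID-S third and visit `1`. On disk, `tempdir()/DEMO/` now holds per track a
`(ID-P, ID-T)` file in creation order and a `(ID-S, ID-T)` file in shuffled
row order (so file order cannot re-associate the two), e.g.
`DEMO_IDS_IDT_T=1_N=4_Baseline.txt`:

```
15832914	17220117
15622915	18368616
15187614	18619112
14640916	19533719
```

plus `_barcode` companions and the persisted `config.xml`. Follow-up tasks
work from the directory alone:

```r
add_visit(attr(res, "dir"), "2")        # 15832914 -> 15832923 (visit + check)
generate_external(attr(res, "dir"), "EXT", seed = 42)
#>   1 15832914 EXT8525354              # EXT + 6-digit number + check digit
add_ids(attr(res, "dir"), c("1" = 10), seed = 43)  # batch extension, no collisions
```

The same tasks are available from a shell via the installed script
(`system.file("scripts", "idgen", package = "cohortid")`):

```sh
idgen create --study DEMO --layout T,N,V,X --k 5 --tracks "1;2" --n "4;2" \
      --visit 1 --algorithm damm_2004 --seed 42
idgen verify --config DEMO/config.xml 15832914
```

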