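# avoidedwords

Finds **avoided words** in biological sequences: words whose observed
frequency falls significantly short of what the frequencies of their own
maximal proper factors predict. Such words are of interest in DNA
linguistics — strongly underrepresented oligonucleotides mark restriction
endonuclease target sites in prokaryotes, signals confined to specific
positions, and sequence classes (such as conserved non-coding elements)
with distinctive composition constraints.

## The statistic

For a word `w` with `|w| > 2` in a sequence `x`, with `f(·)` the count of
possibly overlapping occurrences and `w_p`, `w_s`, `w_i` the longest proper
prefix, suffix and infix of `w`:

```
E(w)   = f(w_p) · f(w_s) / f(w_i)        (0 if the infix is absent)
dev(w) = (f(w) − E(w)) / max(√E(w), 1)
```

Given a threshold `ρ < 0`, `w` is **ρ-avoided** when `dev(w) ≤ ρ`. Avoided
words may *occur* in `x` or be entirely *absent*; every absent avoided word
is a minimal absent word (absent, but with all proper factors occurring),
which is what makes the computation tractable: instead of scoring all `σ^k`
possible words, the package scores the ≤ `σn` minimal absent words plus the
first-letter children of explicit internal suffix tree nodes, in time
linear in `n` for a fixed alphabet. Core data structures (an annotated
Ukkonen suffix tree with occurrence counts, word depths and suffix links)
are implemented in C++.

## Worked example

```r
library(avoidedwords)
avoided_words("AGCGCGACGTCTGTGT", k = 3, rho = -0.4)
#> rho-avoided words (fixed-k, k = 3, rho = -0.4): 7 words
#>  word length    status f         E        dev f_p f_s f_i
#>   TCG      3    absent 0 0.7500000 -0.7500000   1   3   4
#>   TGC      3    absent 0 0.6666667 -0.6666667   2   2   6
#>   AGT      3    absent 0 0.5000000 -0.5000000   1   3   6
#>   GAG      3    absent 0 0.5000000 -0.5000000   1   1   2
#>   GCT      3    absent 0 0.5000000 -0.5000000   2   1   4
#>   CGT      3 occurring 1 1.5000000 -0.4082483   3   3   6
#>   GTG      3 occurring 1 1.5000000 -0.4082483   3   2   4
```

Reading the `CGT` row: `CG` occurs 3 times, `GT` 3 times and the infix `G`
6 times, so `E = 3·3/6 = 1.5` while `CGT` occurs once, giving
`dev = (1 − 1.5)/√1.5 = −0.408248` — an *occurring* avoided word. `AGT`
never occurs (`f = 0`) although `AG`, `GT` and `G` all do
(`E = 1·3/6 = 0.5`, `dev = −0.5`) — an *absent* avoided word. Rows are
ranked by deviation (most avoided first), ties broken alphabetically; the
integer columns `f_p, f_s, f_i` let you reproduce `E` exactly.

Other entry points:

* `all_avoided_words(x, rho)` — every length at once; the longest reported
  word never exceeds the longest repeated factor of `x` plus 2.
* `minimal_absent_words(x)` — the MAW set in its unique
  `<(i, j), alpha>` tuple representation.
* `suffix_tree(x)`, `occurrence_count(st, w)`, `st_locate(st, w)` — the
  annotated tree itself.
* `brute_force_avoided()`, `brute_force_maws()`, `naive_count()` —
  independent sliding-window reference implementations used by the tests.
* `random_sequence()`, `maw_dense_sequence()`,
  `maw_dense_triplet_sequence()` — seeded random input and extremal
  constructions that meet the `Ω(σn)` minimal-absent-word bounds.
* `is_self_complementary()`, `summarize_self_complementarity()` — for
  restriction-site style analyses of the most avoided DNA words.

## Command line

The installed executable `exec/avoided-words` runs the same computation
from a shell:

```sh
avoided-words -i genome.fa -k 6 -r -10 -o avoided.tsv --self-complementary-report
avoided-words --generate ACGT:1000000:7 -k 8 -r -10 -o avoided.tsv
```

Output is a tab-separated file (sequence id, word, status, `f`, `E`,
`dev`), one result block per FASTA record, preceded by comment lines
recording `k`, `ρ`, the mode and any generator seed. `--all-lengths`
switches to the every-length algorithm, `--maw-output` additionally writes
the minimal absent words one per line.

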