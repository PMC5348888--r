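---
title: "Avoided words: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Avoided words: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidedwords)
```

## The statistic

Given a sequence $x$ of length $n$ over an alphabet of size $\sigma$, write
$f(w)$ for the number of (possibly overlapping) occurrences of a word $w$ in
$x$. For $|w| > 2$, let $w_p$, $w_s$ and $w_i$ be the longest proper prefix,
suffix and infix of $w$. The expected frequency of $w$ is estimated from the
counts of its maximal proper factors:

$$E(w) = \frac{f(w_p)\,f(w_s)}{f(w_i)} \quad \text{if } f(w_i) > 0,
\qquad E(w) = 0 \text{ otherwise.}$$

The rationale: of the $f(w_i)$ occurrences of the infix, a fraction
$f(w_p)/f(w_i)$ is preceded by the first letter of $w$ and a fraction
$f(w_s)/f(w_i)$ is followed by its last letter; treating the two events as
independent predicts $E(w)$ occurrences of $w$. The two events are *not*
always independent; the estimator is nevertheless used verbatim, as is
standard for this statistic, and no correction is applied.

The standardized difference

$$\mathit{dev}(w) = \frac{f(w) - E(w)}{\max\{\sqrt{E(w)},\, 1\}}$$

is a chi-square-style score. For a user threshold $\rho < 0$, a word is
**$\rho$-avoided** when $\mathit{dev}(w) \le \rho$; the boundary
$\mathit{dev}(w) = \rho$ counts as avoided. An avoided word may occur in $x$
or be entirely absent from it. There is no significance calibration here:
$\rho$ is a cutoff the analyst chooses, and in practice one runs with a
$\rho$ close to zero and inspects the deviation-ranked extreme of the list
(which is how the package orders its output).

```{r example}
avoided_words("AGCGCGACGTCTGTGT", k = 3, rho = -0.4)
```

## Why the computation is not a $\sigma^k$ sweep

Two structural facts make the search linear rather than exhaustive:

* **Absent avoided words are minimal absent words (MAWs).** If $f(w) = 0$ and
  $\mathit{dev}(w) \le \rho < 0$ then $E(w) > 0$, so both maximal proper
  factors of $w$ occur — exactly the definition of a MAW. A sequence has at
  most $\sigma n$ MAWs, each of length at most the longest repeated factor
  plus 2, so the absent side reduces to scoring MAW tuples.
* **Occurring avoided words have an explicit prefix locus.** If the longest
  proper prefix $w_p$ of an occurring word labels an *implicit* suffix tree
  position, then $f(w_p) = f(w)$ and $f(w_i) \ge f(w_s)$ give
  $\mathit{dev}(w) \ge 0$. So only first-letter children of explicit internal
  nodes need scoring: at most $n - k + 1$ candidates at a fixed length $k$,
  at most $2n - 1$ (the suffix tree edge bound) over all lengths.

Together the candidate count at fixed $k$ is at most $(\sigma + 1)n - k + 1$,
and every candidate is scored in constant time from the annotated tree:
$f(w) = C(\text{child locus})$, $f(w_p) = C(v)$, $f(w_i) = C(\text{suffix
link of } v)$ and $f(w_s) = C(\text{its } \alpha\text{-child})$.

## Implementation

The suffix tree is built by Ukkonen's online algorithm over $x$ plus a
unique sentinel, in C++ behind the R surface. The sentinel makes every
suffix end at a leaf, which keeps the terminal count $C(v)$ well defined; it
is excluded from everything user-visible (counts never include it, and leaf
word-depths are reported without it, so the leaf for suffix 0 of a 16-mer
has depth 16). A depth-first pass fills word-depths, subtree terminal
counts, and a smallest-suffix-index witness per node so any node's label is
recoverable as a slice of $x$ without storing strings.

MAWs are enumerated from the tree in $O(\sigma \cdot \text{nodes})$: for
each explicit node $u$ and child edge with first letter $b$, the letters
that precede occurrences of $L(u)$ but no occurrence of $L(u)b$ each yield a
MAW $a\,L(u)\,b$. The sentinel guarantees every suffix locus is explicit,
which is what makes this scan exhaustive; correctness is nevertheless pinned
down by exhaustive equivalence tests against a brute-force enumeration that
shares no code with the tree. Each MAW is reported once in the tuple form
$\langle (i, j), \alpha\rangle$ with $x[i..j]$ its longest proper prefix,
using the smallest witness occurrence; tuples are streamed to the scoring
routine for lengths $\ge 3$ only, since the deviation is undefined below
that (absent letter pairs are still reported by
`minimal_absent_words()` for completeness).

### Numerical choices

* $E$ is computed in double precision from exact integer counts; every
  record also carries the integer triple $(f_p, f_s, f_i)$ so $E$ is
  reproducible as a rational.
* Text output rounds $E$ and $\mathit{dev}$ to 6 decimals (the precision the
  statistic is conventionally quoted at), but the threshold comparison uses
  the unrounded value, so formatting can never move a word across $\rho$.
* Ties in the deviation ranking are broken lexicographically on the
  rank-mapped word (C-locale order), making output deterministic
  byte-for-byte.
* `k > n + 1` returns an empty result rather than an error: no word that
  long occurs, and no MAW is that long.
* The alphabet is whatever letters occur in the input, rank-ordered; case is
  preserved (an `--uppercase` switch normalises on request). Ambiguity
  letters such as `N` are ordinary letters to the core computation; only the
  self-complementarity utility rejects them, and `--skip-N` drops such
  records wholesale.

## Synthetic data: what it covers and what it does not

`random_sequence()` draws i.i.d. uniform letters with R's Mersenne-Twister
stream, seeded and restoring the caller's RNG state. This matches the
regime in which the expected length of the longest repeated factor — and
hence of the longest avoided word — is $O(\log_\sigma n)$, a property the
tests probe empirically (median longest avoided word at $n = 10^5$ versus
$10^3$ over several seeds, expected gap $\approx 2\log_4 100 \approx 6.6$,
asserted within generous slack). Uniform sequences have no composition
bias, no repeats and no selection, so tests passing on them demonstrate
algorithmic correctness, not biological insight: on such input extreme
thresholds like $\rho = -10$ correctly return nothing, whereas real genomes
(where avoidance reflects restriction sites, chromatin constraints or
replication slippage) produce the interesting lists.

Two deterministic extremal constructions exercise the combinatorial edge of
the MAW machinery: `maw_dense_sequence(sigma, n)` (for $\sigma = 2$ the word
$b\,a^{n-2}\,b$; in general one separator letter between runs of $a$) meets
the $\Omega(\sigma n)$ lower bound on MAW counts, and
`maw_dense_triplet_sequence(sigma)` concatenates shrinking blocks so that
prefixes carry $\Omega(\sigma |y|)$ MAWs of length exactly 3. The tests
assert the explicit counting bounds these constructions realise
($(\sigma-1)(\sigma-2)\lfloor n/(\sigma-1)\rfloor - (\sigma-2)$ MAWs, and
$((\sigma-2)^2 - \sigma)\lfloor |y|/2\sigma\rfloor$ length-3 MAWs).

## Problem sizes in the test suite

The exhaustive equivalence sweep covers every binary word up to length 10,
all lengths $2 < k \le 11$ and three thresholds, plus 100 seeded random DNA
sequences of length 200 at $k = 3..8$ — small enough that the $\sigma^k$
brute-force route is itself trustworthy, which is the point of the sweep.
The scaling check runs generated DNA at $n = 1, 2, 4$ million letters
($k = 8$, $\rho = -10$) and asserts that elapsed time grows roughly
linearly (with generous slack, since wall-clock ratios are noisy) and that
the node count — the memory driver — is linear, which it provably is.
These sizes keep the default suite comfortably interactive while still
exercising the regime the method is designed for; the implementation itself
has no size-dependent switches, so nothing changes qualitatively at larger
$n$.

## Known limitations

* One suffix tree per FASTA record: statistics are per sequence, and no
  cross-record aggregation is offered (a word avoided in each of two records
  is reported twice, once per record).
* The child maps use ordered containers, so construction is
  $O(n \log \sigma)$ rather than strictly $O(n)$; at genome scale this is a
  constant-factor matter, not an asymptotic one, and multi-megabase inputs
  run in seconds.
* Overabundant words ($\mathit{dev}$ large and positive) are out of scope,
  as is any p-value attached to $\mathit{dev}$.
* The all-lengths mode reports each avoided word once with its own length;
  there is no per-$k$ normalisation across lengths.
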