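---
title: "One-way ANOVA tables with letter-based mean separation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-way ANOVA tables with letter-based mean separation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aovtab)
```

## The problem

Tables in agricultural, nutritional, and biomedical papers typically report
each treatment group as mean ± SEM, with superscript letters marking which
group means differ significantly: groups sharing a letter are *not*
significantly different at the chosen level. Producing such a table by hand
means running a one-way ANOVA per response variable, an all-pairwise
post-hoc procedure, translating the pairwise decisions into letters, and
typesetting the result — a tedious and error-prone chain. `aovtab`
implements that chain end to end, for raw observations and, importantly,
for *summary* data (per-group n, mean, and SD or SEM), so a published table
can be checked or regenerated without the raw measurements.

## The model and the summary-statistics decomposition

The one-way fixed-effects model assumes k groups with observations
$y_{ij} \sim N(\mu_i, \sigma^2)$ — normal within-group errors with a
common variance, groups differing only in their means. Every quantity in
the ANOVA table is a function of the per-group triples $(n_i, m_i, s_i)$:

$$
SS_B = \sum_i n_i (m_i - \bar{y})^2, \qquad
SS_W = \sum_i (n_i - 1) s_i^2,
$$

with $\bar{y} = \sum_i n_i m_i / N$, degrees of freedom $k-1$ and $N-k$,
$F = MS_B / MS_W$, and the p-value from the upper tail of
$F(k-1,\,N-k)$. `anova_from_raw()` is literally
`anova_from_summary(summarize_raw(...))` — one computation path, so raw and
summary input agree exactly, and the k = 2 case collapses to the pooled
two-sample t-test ($F = t^2$, identical p).

When the source reports SEM rather than SD, the SD is recovered as
$s_i = \mathrm{SEM}_i \sqrt{n_i}$, the standard definition with no
small-sample correction. $MSE = MS_W$ is the pooled variance reused by all
post-hoc procedures; the *pooled SEM* reported in the compact table format
is $\sqrt{MSE/n}$, with $n$ replaced by the harmonic mean of the $n_i$ in
unbalanced designs — the same convention the range tests use, so the two
places a harmonic mean appears cannot disagree.

Degenerate inputs are handled rather than crashed on: all-zero SDs with
equal means give `f_stat = NA`, `p = 1` plus a warning (a constant column
in a workbook should not kill a batch run); all-zero SDs with unequal means
is an error, since no finite F exists.

## The post-hoc menu and its error-rate trade-offs

All four procedures compare every pair of means on the shared MSE; they
differ in how they pay for multiplicity.

* **Fisher LSD** (`lsd_test`): pairwise t-tests,
  $t = (m_i - m_j)/\sqrt{MSE(1/n_i + 1/n_j)}$ on $N-k$ df. Most powerful,
  weakest family-wise error control (strong control only at k = 3).
  Optionally the family of raw p-values is adjusted by Bonferroni
  ($\min(1, mp)$) or Holm (step-down, uniformly no larger than Bonferroni);
  `adjust_pvalues()` exposes the adjustment separately.
* **Tukey-Kramer** (`tukey_kramer`): single-step studentized-range test,
  $q = |m_i - m_j|/\sqrt{(MSE/2)(1/n_i+1/n_j)}$ referred to the
  studentized range distribution with parameters $(k, N-k)$ — the Kramer
  pairwise standard error handles unbalanced designs. Strong FWER control,
  lowest power of the menu.
* **SNK** (`snk_test`): stepwise range test. Means are ordered; a pair
  spanning r ordered means is tested against the critical range
  $q_{\alpha}(r, N-k)\sqrt{MSE/n_h}$, $n_h$ the harmonic mean of the sizes
  of the spanned groups. Spans are examined widest first, and when a span's
  extreme difference fails, every pair inside it is declared not
  significant untested — the blocking rule that keeps stepwise decisions
  coherent.
* **Duncan** (`duncan_test`): SNK with the relaxed per-span protection
  level $\alpha_r = 1 - (1-\alpha)^{r-1}$, hence critical ranges never
  above SNK's and strictly more rejections on the same data.

On balanced data the rejection sets nest: TK ⊆ SNK ⊆ Duncan ⊆ unadjusted
LSD; the suite property-tests this ordering on random inputs.

Two design points were genuinely open and are resolved as follows. First,
the stepwise tests do not define a single family-wise-calibrated adjusted
p-value, so SNK/Duncan report the *decision* and the critical range as
normative, plus an informational per-pair p from the span-r range
distribution with `p_adjusted = NA`. Second, post-hoc testing runs
*unprotected* by default — published tables are generally produced that
way and the range tests carry their own protection — with
`protected = TRUE` opting into the classical two-step rule that blanks the
letters whenever the omnibus p exceeds α.

## Compact letter display: insert and absorb

`insert_absorb()` converts the pairwise significance relation into letters
by the insert-and-absorb algorithm: start with a single class holding all
groups; for each significant pair, duplicate every class containing both
members, deleting one member from each copy; after every insertion delete
any class that is a subset of another ("absorption"). The result is sound
by construction — significant pairs share no letter, non-significant pairs
share at least one — and the suite verifies soundness exhaustively over
all $2^{\binom{k}{2}}$ relations for k ≤ 4 and on 1,000 random relations
for k ∈ {5, 6, 7}.

Pairs are processed in a fixed lexicographic order, so the output is
deterministic; any order would be valid. No letter-minimisation beyond
absorption is attempted (no sweeping or clique-cover optimisation):
absorption alone guarantees correctness, and for the interval-structured
relations real mean comparisons produce it is also economical. For
*arbitrary* relations the number of classes can exceed k (the absorbed
family is an antichain, so Sperner's bound $\binom{k}{\lfloor k/2\rfloor}$
is the sharp limit) — irrelevant in practice but asserted honestly in the
tests.

Which class is named 'a' is pure presentation, and published tables are
not even self-consistent about it. The pipeline attaches 'a' to the class
containing the largest mean; all internal comparisons use
`letters_to_partition()`, the canonical set-of-classes form invariant to
letter renaming.

## Input handling

`read_workbook()` covers four arrangements: a single raw dataset (S1),
multiple raw datasets one-per-sheet (S2), a single summary dataset (S3),
and multiple summary sheets (S4). XLSX/XLS go through readxl; CSV (single
"sheet", so S1/S3) is a documented convenience extension. The data
rectangle need not start at cell A1 — the reader locates the single
contiguous block of non-empty cells and treats its first row as the
header; two disjoint blocks in one sheet is an error rather than a guess.
Missing values are empty cells (or empty/`NA` fields in CSV).

The summary layout is normative here, since the original toy files exist
only as screenshots: first column the group label, then per response a
mean column (whose header names the response) immediately followed by its
dispersion column. Whether dispersion columns hold SD or SEM is a user
declaration, not auto-detected; sample sizes are user-supplied via
`parse_sizes()` — one token for a balanced design, otherwise one per group
in source order. Variable names with spaces are a hard error (failing fast
beats guessing); names over 10 characters draw a warning suggesting a
descriptive abbreviation but are never truncated.

## Rendering and precision

`build_table()` assembles either the per-group-SEM format
("mean ± SEM" cells with superscripts) or the pooled-SEM format
(mean-only cells plus a pooled-SEM column). Rows whose letter display has
a single class carry no superscripts, matching how unlettered rows appear
in print. All arithmetic is double precision throughout; rounding happens
only at the display layer, half away from zero. Summary input echoes the
decimal places of the source text (a value printed "1.60" renders at two
decimals); raw input defaults to two decimals, configurable. The pooled
SEM prints at one decimal more than its row's means, as it is typically an
order of magnitude smaller; published pooled-SEM columns are too
inconsistent to reproduce digit-for-digit and are not treated as a
contract.

`write_rtf()` emits a deterministic single-table RTF 1.x document
(superscripts via `\super`, "±" as the code-page escape `\'b1`, bold
header, footnote paragraph); byte-identical output for identical input is
tested. `read_rtf_cells()` is a deliberately minimal parser for exactly
these documents, existing to close the round-trip test loop, not to read
arbitrary RTF. TSV and Markdown mirrors serialize letters as plain
suffixes for diffing.

## The synthetic workbook generator

`make_raw_workbook()`/`make_summary_workbook()` realize exactly the model
the ANOVA assumes: group i of each response is
`group_effects[i] + N(0, sigma)`, independent across responses, written as
a spreadsheet plus a sidecar TSV recording both the true parameters and
the exact sample moments. Defaults emulate the toy files used in the
documentation: raw — factor "group", four levels A–D, six responses
V1–V6, n = 10 per group, σ = 1, effects (0, 0.5, 1, 2) so generated
tables contain both lettered and unlettered rows; summary — two responses
Var1–Var2 over levels L1–L4 with n = 15, the balanced-size example used
in the input grammar. Workbooks are byte-identical per seed (the writer
uses fixed archive timestamps), which the determinism tests rely on.

What the generator does *not* emulate: heteroscedasticity, heavy tails,
outliers, missingness mechanisms, or correlated responses. Passing tests
therefore demonstrate correctness of the computations under the model's
own assumptions, not robustness of the statistical conclusions when those
assumptions fail — the same caveat that applies to one-way ANOVA itself.

## Reference dataset and what the checks show

`table1_data()` packages an 11-response summary dataset from a published
interferon-tau dose study in Zucker diabetic fatty rats (doses 0/4/8
µg/kg/day, n = 6, mean ± SEM) together with its published letter
partitions. Re-analysis from the printed summaries reproduces all 11
partitions under SNK, Duncan, and unadjusted LSD. Tukey-Kramer reproduces
9 of 11: for total cholesterol (q = 3.45) and free fatty acids (q ≈ 3.55)
the widest-span q falls just short of q₀.₀₅(3, 15) = 3.67, giving the
overlapping a/ab/b display — the expected behaviour of a more conservative
test near the boundary, compounded by reconstruction from rounded SEMs.
The packaged pooled-SEM figures of the study's compact-format table were
evidently computed from unpublished raw data and do not all equal
$\sqrt{MSE/n}$ from the rounded SEMs; rendered pooled SEMs follow the
formula.

Problem sizes used by the verification suite: exhaustive letter-display
checks to k = 4 plus 1,000 random relations at k ∈ {5,6,7}; 100 random
instances for the k = 2 t-test identity; 1,000 random vectors for the
adjustment oracles; 200 random balanced rows for the rejection-set
nesting; 500 simulated null datasets (k = 3, n = 10) for the α-calibration
check, which expects the 0.05-level rejection rate within ±0.02.

## Known limitations

Single-factor designs only: no factorial or repeated-measures ANOVA, no
Welch correction, and no normality or homoscedasticity diagnostics — the
package computes under the model's assumptions and leaves checking them to
the analyst. The post-hoc menu is the four tests above plus
Bonferroni/Holm for LSD; Scheffé, Dunnett, and FDR-type adjustments are
out of scope, as are general contrasts. Output is RTF (plus text
mirrors), not DOCX; transposing the table is left to the word processor.
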