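# aovtab

Publication-ready one-way ANOVA tables with post-hoc letter displays, in R.

Life-science papers report treatment effects in tables of the form
"mean ± SEM" per group, with superscript letters marking significance:
groups that share a letter are *not* significantly different at the chosen
level. Building such a table means chaining a one-way ANOVA per response
variable, an all-pairwise multiple comparison procedure, a letter
assignment, and typesetting. `aovtab` automates the whole chain — and works
from **summary statistics alone** (per-group n, mean, SD or SEM), so a
table in a submitted or published paper can be re-checked without the raw
data.

## What it computes

For k groups with sizes $n_i$, means $m_i$, SDs $s_i$
($s_i = \mathrm{SEM}_i\sqrt{n_i}$ when SEMs are given), the fixed-effects
decomposition

$$SS_B = \sum n_i (m_i - \bar y)^2,\quad SS_W = \sum (n_i-1)s_i^2,\quad
F = \frac{SS_B/(k-1)}{SS_W/(N-k)}$$

with the p-value from $F(k-1, N-k)$; then one of four all-pairwise
procedures on the pooled $MSE = SS_W/(N-k)$:

| test | kind | error control |
|---|---|---|
| Fisher LSD (`lsd_test`) | pairwise t, optional Bonferroni/Holm | weak FWER (strong at k = 3) |
| Tukey-Kramer (`tukey_kramer`) | single-step studentized range | strong FWER |
| SNK (`snk_test`) | stepwise range, span-r critical values | weak FWER |
| Duncan (`duncan_test`) | SNK with protection level $1-(1-\alpha)^{r-1}$ | weak FWER |

The pairwise decisions become letters via the insert-and-absorb algorithm
(`insert_absorb`), and `build_table` + `write_rtf` render the result as an
RTF table (per-group-SEM or pooled-SEM format) that opens directly in
Microsoft Word, with TSV/Markdown mirrors for diffing.

## Worked example

The packaged reference dataset (`table1_data()`) holds an 11-response
summary table from an interferon-tau dose study in Zucker diabetic fatty
rats — doses 0/4/8 µg/kg/day, n = 6 per group, mean ± SEM — plus the
letter partitions as published.

```r
library(aovtab)
t1 <- table1_data()

anova_from_summary(t1$summaries$Arginine)
#> One-way ANOVA: F(2, 15) = 17.545, p = 0.0001182
#>   MSE = 154, pooled SEM = 5.0662

res <- lapply(t1$summaries, analyze_response, test = "snk")
tab <- build_table(res, mode = "per_group_sem", alpha = 0.05, test_name = "SNK")
tab
#> Variable | 0 | 4 | 8
#> Arginine | 110 ± 4 b | 115 ± 5 b | 149 ± 6 a
#> Valine | 219 ± 9 a | 201 ± 7 a | 172 ± 6 b
#> ...
#> Insulin | 307 ± 10 | 294 ± 11 | 301 ± 7
#> ...
#> Values are the means ± SEM. Means in a row without a common superscript
#> letter differ (P < 0.05), as analyzed by one-way ANOVA with the SNK test.
write_rtf(tab, "table1.rtf")
```

The arginine row reads: mean arginine rose from 110 µM (dose 0) to 149 µM
(dose 8); the two lower doses share letter "b", so they do not differ, while
dose 8 carries "a" — significantly different from both at α = 0.05. The
insulin row has no letters: its omnibus p (0.63) shows no significant
differences anywhere. Re-analysis from the printed summaries reproduces all
11 published letter partitions under SNK, Duncan, and unadjusted LSD;
Tukey-Kramer, being more conservative, reproduces 9 (cholesterol and free
fatty acids land just short of the q critical value and get a/ab/b).

Whole workbooks go through one call — for raw data
(`scenario = "S1"`/`"S2"`) or summary sheets (`"S3"`/`"S4"`, sample sizes
supplied as `"15"` or `"15 14 15 16"`):

```r
run_tables("mydata.xlsx", scenario = "S1", factor_name = "group",
           test = "snk", alpha = 0.05, output_dir = "out")
```

or from the shell via the thin CLI wrapper:

```sh
Rscript inst/cli/aovtab.R --input mydata.xlsx --scenario S1 \
    --factor group --test snk --out out/
```

One RTF (plus TSV mirror) is written per dataset/sheet.
`make_raw_workbook()` / `make_summary_workbook()` generate seeded synthetic
workbooks for experimentation and testing.

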