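---
title: "Disproportionality signal detection for spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signalkit)
library(data.table)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect unsolicited reports of suspected drug
reactions. They have no denominator — nobody knows how many patients took a
drug without incident — so absolute risks cannot be estimated. What can be
estimated is *disproportionality*: whether a given adverse-event term is
reported more often with a drug of interest than its share of the rest of the
database would predict. signalkit implements the standard workflow around
that idea for FAERS-style quarterly extracts: case cleaning, restriction to a
drug/indication cohort, descriptive epidemiology, three disproportionality
algorithms with their published decision rules, and a downstream
network-toxicology stage that connects flagged organ classes to candidate
molecular targets.

The package was built around the safety question posed by two recent classes
of myasthenia gravis (MG) biologics — complement C5 inhibitors (eculizumab,
ravulizumab, zilucoplan) and neonatal Fc receptor (FcRn) inhibitors
(efgartigimod, rozanolixizumab) — and ships a dictionary for those five
drugs, but every stage is generic and configuration-driven.

## Data model and case cleaning

A FAERS quarter is seven `$`-delimited tables (DEMO, DRUG, REAC, INDI, THER,
OUTC, RPSR) keyed by PRIMARYID (report version) and CASEID (case). The
reader stores fields verbatim; text normalization (case folding, whitespace
collapse) happens only at matching time. Malformed lines with *more* fields
than the header are rejected and counted rather than repaired: an embedded
`$` would silently shift every later column, and a loud count is auditable
where a heuristic merge is not. Child-table records whose PRIMARYID lacks a
DEMO row are kept and counted as orphans; nothing is silently dropped.

FAERS dates come at day, month, or year precision (`YYYYMMDD`, `YYYYMM`,
`YYYY`). `parse_partial_date()` is total: invalid months or impossible
calendar days yield a counted missing value, never an error. For
deduplication ordering, partial dates are compared on a zero-filled
`year*10000 + month*100 + day` key, which reads lower-precision dates as
older — a conservative choice the data layout itself cannot resolve.

Deduplication keeps, per CASEID, the report version with the latest FDA
receipt date, breaking ties by the highest PRIMARYID. The rule is
deterministic and order-invariant, and the test suite asserts idempotence
and permutation invariance.

Cohort restriction assigns a report to target drug $D$ when a
primary-suspect (PS) drug row matches $D$'s synonym set exactly (generic or
brand, on normalized strings — substring matching is deliberately avoided so
that e.g. biosimilar names do not leak in), an indication row linked to that
drug row via its sequence number carries one of the configured MG terms, and
the report arrived on or after $D$'s approval date. Whether the indication
must be linked to the suspect drug or may appear anywhere in the report is
ambiguous in the source workflows; both modes are implemented
(`indication_mode`), with *linked* as the default because the INDI table is
keyed to drug sequences. Reports whose PS drugs match two target
dictionaries are counted as ambiguous and excluded rather than
double-counted.

## Time to onset

Onset is the day difference between the earliest day-precision therapy start
of the matched suspect drug and the report's event date. Same-day pairs map
to 1 (published onset tables print a minimum of 1, so day zero and day one
are not distinguishable), and negative differences — data errors — are
counted missing. Onset summaries therefore describe only the minority of
reports that carry both dates at day precision; the characteristic tables
keep a `NOT_SPECIFIED` bin so the denominator stays the full cohort.

## The three algorithms

All three operate on the 2×2 table for a (drug, PT) pair: $a$ reports of the
target drug with the term, $b$ without it, $c$ and $d$ likewise for the
comparator, $N = a+b+c+d$.

**Reporting odds ratio.**
$\mathrm{ROR} = ad/bc$ with the log-symmetric Wald interval
$\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$.
Signal when $a \ge 3$ and the lower bound exceeds 1.

**MHRA method.**
$\mathrm{PRR} = [a/(a+b)]\,/\,[c/(c+d)]$ together with the Pearson statistic
$\chi^2 = N(ad-bc)^2/[(a+b)(c+d)(a+c)(b+d)]$, *without* continuity
correction. Signal when $a \ge 3$, $\mathrm{PRR} \ge 2$ and $\chi^2 \ge 4$.
The no-correction convention is not cosmetic: recovering the integer table
behind a fully printed published row from three of its statistics and
recomputing the fourth reproduces the printed value only without Yates'
correction (see `recover_contingency()` and the acceptance tests); a
Yates variant remains available by configuration.

**BCPNN information component.**
$\mathrm{IC} = \log_2 \, p_{11}/(p_{1\cdot}p_{\cdot 1})$ under independent
Beta priors on the two margins ($\alpha_1=\beta_1=1$, $\alpha=\beta=2$) and
a joint-cell prior ($\gamma_{11}=1$, with $\gamma$ tied to the margins so
the prior IC is centred at zero). `bcpnn_stats()` returns the *exact*
posterior mean and variance of IC — digamma/trigamma closed forms of the
three Beta posteriors — rather than the classical plug-in approximation
that takes the log of posterior means. The two differ by roughly
$1/(2a\ln 2)$ bits, irrelevant for $a \gtrsim 20$ but visible for small
cells; the exact form is what a Monte-Carlo posterior converges to, which
makes the oracle comparison in the test suite sharp. The plug-in form is
kept under `method = "approx"`. In both cases
$\mathrm{IC025} = \mathrm{IC} - 2\sqrt{V(\mathrm{IC})}$, the conventional
normal-style lower credibility bound; signal when $\mathrm{IC025} > 0$.
Because this bound is mean-minus-two-SD rather than an exact quantile, it
drifts from the true 2.5th posterior percentile once $a \lesssim 5$, where
the log-Beta posterior is visibly skewed — a property of the published
convention, and the reason the oracle-equivalence tests use tables with
$a \ge 6$.

A pair is a *positive signal* when all three rules fire; rankings, Venn
region counts, SOC rollups and subgroup reruns all operate on that
intersection, which trades sensitivity for specificity in the usual way. No
multiple-testing adjustment is applied, matching disproportionality
practice.

**Zero cells.** When $bc = 0$ the ROR/PRR are undefined; the default
suppresses the frequentist statistics for those rows (they cannot flag) and
reports them, because continuity corrections can fabricate signals from
single-report terms. A Haldane +0.5 option exists for sensitivity analyses.
The BCPNN is always computed — its priors regularize zeros.

**Comparator.** The comparator population is configurable: all other
reports in the loaded window (classical, the default), the other target
drugs' reports, or a user-supplied set. Published row statistics can imply
surprisingly small $c$ cells, suggesting some analyses use restricted
backgrounds; since the choice cannot be recovered with certainty, it is a
config option rather than a guess baked into the code.

## Recovering published tables

`recover_contingency()` solves for the integer $b, c, d$ behind a published
row given $a$ and three of {ROR, PRR, CI-implied standard error, $\chi^2$},
by continuous least squares on the log scale from a grid of starts followed
by exhaustive integer refinement near the optimum. Recomputing the withheld
fourth statistic from the recovered table is a strong end-to-end consistency
check of all closed forms at once, and is what the acceptance script
reports.

## The synthetic report generator

`simulate_faers()` emits the seven tables with known ground truth. Each
report draws every vocabulary PT independently with probability
$\text{baseline} \times \mathrm{RR}(\text{drug}, \text{pt})$, so a planted
pair's true relative reporting rate is exactly its configured RR; reports
whose draws all miss receive the disease-progression fallback term (itself a
common spontaneous-report PT), whose realized frequency therefore exceeds
its baseline and which is excluded from moment checks. Duplicates are
re-emissions of a case with a new PRIMARYID and later FDA_DT, so the dedup
rule provably recovers the unique-case count. Therapy-start and event dates
realize a log-normal onset (median 25 days, matching the 2–5 week medians
typical of these cohorts) for a configurable fraction of reports, with a
further fraction degraded to month precision to exercise partial-date
handling.

The defaults are the package's study conditions: per-drug unique-case
counts at the published cohort sizes (5276 / 3031 / 221 / 2446 / 370), a
background bringing the window to ~5×10⁴ reports, 10% duplicate versions,
three pairs planted at RR = 8 with baselines chosen so the expected $a$ cell
is near 40, and Table-1-like missingness. What the generator does *not*
emulate: free-text drug-name noise (misspellings), correlated PT
co-occurrence, reporting-rate drift over calendar time, and
indication-dependent event profiles. Passing the operating-characteristic
tests therefore shows the algorithms behave correctly under the assumed
sampling model, not that real-database signal lists are reproduced — those
depend on the full database and are out of desk-scale reach by design.

Every random quantity flows from one seed through per-stage derived
streams, so outputs are byte-identical for a fixed seed and extending one
stage leaves the others' draws untouched.

## Network-toxicology stage

The downstream stage is deliberately file-based: drug-target and organ-class
gene lists, a PPI edge list (with STRING-style confidence scores, kept at
≥ 0.4 by default), and GMT annotation collections are inputs, because the
live services are unversioned and irreproducible. Key nodes are the top-k
(default 5) degrees of the subgraph induced on the intersection targets —
degree only, other centralities being out of scope. Enrichment is the
upper-tail hypergeometric $P(X \ge k)$ with Benjamini–Hochberg adjustment
within each category tag, against a DAVID-like universe (all genes in the
annotation collection) unless overridden. Ties and orderings everywhere
break lexicographically so outputs are byte-stable.

## Numerical and scale choices

* Percentages print at two decimals with half-up rounding; quartiles use
  linear interpolation between order statistics (quantile type 7). Published
  tables rarely state either convention, so exact quartile comparisons are
  not treated as decisive.
* Age unit codes convert as YR×1, DEC×10, MON÷12, WK÷52.18, DY÷365.25;
  ages above 120 years are treated as data errors. Weights convert LBS→kg by
  0.45359237.
* Contingency cells are coerced to double before products — $N(ad-bc)^2$
  overflows 32-bit integers already at modest database sizes.
* The operating-characteristic suite runs 200 seeded replicates of the
  ~5×10⁴-report default window (a few minutes on one core); unit tests use
  windows of 10³–10⁴ reports. Oracle comparisons use 10⁵ Monte-Carlo draws
  per table and exhaustive enumeration for hypergeometric universes up to
  N = 25.

## Known limitations

Disproportionality quantifies reporting association, not causation; the
package computes the statistics and their decision rules but interpretation
requires clinical context. The dedup rule cannot merge duplicates filed
under different CASEIDs (probabilistic record linkage is a non-goal). The
MedDRA hierarchy is licensed, so PT→SOC mapping relies on a user-supplied
table with an explicit `UNMAPPED_SOC` sentinel. Pre-2012 LAERS layouts and
FAERS XML are unsupported.
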