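---
title: "Deriving lines of therapy from patient-forum text: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving lines of therapy from patient-forum text: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forumlot)
```

## The problem

Treatment-pattern studies ask what fraction of patients received which
regimen at first, second, and third line. The usual sources — oncology EMR
extracts and administrative claims — are expensive and slow to access.
Patient forums are an alternative: posters describe, in free text, which
drugs they started and roughly when. `forumlot` implements the full chain
from raw posts to per-line regimen proportions with 95% confidence
intervals, plus a matched-cohort comparison against EMR/claims-style tables,
and a synthetic-data generator that stands in for the (non-redistributable)
scraped forums and proprietary databases.

The package's validation logic is benchmarked against a published melanoma
study that ran this design at scale across four US patient forums and four
databases (Flatiron, McKesson, MarketScan, PharMetrics+); its printed
per-line estimates, denominators, year distributions and concordance
annotations are bundled as `reference_estimates()` and friends, and the
test suite recomputes them from first principles.

## Pipeline model and assumptions

**Unit of analysis.** One forum account = one patient (`make_user_id()`
hashes username + forum). The pipeline classifies *sentences*, not whole
posts: negation and temporal scope are sentence-local, and a single post
often mixes receipt statements with chatter.

**Mention detection.** Whole-token matching over a curated lexicon
(generic + brand names + abbreviations), with a bounded fuzzy pass: tokens
of length ≥ 6 match at Levenshtein distance exactly 1 when the nearest
canonical is unique. The length gate prevents three-letter abbreviations
("ipi") from fuzzy-firing; distance 1 covers the dominant class of forum
typos ("temozolamide"). The bundled lexicon is a reconstruction from
NCCN-era melanoma systemic therapies; it is a package data file
(`inst/extdata/melanoma_lexicon.csv`) and can be replaced wholesale.

**Receipt classification.** TF-IDF unigrams, with the smoothed-idf dialect
`idf(t) = ln((1+N)/(1+df(t))) + 1` and L2-normalized rows, fitted on the
training fold only. Three classical models are compared — linear-kernel
SVM, multinomial naive Bayes (written in-package: the naive Bayes
implementations available to us model numeric features as Gaussians, which
is the wrong likelihood for term weights), and KNN with K = 5. Model
selection maximizes precision + recall with ties broken by precision, then
a fixed model order. When class imbalance exceeds 60/40 the majority class
is downsampled before fitting.

**Negation and time.** Negation is a NegEx-style rule: a cue ("not",
"never", "refused", ...) within the five tokens preceding the mention, with
scope cut by "but"/"however"/"although". Temporal resolution is total — it
always returns a date and a rule tag: explicit month expressions ("in March
2014", "3/2014") resolve to day 15 of that month; relative expressions
("three months ago", "last year", number words one–twelve) subtract from
the post date; otherwise the post date itself is used. Mentions dated more
than 30 days after their post are treated as intent, not receipt, and
excluded. The three gates (classifier verdict, negation, future-dating) are
conjunctive, so their order cannot change the result.

**Lines of therapy.** Events are deduplicated at (drug, calendar month)
granularity and folded into lines with six rules: a first non-adjuvant
event opens line 1; a drug first seen within `combo_window_days` (default
28, the common claims-analytics convention, exposed as a parameter) of the
line start joins the regimen; a new drug after the window opens the next
line; re-mentions never advance lines; interferon or docetaxel alone never
form a line (adjuvant use), but do count inside combinations. The
implementation anchors lines on non-adjuvant events and then attaches
adjuvant events falling inside `[start, start + window]`; on any timeline
with a non-adjuvant anchor this is equivalent to applying the rules
chronologically, and it makes the monotherapy-exclusion rule explicit.
Drug *stops* are deliberately not modelled: forums report starts far more
reliably than discontinuations, so only a new non-regimen drug closes a
line.

**Matching and concordance.** Comparator patients are frequency-matched on
first-line initiation year at ratio 4 (per year,
`min(pool, 4 × social-media count)`, uniform within year, seeded);
social-media patients in years with an empty pool are reported dropped.
Proportions use the denominator "patients with ≥ that line" and Wald
intervals `p̂ ± 1.96·√(p̂(1−p̂)/n)`, reported in percent to one decimal. The
Wald form is not an arbitrary choice: the bundled reference estimates
include cells (e.g. a third-line 1.4% ± 2.7%) whose lower bound is
negative, which Wilson or Clopper–Pearson intervals cannot produce. Two
estimates are concordant when their *reported* (rounded) intervals
intersect, as closed intervals — the reference annotation contains a pair
of intervals that touch exactly at one endpoint and are marked concordant,
which fixes both conventions.

One caveat surfaced by recomputation: in the bundled reference annotation,
nine database cells at second and third line are marked non-concordant even
though their printed intervals intersect; every cell marked concordant does
recompute as overlapping, and every treatment × line row overlaps at least
one database either way. The package reports what the arithmetic gives; the
test suite records the discrepancy rather than reproducing the annotation
by special-casing.

## The synthetic cohort generator

`sim_config()` defaults *are* the emulated study conditions, fixed once:

* first-line year distribution 2011–2017 = (40, 96, 140, 180, 127, 127,
  107)/817, the published social-media cohort;
* P(second line) = 226/817, P(third | second) = 73/226;
* year- and line-specific regimen distributions reflecting treatment eras
  (chemotherapy/ipilimumab/vemurafenib before 2014, PD-1 inhibitors from
  2014, combination immunotherapy and BRAF/MEK doublets from 2015) —
  conventions, not estimates, since no source characterizes them;
* comparator pools mirroring the published per-database year tables.

Journeys are rendered as posts with a single noise dial (default 0.1)
controlling typo, negated-decoy, future-intent, hearsay and off-topic
rates; brand names appear at rate 0.3, relative-vs-absolute date phrasing
at 0.5. Post dates lag events by 0–90 days and relative expressions are
generated consistently with that lag, so the temporal resolver has
nontrivial but solvable work; truth is month-granular (day = 15) because
forum language rarely carries day precision. Combination regimens are
always mentioned within one sentence, so their drugs share a date;
consecutive truth regimens are drawn drug-disjoint from the immediately
preceding line, because under the line rules a continuation or re-challenge
of a current drug is textually indistinguishable from staying on it.
Sentences are composed from fixed, versioned template material in which the
classes share most of their vocabulary (the same receipt verbs, drugs and
temporal phrases appear in receipt, hearsay and intent sentences) and
differ in short cue words; a shared pool of circumstantial clauses is
appended at a fixed rate. This is what gives the classifiers a realistic
difficulty gradient instead of a trivially separable corpus.

What the generator does **not** emulate: thread structure and replies,
multiple users describing one patient, post-length and posting-frequency
distributions (uncharacterized in any source — the per-line posting model
is a convention), sarcasm, and demographic signals. Passing tests therefore
show that the *pipeline logic* is correct under controlled noise, not that
the trained classifier would transfer to live forum text.

## Numerical choices and degenerate inputs

* Seeds: every stochastic stage derives its own 31-bit stream from the
  master seed and a stage label (FNV-1a), so stages rerun independently and
  reruns are byte-identical.
* Text cleaning keeps the whitelist letters/digits/space/`. , ! ? ' - /`
  (sentence terminators survive for the splitter); cleaning is idempotent;
  unparseable post dates are an error, never a silent drop; identical
  (user, date, text) posts are deduplicated.
* Same-date treatment events are ordered alphabetically by drug for
  determinism; empty timelines produce zero lines; a zero denominator in a
  proportion table is an error; undefined precision/recall are `NA`, never
  zero; `line_counts()` of an empty cohort reports counts of 0 and absent
  percentages.
* Interval overlap uses a 1e-9 slack so touching endpoints survive floating
  point.

## Problem sizes used by the test suite

The packaged tests run the classifier comparison on three corpora of
≈ 5,500 labeled sentences (1,700 simulated patients each, noise 0.1) and
the end-to-end recovery on 20 seeds × 1,000 patients at noise 0.1 plus one
zero-noise run of 300 patients; unit and property tests use corpora of
25–400 patients. These sizes give stable metrics (SVM precision/recall
vary by well under three points across seeds at this scale) while keeping a
full run of the suite in the tens of minutes on one core.

## Known limitations

* The negation window is symmetric with the generator's cue grammar;
  post-mention negation ("...{drug}, which I declined") is not detected and
  is left to the classifier.
* Temporal resolution handles one expression per sentence and no
  cross-sentence ordering ("before that, I was on...").
* The line algorithm cannot see re-challenge with a drug from the
  immediately preceding regimen, and gap-based line splitting is impossible
  without dosing dates.
* Real scraped text is far messier than the template language; the
  classifier metrics reported on synthetic corpora characterize the
  pipeline, not expected field performance.
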