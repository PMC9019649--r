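---
title: "Measuring societal age stereotypes from year-stamped corpora: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring societal age stereotypes from year-stamped corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestereo)
```

## The problem

News text encodes how a society portrays its older adults. When a large,
well-publicised aging policy arrives — a health-care subsidy scheme
announced at a national address and rolled out the following year — that
portrayal can shift, and not necessarily in the intended direction: media
coverage that frames older adults primarily through clinics, subsidies and
chronic illness can *medicalize* aging and drag overall sentiment down.

`agestereo` operationalises this question as a measurement-plus-inference
pipeline on any year-stamped document corpus:

1. **Measurement.** For a node noun denoting older adults (by default
   *elderly*, the dominant choice in Singapore English news), collect its
   collocates under a windowed span rule, keep those whose association with
   the node clears a pointwise-mutual-information bar and that human raters
   marked as genuinely about an old person, and average the raters' 1–5
   sentiment over each year's collocate set. That annual mean is the
   **Societal Age Stereotype (SAS) score**. The same collocate sets, scored
   with binary "is this word about physical health?" flags, give an annual
   **medicalization score** in [0, 1].
2. **Inference.** On the resulting annual panel — SAS, medicalization, a
   pre/post policy indicator, and the old-age support ratio (working-age
   adults aged 20–64 per person 65+) — fit polynomial trends, a
   single-mediator path model (policy → medicalization → SAS), and a
   first-stage moderated mediation in which the policy→medicalization path
   varies with the support ratio. Indirect-effect inference uses the
   percentile bootstrap.

Human ratings enter only as files (a TSV lexicon with one sentiment and one
medical column per rater); the package deliberately contains no automatic
sentiment model, mirroring the rating design it implements.

## The span rule, precisely

The collocation window is where most hidden degrees of freedom live, so the
package fixes one literal reading and tests it against a naive oracle:

* The window extends `span` (default 6) *consumed positions* to each side
  of a node occurrence and never crosses a sentence boundary. A node that
  opens a sentence takes nothing from the previous sentence.
* **Articles** (*a, an, the*) never consume a position and are never
  collocates.
* **Other stop words** (prepositions, conjunctions, pronouns, auxiliaries —
  the shipped list; user-overridable) consume a position but are not
  emitted, reflecting a pipeline in which stop words were "excluded" by
  preprocessing yet still occupy linear positions. Setting
  `stopword_policy = "skip"` makes them behave like articles instead; both
  behaviours are unit-tested.
* Node words are never their own collocates (they consume a position).
* A token instance that falls inside the windows of two nearby node
  occurrences is counted **once**. This set-of-positions semantics keeps
  the invariant `F_near(y, w) <= F_colloc(y, w)` — co-occurrence can never
  exceed corpus frequency — which pair-enumeration counting would violate
  whenever node windows overlap.

Tokenization is rule-based and deterministic: sentences split on `.?!` +
whitespace, lowercasing, punctuation stripped, possessive *'s* removed,
hyphenated tokens kept whole, no abbreviation handling (the corpora the
tests run on are synthetic or fixtures, where this cannot bite). Stop words
are *flagged, not deleted*, so the span rule above is decidable from the
token stream alone.

## Association score

The retention score is the span-adjusted pointwise MI used by the large
web-corpus query interfaces:

$$\mathrm{MI} = \log_2 \frac{F_{near} \cdot N}{F_{node} \cdot F_{colloc} \cdot S},
\qquad S = 2 \cdot \mathrm{span},$$

in bits: 0 means the collocate appears near the node exactly as often as
its overall corpus rate predicts; each extra bit doubles that ratio.
Retention is inclusive at the default threshold 1.5 ("1.5 and above").
Scores are computed per year by default, because annual scores are the
analysis unit; a pooled mode exists. Words that clear the bar but have no
lexicon entry are routed to a *needs-rating* report rather than silently
dropped, so the rating workflow can iterate.

Whether corpus size $N$ (and $F_{colloc}$'s reference population) should
count stop words is genuinely underdetermined; the counts object carries
both totals (`n_tokens`, `n_content`) and `mutual_information()` takes a
`denominator` argument. The default is all tokens.

Years with no node occurrence propagate as missing SAS with a warning,
never as a silent zero.

## Scoring choices

* **Weighting.** "Mean ratings per year" is ambiguous between type-level
  (each retained collocate counts once; the default) and token-level
  (weighted by in-span frequency `F_near`). Both are implemented and one
  test pins the case where they differ.
* **Medicalization as a proportion.** The annual medicalization score is
  the mean per-word medical value over the retained set, i.e. a proportion
  in [0, 1] rather than a count — scale-free across years whose collocate
  yields differ.
* **Rater disagreement** on a binary medical flag contributes 0.5
  (unbiased under rater symmetry); sentiment is the plain mean of the 1–5
  ratings.
* **Reliability.** Cronbach's alpha treats raters as parallel measurements
  (`alpha = K/(K-1) (1 - \sum_j var_j / var_{total})`), with a Feldt
  F-distribution confidence interval (`(n-1)` and `(n-1)(K-1)` degrees of
  freedom); the CI method had to be chosen, since reported alphas of this
  kind rarely name one. Zero total variance is reported as undefined, not
  as 1.
* **Policy coding** is a binary step at `policy_year` (announcement late in
  year *t−1*, implementation and sustained coverage from year *t*). This is
  the only coding implemented; a years-since-policy coding would be a
  reasonable extension but is currently out of scope.

## Trend and path models

Polynomial trends are ordinary least squares on centered year powers
$(year - \overline{year})^k$, fitted jointly; the reported trend
coefficient is the highest-order term, with t inference on
$n - degree - 1$ df. Centering makes coefficients invariant to the year
origin (tested), but note that a quadratic "trend β" is still
coding-dependent across conventions (raw vs orthogonal polynomials), which
is why no cross-study numeric comparison is built on it. With eight annual
points there is no autocorrelation correction — a documented limitation,
not an oversight.

The mediation model is three OLS equations on the same sample
($Y \sim X$; $M \sim X$; $Y \sim X + M$), so the decomposition
$c = c' + a b$ holds to machine precision and is asserted everywhere. The
moderated model adds the first-stage interaction
$M = i_1 + a_1 X + a_2 W + a_3 XW$ with $W$ mean-centered by default —
centered $a_1$ is the effect at the observed moderator mean and the
small-sample fit is better conditioned. Raw-variable coding (matching
conventions that produce large raw-scale interaction coefficients) is one
switch away (`center_w = FALSE`); the two codings agree exactly on every
conditional effect, and a test says so. Conditional indirect effects are
$(a_1 + a_3 w) b$ at $w \in \{-SD, 0, +SD\}$; the index of moderated
mediation is $a_3 b$, the slope of the conditional indirect effect in $w$.
Only the first stage is moderated: that is the model of interest here, and
second-stage or direct-path moderation options are deliberately not
exposed.

**Bootstrap.** Percentile, not bias-corrected: resample rows with
replacement, refit, take empirical quantiles of $a b$ (or $a_3 b$).
Defaults: $B = 5000$, mandatory seed, identical seeds give bit-identical
intervals, and the caller's RNG stream is restored afterwards. Degenerate
resamples (constant exposure or collinear columns — a real possibility
with $n = 8$ and a binary exposure) are redrawn and counted, not silently
propagated. Runs with $n < 20$ emit an explicit small-sample caution
rather than refusing: the method is defined, its fragility is the user's
to weigh. Percentile intervals in tiny samples may not even contain the
point estimate; tests assert only `ci[1] <= ci[2]`.

## What the synthetic worlds do and do not emulate

Two generators make every stage testable without licensed corpora.

**Score-level panels** (`generate_panel()`) draw directly from the
structural model the path analysis estimates: step exposure, linearly
declining support ratio (7.4 → 5.1 across the default 8 years — the
published endpoints; intermediate years are interpolation, and the
packaged covariate file is named `*_synthetic.tsv` for that reason),
Gaussian noise. Default coefficients encode the qualitative story: the
policy raises the medical share of collocates by 4–7 percentage points,
more strongly at lower support ratios ($a_1 = 0.225$, $a_3 = -0.03$ on the
raw support-ratio scale), the mediator depresses sentiment ($b = -2$ per
unit proportion), and there is no direct effect ($c' = 0$). Noise SDs
(0.005, 0.01) are small because each annual score averages hundreds of
word ratings. Panels from this generator live on the model's own scale and
skip the [1,5]/[0,1] range validation that measured panels must pass.

**Document-level corpora** (`generate_corpus()`) are streams of Zipf
background tokens, articles and stop words at fixed rates, with node
occurrences planted at 8 per 1,000 tokens (expected 30 per year — enough
for stable MI) and window slots near each node overwritten by vocabulary
words sampled proportionally to association strength. From the policy year
on, medical words' strengths are multiplied by `medical_boost` (default
3). Because planted words occur *only* in windows (which is what makes
"strength 0 ⇒ never occurs" exactly true), their corpus frequency equals
their co-occurrence count and their MI is set by corpus scale rather than
by strength; chance-level behaviour — window rate equal to corpus rate, MI
≈ 0 — belongs to the frequent background words instead, and that is how
the threshold-separation test is built. Two consequences worth stating
plainly:

* the generator plants a *frequency* shift within a fixed vocabulary, not
  a change in the type inventory, so the planted signal is carried by
  token-weighted scores; the end-to-end recovery test runs the pipeline
  with `weighting = "token"` while type weighting stays the default for
  real corpora;
* there is no grammar, register, named entities, or topic drift — windows
  and counts drive every downstream statistic, and that is all the
  generator claims to emulate. A green end-to-end test establishes that
  the pipeline recovers planted co-occurrence structure and effect signs,
  not that it would reproduce any particular published coefficient from
  real news text.

## Numerical and degenerate-input policy

* OLS via QR; rank deficiency is a hard error naming the collinear
  columns.
* MI never emits `-Inf`: zero co-occurrence is absence; `F_colloc = 0`
  with `F_near > 0` is an internal inconsistency and a hard error.
* Threshold comparisons are inclusive; quantiles are R's default type 7.
* Empty documents tokenize to zero sentences (not an error); empty corpora
  give empty counts; a single-year panel is valid but trend and mediation
  refuse it with an error stating their minimum n.
* All randomness (generators, bootstraps) is seeded through a
  save-and-restore wrapper, so library calls never perturb the caller's
  RNG stream.

## Known limitations

* Sentence splitting does not special-case abbreviations; on real news
  text this slightly over-segments, tightening windows.
* Node matching is exact (`"elderly"`); inflections or multiword variants
  must be supplied explicitly.
* No association measures besides MI; no dependency parsing; no
  lemmatization; no changepoint detection; no autocorrelation-robust
  trend errors at n = 8.
* The mediation identity and bootstrap are exact for the single-mediator
  linear model only; nothing here generalises to multiple mediators or
  latent variables.
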