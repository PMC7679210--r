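---
title: "Topic modeling of referral letters: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic modeling of referral letters: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Referral letters for knee and hip pain carry the information on which
triage decisions are made, but they are short, idiosyncratic clinical
narratives. `lettertopics` treats a corpus of such letters as a mixture
of latent topics: each letter $d$ draws a topic distribution
$\theta_d \sim \mathrm{Dir}(\alpha)$, and each token is emitted from a
topic-specific word distribution $\phi_k \sim \mathrm{Dir}(\beta)$. Two
empirical questions follow. Do $\theta_d$ vectors predict the treatment
the patient eventually received? And are the $\phi_k$ readable by
clinicians as patient cohorts? The package implements the full chain —
text regularization, semantic enrichment, LDA, coherence-guided model
selection, treatment classification, and the inter-rater agreement
arithmetic of the interpretability protocol — together with a synthetic
corpus generator that makes all of it testable without confidential
data.

## Linguistic processing

Regularization applies, in order: honorific-based personal-name masking
(before lowercasing, because capitalization is the cue), lowercasing,
enclitic expansion from a fixed shipped table, variant/abbreviation
replacement (longest key first, whole-word), and punctuation
normalization that keeps `.`/`!`/`?` as free-standing sentence marks
(the sentence segmentation is later reused for sentence-sized virtual
documents in coherence). The operation is idempotent, which the test
suite asserts on 200 generated letters.

Name masking is deliberately *not* general-purpose NER: many clinically
meaningful terms are eponymous (Baker cyst, McMurray test, Hoffa fat
pad), and an overzealous recognizer would strip them. Instead, two
trigger families drive the masking: an editable honorific list (Dr, Mr,
Mrs, Ms, Miss, Prof, Sister, ...) followed by up to four capitalized
words, and patient-pattern phrases ("Thank you for seeing ...")
followed by a capitalized full name. The mask surface is a single
reserved alphabetic token (`zzperson`) excluded from the topic-model
vocabulary by default, so masked names can never become topic
descriptors.

Tokenization removes a standard English stop-word list from which the
clinical negation cues "no" and "not" have been deliberately excluded —
negation is clinically meaningful. Both a full Porter (1980) stemmer
(implemented in-package and tested against canonical reference outputs)
and a rule-plus-exception-table lemmatizer are available, so experiments
can switch freely between stemming and lemmatization.

## Semantic enrichment

Concept recognition is a self-contained dictionary matcher, not a
wrapper around an external terminology server. A lexicon row is (term,
concept id, semantic type); a concept id owns many terms, which is how
synonymy ("painkiller"/"analgesic" → one identifier) is represented.
Matching is order-insensitive and derivation-tolerant: inside a sliding
window (default 8 tokens, which must be at least the longest lexicon
term), an entry matches a contiguous sub-span when the entry's Porter
stem multiset is contained in the sub-span's stem multiset — this is
what conflates "meniscus tear" with "tear of meniscus". The tightest
span per candidate is kept; the longest match wins ("ligament tear"
beats "tear"), ties break leftmost then by smallest concept id, and
accepted matches never overlap. Acronyms are intentionally *not*
matched here: they are the least reliable form of variation and are
handled upstream by the curated variant lexicon.

Annotation appends a concept token (the lowercased identifier) and/or a
semantic-type token at the match position, giving the four feature
variants D1 (words only — the identity), D2 (+concepts), D3
(+semantic types), D4 (+both). Concept tokens accompany rather than
replace the matched words; the published markup examples show inline
annotation and do not settle the question, so accompaniment was chosen
as the less destructive option and is configurable via the variant
flags. Concept and semtype surfaces are lowercased identifiers, so they
cannot collide with word tokens.

The bag of words drops terms in fewer than `min_df` documents *and*
terms in more than `max_df = 0.5` of documents. The ceiling is not in
the original design but is standard practice (cf. Gensim's
`filter_extremes`): corpus-wide formulaic boilerplate — greeting and
closing salutations present in every letter — otherwise coalesces into
a coherent "formulaic" topic that consumes one of the K slots. On the
default synthetic corpus this single effect capped planted-topic
recovery at 10 of 11 topics; with the ceiling, mean matched cosine is
about 0.99.

## Topic model

Collapsed Gibbs sampling with a self-contained PCG32 generator: runs
are bit-identical given a seed and never touch R's RNG state. Defaults
are the standard collapsed-Gibbs settings $\alpha = 50/K$,
$\beta = 0.01$, 1000 sweeps with 500 burn-in, and $\hat\phi,\hat\theta$
as posterior means over 10 thinned post-burn-in samples (final-state
estimates are available). K defaults to 11, the selected topic count of
the referral-letter configuration, and is always overridable. New
documents are folded in with $\phi$ frozen; out-of-vocabulary tokens
are dropped, and a document empty after projection yields the uniform
distribution with a warning flag.

Two K-selection routes are provided. The perplexity route computes
held-out perplexity on a seeded 90/10 split and takes the elbow of the
curve (maximum second difference; a strictly linear curve is flagged
`no_elbow`). The coherence route fits one model per K per seed and
maximizes mean topic coherence. On a five-topic synthetic corpus both
routes recover K = 5.

One degenerate-case caveat, found while testing: on a corpus genuinely
generated from a *single* topic, fitting K = 2 does **not** reliably
collapse all mass onto one topic. The posterior is multi-modal — a
vocabulary-split solution, with each learned topic a sparse half of the
true distribution and every document mixing both, is
likelihood-equivalent to full collapse — and across seeds the sampler
lands in either mode. What the degenerate case does guarantee, and what
the tests assert, is that the learned mixture $\theta\phi$ reconstructs
the true word distribution in every document (observed total variation
\< 0.06).

## Coherence

All word and pair probabilities are Boolean-document relative
frequencies: a word's probability is the fraction of virtual documents
containing it, multiplicity ignored. Virtual documents are whole
documents, sentences, or sliding token windows; the defaults follow the
coherence literature — whole documents for C_UMass, sliding 10 for
C_UCI/C_NPMI, sliding 110 for the context-vector measures. The
primitives, with smoothing constant $\varepsilon = 10^{-12}$ ("small
positive", unquantified in the source, so the smallest round value that
avoids log 0):

* $\mathrm{PMI} = \log\frac{P(w_i,w_j)+\varepsilon}{P(w_i)P(w_j)}$
* $\mathrm{NPMI} = \mathrm{PMI} / \lvert\log(P(w_i,w_j)+\varepsilon)\rvert$, clipped to $[-1,1]$
* $\mathrm{LCP}(i\mid j) = \log\frac{P(w_i,w_j)+\varepsilon}{P(w_j)}$ (directed)

The absolute value in the NPMI normalizer matters only at
$P(w_i,w_j)=1$, where the raw $-\log(P+\varepsilon)$ crosses zero from
below and would flip the sign of a perfectly associated pair; the clip
absorbs $\varepsilon$-order overshoot when marginals coincide.

Aggregates over a topic's `top_n` (default 10) highest-probability
words: C_UCI, C_NPMI, C_UMass are means of the pairwise primitive
(LCP ordered so the higher-ranked word is conditioned on the
lower-ranked); C_cos is the mean pairwise cosine of NPMI context
vectors whose dimensions are the topic's own top words (the smallest
self-contained choice — the context dimension set is unstated in the
source literature's terms); C_V compares each word's context vector
with the summed vector of the whole set. All five agree with a naive
brute-force implementation to $10^{-10}$, and planted topics out-score
random word sets in ≥95 of 100 trials.

## Triage classification

The document-topic matrix X (training $\theta$ by default; re-inferred
$\theta$ optionally) is paired with nine binary treatment outcomes —
orthopedic referral, discharge, injection, nutritionist, physiotherapy,
diagnostic imaging, surgery, review appointment, any other referral;
multiple positives per letter are allowed. One binary k-NN classifier
per treatment (k = 5, Euclidean distance on the simplex; cosine and
Jensen–Shannon by flag), 10-fold cross-validation with folds
*stratified* on the treatment column: with as few as 15 positives of
576, unstratified folds would routinely contain no positives.
Accuracy is $(TP+TN)/N$ per fold. The baseline formalizes the
"stratified random classifier" as prevalence-matched Bernoulli
prediction with expected accuracy $p^2+(1-p)^2$, computed analytically
with an optional Monte-Carlo check. Ties are impossible with k = 5 and
binary votes.

## Interpretability arithmetic

Confidence is a 5-point scale (0 = not confident at all ... 4 = very
confident); similarity a 6-point scale with no zero (−3 = very
dissimilar ... 3 = very similar). For agreement, categories are treated
as consecutive ordinal ranks — the −1→1 gap of the similarity scale
collapses to adjacent ranks, and linear-weight kappa is invariant to
any affine re-indexing of ranks (tested). Weights are
$w_{ij} = 1 - |i-j|/(m-1)$; $\kappa = (P_o-P_e)/(1-P_e)$; the standard
error is the Fleiss–Cohen large-sample (non-null) variance. On the
bundled 11-topic paired-rater questionnaire this reproduces the
published agreement values exactly (0.1391 confidence, 0.7343
similarity — and, as it turns out, their standard errors and confidence
intervals too). One transcription note: the questionnaire's printed
summary reports an average confidence of 3.00 for the first rater,
while the labels themselves average 31/11 ≈ 2.82; only the recomputable
value (2.00, second rater) is used as a test target.

## The synthetic world

The generator emulates the features of referral letters the pipeline
must cope with, with defaults chosen once to mirror the study's stated
conditions: D = 500 letters (near the 576 with complete data), K = 11
planted topics, ~600 surface forms, mean length 120 tokens
(negative-binomial, dispersion 20), $\alpha_{true} = 0.1$ (letters
dominated by few themes), topic-word concentration 0.05 (well-separated
topics). Nine treatment outcomes have target prevalences 53, 173, 101,
15, 152, 112, 99, 223, 16 of 576; each outcome's probability is
$\mathrm{logit}^{-1}(b_t + w_t^\top \theta_d)$ with intercepts
calibrated by root finding to hit the targets within 0.005 — a minimal
invented mechanism that makes "topics predict treatment" true by
construction, which is precisely the hypothesis the pipeline is meant
to detect. Letters are wrapped in boilerplate with honorific-prefixed
fabricated names (recorded as ground truth), synonym-cluster emissions
surface as one of two synonyms sharing a concept id, a subset of words
sometimes surfaces abbreviated (restored by the variant lexicon), and
lowercase eponyms are sprinkled in.

What the generator does *not* emulate: clinical grammar and pragmatics
(tokens are pseudo-words sampled from syllables, constrained to be
fixed points of the stemmer and lemmatizer so identity is preserved
through preprocessing), spelling errors, negation scope, section
structure, or label noise. A green end-to-end test therefore
establishes that the machinery is correct and that the statistical
chain (topics → treatments) is detectable when present — not that the
pipeline handles real clinical prose.

## Numerical choices and degenerate inputs

* Character spans are 0-based half-open into the regularized text.
* Empty letters are rejected with a distinct `empty_letter` signal; a
  corpus emptied by filtering raises `all_empty_corpus`; all-zero BOW
  rows are excluded from fitting with a warning and listed.
* Model serialization writes matrices as `%.17g` text, which
  round-trips doubles bit-exactly.
* Weighted kappa with both raters constant and agreeing has $P_e = 1$
  and is reported as undefined (`kappa_undefined`), as is a category
  set of size < 2.
* The experiment manifest records seeds, all parameters, a corpus
  content hash, the labels, *and the exact lexica*; re-running a
  manifest reproduces every report cell bit-identically (the lexica
  turned out to be essential — without them a rerun silently used the
  shipped defaults).

## Known limitations

* The concept matcher approximates derivational variation by stem
  equality plus lexicon variant rows; true morphological analysis
  (e.g. "meniscal"/"meniscus" without a variant row) is out of scope.
* Word-sense disambiguation is approximated by the semantic-type
  whitelist plus longest-match; there is no context model.
* C_V follows the two defining properties stated for it (NPMI context
  vectors; each word against the summed set vector); segmentation
  details beyond that are under-determined in the source and other
  implementations may differ in normalization.
* Absolute coherence and accuracy values from the confidential corpus
  are not reproducible by construction; the package asserts directions,
  invariants, and the exactly recomputable agreement statistics.
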