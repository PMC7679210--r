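Package: lettertopics
Title: Topic Modeling of Clinical Referral Letters for Patient Triage
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for triaging musculoskeletal referral
    letters with topic models. Provides clinical-text regularization
    (abbreviation expansion, enclitic expansion, honorific-based masking
    of personal names that preserves clinical eponyms), dictionary-lookup
    semantic enrichment with concept and semantic-type tokens, latent
    Dirichlet allocation by collapsed Gibbs sampling with perplexity- and
    coherence-guided selection of the number of topics, per-treatment
    k-nearest-neighbour classification from document-topic distributions
    with a stratified random baseline, linearly weighted Cohen kappa for
    ordinal inter-rater agreement, and a synthetic referral-letter corpus
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
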