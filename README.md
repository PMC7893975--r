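# eshgminer

Two-stage detection of **efficacy-specific herbal groups (ESHGs)** from
Traditional Chinese Medicine prescription corpora.

A TCM prescription is a set of herbs; an ESHG is a subset of herbs that
jointly delivers a named therapeutic efficacy (e.g. a three-herb core
for "activating blood to resolve stasis"). Mining ESHGs by raw
co-occurrence is confounded by ubiquitous auxiliary herbs whose
co-occurrence support rivals the true cores. `eshgminer` addresses this
for corpus curators and TCM informatics researchers with:

1. **A hierarchical attentive neural network** classifying
   prescriptions by efficacy. For a prescription
   `P = {h_1, …, h_k}` with stacked embeddings `𝓗`:

   ```
   β  = softmax(𝓗 W₁ 𝓗ᵀ)          (row-wise herb–herb attention)
   𝓗̄  = β 𝓗
   α  = softmax(W₃ tanh(W₂ 𝓗̄ᵀ))    (per-herb efficacy contribution)
   M  = α 𝓗
   p  = σ(W₅ ReLU(W₄ M))
   L  = −[y log p + (1−y) log(1−p)] + λ‖ω‖₂
   ```

   trained with Adam at batch size 1. The second-layer weights `α`,
   aggregated over repeated runs, rank each positive prescription's
   herbs by relevance; the top-N herbs form the *distilled*
   prescription.

2. **Apriori frequent-itemset mining** over the distilled
   prescriptions, with the support threshold set to the M-th largest
   support among all occurring K-itemsets. The frequent K-itemsets are
   the candidate ESHGs.

3. **Evaluation**: greedy Dice-coefficient soft accuracy of mined
   groups against a gold standard, exact-match strict accuracy,
   average-precision ranking metrics (AP/MAP) for essential-herb
   identification, and a distilled-versus-raw comparison harness with
   95% confidence half-widths.

4. **A synthetic corpus generator** planting gold-standard groups into
   Zipf-skewed background noise, since no public prescription database
   with vetted ESHGs exists.

## Worked example

```r
library(eshgminer)

study <- simulate_study(sim_config(seed = 1))   # 2 efficacies, 200 prescriptions
study$gold$efficacy_1
#> [[1]] "herb_001" "herb_039" "herb_068"
#> [[2]] "herb_034" "herb_087"
#> [[3]] "herb_014" "herb_043"

res <- run_efficacy_pipeline(study$corpus, study$gold, "efficacy_1",
                             K = 2, M = 8, n = 8, runs = 3, seed = 7,
                             hyper = hann_hyper(epochs = 10))
res$raw_acc   # raw Apriori soft accuracy:  0.511 (9 groups)
res$acc       # two-stage  soft accuracy:   0.622 (9 groups)
head(attr(res$groups, "supports"))
#> 34 34 34 33 26 24
```

The balanced dataset (50 positives, 50 under-sampled negatives) is
trained `runs = 3` times; aggregated attention distills each positive
to its top 8 herbs; Apriori mines pairs at `min_sup` = 8th-largest
support. Here the top mined pairs are exactly the 2-subsets of the
planted groups (supports 24–34), and distillation lifts soft accuracy
from 0.511 to 0.622 by pushing ubiquitous background herbs out of the
support ranking. `compare_harness()` repeats this over seeds and
efficacies and adds confidence intervals; `run_all(pipeline_config())`
sweeps the full `K ∈ {2,3,4}`, `M ∈ {5..8}` protocol and writes TSV
reports.

A command-line front end wrapping the same functions lives in
`inst/cli/eshg.R` (subcommands `simulate`, `train`, `distill`, `mine`,
`evaluate`, `rank-eval`, `run-all`).

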