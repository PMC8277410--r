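# chdi — composite hospital performance scoring

`chdi` builds ranked composite performance indices for hospitals from the
kind of performance information that is publicly available in China: a
hospitals × indicators table whose columns fall into three domains —
**research and development** (SCI publications, citations, high-impact
papers, clinical trials), **academic reputation** (academicians,
editorships, association posts, national awards — small-integer ordinal
counts), and **quality and safety** (key clinical specialties and two
cost-direction malpractice litigation ratios).

The scoring chain, per domain and then across domains:

1. **Suitability diagnostics** — Kaiser–Meyer–Olkin sampling adequacy for
   all-numeric domains, Cronbach α for domains with categorical
   indicators; pass requires > 0.7.
2. **Exhaustive indicator-subset search** — every nonempty subset (≤ 16
   indicators) is scored; acceptable subsets clear the diagnostic and a
   cumulative-variance floor, and the largest acceptable subset wins.
3. **Dimension reduction** — correlation-matrix PCA, or CATPCA
   (optimal-scaling alternating least squares with monotone ordinal
   quantifications) when indicators are categorical; two components
   retained by default, with variance shares C_i and cumulative variance
   G(m).
4. **Logit transformation** — component scores F_hi are mapped into (0,1)
   by S_hi = 1 / (1 + exp(−(C_i/G(m))·F_hi)).
5. **Entropy weighting** — components are combined within a domain with
   weights proportional to their diversification degree d_i = 1 − e_i,
   where e_i is the normalized Shannon entropy of the transformed scores.
6. **Aggregation** — domain scores are combined with configurable domain
   weights (equal by default) and min–max rescaled,
   index = (raw − min) / range × scale, so the top hospital attains the
   output scale (1 or 100) exactly; Pearson correlations among domain
   scores and the total are attached as a validity report.

Because real hospital-level tables of this kind are not published, the
package ships a latent-factor simulator (`default_fixture()`) that
reproduces the assumed structure — 310 hospitals, 13/9/3 candidate
indicators with planted noise columns, heavy-tailed counts, ordinal
scales, cost-direction ratios, and positively correlated domain strengths
— so every stage is testable end to end.

## Worked example

```r
library(chdi)

fx  <- default_fixture(seed = 17)            # 310 synthetic hospitals
run <- run_pipeline(fx$table, scoring_config(seed = 17))
cat(render_report(run, top_k = 5), sep = "\n")
```

```
== Component models ==
domain                        original  selected  components   cumulative variance
research_and_development            13        11           2                 0.894
academic_reputation                  9         6           2                 0.931
quality_and_safety                   3         3           2                 0.881

== Entropy weights (%) ==
research_and_development     PC1:  97.1  PC2:   2.9
academic_reputation          PC1:  97.6  PC2:   2.4
quality_and_safety           PC1:  99.3  PC2:   0.7

== Ranking (top 5 of 310) ==
 rank unit           index
    1 H173          1.0000
    2 H060          0.9971
    3 H008          0.9627
    4 H080          0.9622
    5 H188          0.9566
```

Reading the report: the subset search kept 11 of 13 research indicators
and 6 of 9 reputation indicators — exactly the structural (non-noise)
columns planted by the simulator — and the two retained components
explain 88–93% of each domain's variance. The first component dominates
the entropy weights in every domain because its transformed scores spread
furthest. The top-ranked hospital attains the scale maximum by
construction of the min–max rescaling; the correlation section (not
shown) reports all pairwise domain-score correlations positive, with the
quality domain the weakest link to the total.

The same chain is scriptable from a shell:

```sh
Rscript inst/cli/chdi.R simulate --seed 17 --out table.csv --table-config cfg.yaml
Rscript inst/cli/chdi.R diagnose --input table.csv --config cfg.yaml
Rscript inst/cli/chdi.R run --input table.csv --config cfg.yaml --outdir results/
```

`run` writes `ranking.csv`, `entropy_weights.csv`, `diagnostics.csv`,
`validation_correlations.csv`, per-domain model files and a manifest with
content hashes, so runs with equal inputs and seed are bit-reproducible.
Exit codes: 0 success, 2 validation failure, 3 diagnostic failure (with
`--abort-on-fail`).

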