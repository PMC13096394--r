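# ascvs — automated system-cognitive analysis for virtual screening

`ascvs` classifies bioassay activity from coded molecular-descriptor tables
in the automated system-cognitive (ASC) tradition.  It is aimed at
cheminformatics practitioners who have a flat descriptor table — one row
per screened compound, an `Outcome` column (`Active`/`Inactive`), and a mix
of text pharmacophore codes (`NEG_no1_NEG`, `HBD_no4_HBA`, ...) and numeric
properties (`XlogP`, `PSA`, `MW`, a binary `BBB` flag, ...) — and who need
an interpretable, assumption-free classifier plus feature analytics for
heavily imbalanced screens (~1.4% actives is the motivating regime).

## The method in brief

1. **Coding.**  Every column becomes a *scale* partitioned into discrete
   *gradations* (text categories or numeric intervals; equal-frequency,
   3 bins by default).  Objects become rows of a binary incidence matrix
   L<sub>i</sub>(o) over gradations.
2. **Knowledge models.**  From the gradation-by-class frequency matrix
   N<sub>ij</sub> (margins N<sub>i</sub>, N<sub>j</sub>, N; per-class
   object counts) nine models I<sub>ij</sub> are formed: raw conditional
   probabilities (PRC1, PRC2), the Kharkevich log-ratio measure
   Ψ·log₂(P<sub>ij</sub>/P<sub>i</sub>) with Ψ = 1/log₂ N<sup>obj</sup>
   (INF1, INF2), the chi-square deviation from independence
   N<sub>ij</sub> − N<sub>i</sub>N<sub>j</sub>/N (INF3), the ROI criterion
   P<sub>ij</sub>/P<sub>i</sub> − 1 (INF4, INF5) and plain probability
   differences (INF6, INF7), each on the object- or frequency-conditional
   base.
3. **Recognition.**  An object's similarity to class j is the signed
   percent S(o,j) = 100·cor(I<sub>·j</sub>, L) (or the additive
   100·ΣI·L/Σ|I|); the predicted class is the top of the descending
   ranking.
4. **Reliability.**  Over object-by-class positive decisions (S > 0):
   Van Rijsbergen's F₁ = 2TP/(2TP+FP+FN) and the fuzzy
   L1 = 2TP_f/(2TP_f+FP_f+FN_f) with every decision weighted by |S|/100;
   the L1-best model becomes the current model.
5. **Artifact removal.**  Training objects whose own-class similarity falls
   below a threshold (12 by default, leave-one-out scored against the
   chi-square model) are removed and the models retrained.
6. **Analytics.**  Information portraits per class, gradation/scale
   significance with Pareto curves, signed gradation-to-class contribution
   graphs (TSV/DOT), and imbalance baselines.

A synthetic generator (`generateBioassay()`) reproduces the statistical
shape of an AID362-like screen with planted ground truth, so the whole
pipeline is testable without any external data.

## Worked example

```r
library(ascvs)

gen <- generateBioassay(nObjects = 800, nNumericScales = 10, nTextScales = 20,
                        activeRate = 0.15, nInformative = 6, effectSize = 2.5,
                        labelNoiseCount = 20, seed = 11)
scales <- buildScales(gen$table)
scales
#> ScaleSet: 30 descriptive scales (20 text, 10 numeric), 119 gradations
#>   classification scale 'Outcome': Active, Inactive

sample <- codeObjects(gen$table, scales)
models <- buildAllModels(frequencyMatrix(sample))
selectBestModel(sample, models)
#> ReliabilityReport over 9 model(s); best by L1: PRC1
#>  criterion     F1     L1 accuracy
#>       PRC1 0.7165 0.8224    86.00
#>       PRC2 0.7165 0.8224    86.00
#>       INF3 0.6162 0.7373    61.62
#>       ...

cleaned <- cleanAndRetrain(sample, threshold = 12)
#> removed: 573 objects; retained: 227
classifySample(cleaned$sample, cleaned$models[[cleaned$best]])
#> RecognitionResult (correlation on INF3): 227 objects x 2 classes
#>   identification accuracy: 100.000%

head(informationPortrait(cleaned$models$INF3, "Active"), 3)
#>          scale gradation               id    value         sign
#> 1 NEG_no17_NEG        g3 NEG_no17_NEG::g3 56.09251 contributing
#> 2 ARO_no18_HBA        g3 ARO_no18_HBA::g3 55.61674 contributing
#> 3 HBD_no19_HBA        g5 HBD_no19_HBA::g5 53.51982 contributing

paretoCoverage(significanceTable(cleaned$models$INF3), 0.15)
#> [1] 51.52244
```

Reading the output: before cleaning, the best model identifies 86% of
objects against a 85% trivial baseline — unimpressive, because 20 planted
label-noise objects and every ambiguous borderline compound drag the
profiles.  Cleaning removes the low-similarity objects (16 of the 20
planted artifacts among them; the rest look genuinely like their flipped
class); on the retained sample recognition is perfect and the
top portrait entries are exactly the planted informative gradations.  The
Pareto figure says the top 15% of scales carry ~52% of total significance.

The imbalance yardstick for the motivating screen:

```r
baselineStats(3523, 48)
#> $prevalencePercent     1.3625  (prints as 1.4%)
#> $trivialAccuracyPercent 98.6375 (prints as 98.64%)
#> $trivialCorrect        3475
```

Any accuracy below 98.64% on such a screen is worse than saying "inactive"
to everything — which is why model comparison here leans on F/L1 rather
than accuracy alone.

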