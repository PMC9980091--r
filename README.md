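# riboshift

Sequence-dependent artifacts from nuclease digestion and adapter ligation
distort ribosome profiling data at exactly the resolution that makes it
interesting: the per-codon distribution of footprints along a transcript.
Because a codon's sequence neighborhood is fixed, biased recovery of
particular footprint end sequences produces reproducible false "pauses" —
including an apparent pause at the sixth codon of ORFs that is really
elevated ligation of AUG-starting fragments.

riboshift is an R package for people analyzing ribosome profiling (monosome
or disome) libraries at codon resolution. It models per-codon footprint
counts with a negative binomial regression that separates biology from
technique and inverts the technical part into per-footprint correction
factors:

```
Y[i,j,d5,d3] ~ NB(mu, phi),   var = mu + mu^2/phi
log mu = b0 + b_t[i]                            (transcript abundance)
       + b_A[A] + b_P[P] + b_E[E]               (decoding: A/P/E-site codons)
       + b_d5[d5] + b_d3[d3]                    (digestion lengths)
       + b_f5[f5] + b_f3[f3]                    (end bias sequences)
       + b_d5f5[d5,f5] + b_d3f3[d3,f3]          (interactions)
       + b_g * gc                               (footprint GC)
```

with `f5`/`f3` the terminal transcript k-mers under the footprint and
`gc` the footprint GC excluding the E/P/A codons. Corrected counts are
`count * exp(-(technical terms, GC mean-centered))`, rescaled to preserve
library size. The package also provides A-site offset inference from
start/stop-codon metagenes, a footprint simulator with known ground truth,
differential A-site occupancy testing (Wald + BH across codons),
monosome-to-disome correction transfer, and bias diagnostics
(position-importance profiles, metagenes, pause scores, mean-variance).

## Worked example

Simulate a 100-transcript library with biased recovery at both footprint
ends, fit the model, and correct:

```r
library(riboshift)
library(data.table)

tx  <- simulate_transcriptome(100, codon_range = c(150, 400), seed = 101)
cfg <- make_default_config(tx, "both", library_size = 5e5, seed = 101)
sim <- simulate_library(cfg, tx)

rec      <- aggregate_counts(reads_to_alignments(sim$reads, tx), tx,
                             true_offset_rules(cfg))
training <- select_training_set(rec, tx, seed = 101)
fit      <- fit_nb_glm(build_design(materialize_zero_cells(rec, tx, training)))
fit
#> nb_fit: 785 coefficients, phi = 1.05e+06, loglik = -390162.61 (converged in 4 outer iterations)
```

The dispersion is huge because simulated counts are multinomial (Poisson is
the NB limit `phi -> Inf`); real replicate libraries are overdispersed, as
`mean_variance_diagnostic()` shows. The fitted blocks recover the
simulation parameters — for instance, the 3' recovery probabilities:

```r
b3 <- coef_block(fit, "f3")                        # log scale, ref = "AAA"
truth <- log(cfg$recovery3 / cfg$recovery3["AAA"])
round(cor(exp(b3), exp(truth[names(b3)])), 4)
#> [1] 0.9971
```

Correction removes boundary artifacts and sharpens the A-site signal:

```r
cm  <- correction_model_from_fit(fit, rec)
cor_rec <- apply_correction(rec, cm)               # adds corrected_count
sum(cor_rec$corrected_count) == sum(cor_rec$count) # library size preserved

imp_raw <- position_importance(scale_counts(cor_rec, training, "count"),
                               tx, training)
imp_cor <- position_importance(scale_counts(cor_rec, training,
                                            "corrected_count"),
                               tx, training)
data.table(pos = imp_raw$position, raw = round(imp_raw$importance, 4),
           corrected = round(imp_cor$importance, 4))[pos %in% c(-5, 0, 3, 4)]
#>      pos    raw corrected
#>    <int>  <num>     <num>
#> 1:    -5 0.0359    0.0004
#> 2:     0 0.4411    0.6345
#> 3:     3 0.0199    0.0005
#> 4:     4 0.0065    0.0004
```

Position 0 is the A site (biology: rises after correction); −5 and +3/+4
are where the 5' and 3' bias trimers sit under the default digestion
(technique: drop to the noise floor).

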