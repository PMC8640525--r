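# degensim

Simulating progressive neurodegeneration in trained feed-forward image
classifiers.

## What this is for

Posterior cortical atrophy (PCA) is a visual-variant presentation of
Alzheimer's disease: atrophy of posterior visual cortex with progressive
loss of visual object recognition. `degensim` provides an *in silico*
analogue of such a disease course for computational neuroscientists who use
deep convolutional networks as models of the ventral visual stream: take a
trained classifier, progressively sever its "synapses", and measure how
behaviour and internal representations degrade.

The core procedure is **cumulative random weight ablation**. Let $N$ be the
number of inter-neuron connection weights in the network (convolutional
kernels and dense weight matrices counted elementwise; biases excluded). At
nominal injured fraction $f$, exactly $\mathrm{round}(fN)$ weights are held
at zero; as $f$ increases along a fine schedule (default steps of 0.1%),
previously injured connections stay at zero and an additional uniformly
random set is ablated. Each replicate network follows its own random course.

Readouts along the injury course:

* **accuracy** against the analytic chance level $1/C$;
* **within-superclass error rate** — among misclassified test stimuli, the
  fraction whose predicted class lies in the true class's superclass
  (networks are trained on fine labels only, so superclass structure in
  errors is emergent); reference levels $1/S$ and $(K-1)/(C-1)$;
* **representational similarity**: RDMs with dissimilarity $1-r$ (Pearson)
  over penultimate-layer ("dense_2") activations, compared to the same
  replicate's uninjured reference with Kendall's
  $\tau_A = (C - D)/\binom{n}{2}$ (ties stay in the denominator), plus a
  scrambled-RDM noise floor and block-averaged superclass-level RDMs.

Because full-scale replication (VGG-19 on CIFAR-100) is GPU-sized, the
package ships a synthetic generator that emulates the class/superclass
statistical structure of such datasets, and a compact trainable CNN, so the
entire paradigm runs on one desk CPU in minutes. The VGG-19 replication
profile (learning rate 3e-5, RMSprop, 40 epochs, 30% dropout, 4× input
upscaling, pretrained convolutional weights) is available by configuration.

## Worked example

```r
library(degensim)

cfg <- experiment_config(
  generator = generator_config(images_per_class_train = 50,
                               images_per_class_test = 10),
  training  = training_config("small-cnn", epochs = 15),
  n_replicates = 2,
  schedule  = injury_schedule(increment = 0.05, max_fraction = 0.5,
                              rsa_checkpoints = c(0, 0.1, 0.3, 0.5)),
  rsa_stimuli_per_class = 5,
  seed = 42)

experiment <- run_experiment(cfg)
print(experiment)
#> <degeneration_experiment> 2 replicates, 11 fractions (mode ablate-zero)
#>   baseline accuracy 0.470 +/- 0.042; noise floor tau_a -0.00075

tidy(experiment)        # one row per replicate x injured fraction
#> # A tibble: 22 x 6
#>   replicate_id injured_fraction accuracy within_superclass_error_...1 tau_a_object
#>          <int>            <dbl>    <dbl>                      <dbl>        <dbl>
#> 1            1             0       0.5                            1        1
#> 2            1             0.05    0.41                           1       NA
#> 3            1             0.1     0.295                          1        0.620
#> ...
```

Reading this: the uninjured replicate classifies 50% of held-out stimuli
correctly (chance is 1/20 = 5%), and *every* one of its errors lands in the
correct superclass (`within_superclass_error_rate` 1, superclass chance
0.2). At fraction 0 the network's RDM compared with itself gives
`tau_a_object` exactly 1; `NA` entries are fractions that are not RSA
checkpoints (tau) or error-free batches (error rate) — never zeros. As
injury accumulates, accuracy falls toward chance and $\tau_A$ decays toward
(but, as in cortical-atrophy simulations at scale, not all the way to) the
scrambled noise floor:

```r
glance(experiment)[, c("baseline_accuracy", "final_accuracy",
                       "final_tau_a_object", "noise_floor_tau_a")]
#> # A tibble: 1 x 4
#>   baseline_accuracy final_accuracy final_tau_a_object noise_floor_tau_a
#>               <dbl>          <dbl>              <dbl>             <dbl>
#> 1              0.47         0.0975              0.429         -0.000755

summarize_records(tidy(experiment))  # mean / SD / n per fraction per metric
autoplot(experiment)                 # degeneration curves, mean +/- SD ribbons
autoplot(experiment$rdms[["0.500000"]])  # checkpoint RDM heat map
```

`run_experiment(cfg, out_dir = "results/")` additionally writes
`records.csv`, `summaries.csv`, checkpoint-averaged RDM tensors and a
`manifest.json` capturing every derived seed.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/degensim.R generate-data --out data/ --seed 7
Rscript inst/cli/degensim.R run --out results/ --seed 1
```

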