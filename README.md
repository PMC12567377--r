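# mmhafnn

Four-class emotion recognition (happy / sad / fear / calm) from paired
62-channel EEG and facial-expression frames, for researchers working on
affective computing in populations — such as hearing-impaired subjects —
whose emotional processing leans on visual and physiological channels.
The package implements a multimodal multi-head attention fusion network
(MMHA-FNN) end to end in R: differential-entropy features, topographic
rasterization, two convolutional encoders, a Transformer fusion
classifier with attention attribution, the clip-wise and
leave-one-subject-out evaluation protocols, and a synthetic paired-corpus
generator with analytically known class signatures so the whole pipeline
is testable without access to restricted recordings.

## The model

**EEG features.** Each 1-second, band-filtered window (delta 1–4, theta
4–8, alpha 8–12, beta 12–30, gamma 30–50 Hz; zero-phase 4th-order
Butterworth) is summarized by its differential entropy under the Gaussian
model,

```
h(X) = -∫ f(x) ln f(x) dx  =  ½ ln(2πe σ²)   [nats],
```

with the 1/n variance estimator, so h(cX) = h(X) + ln|c| exactly.  The 62
per-channel values of each band are rasterized to a topographic map by
bilinear interpolation between the four electrodes surrounding each pixel
(nearest electrode per open quadrant, area-product weights
ω_q ∝ |x_p − x_opp|·|y_p − y_opp|, normalized; zero outside four-quadrant
coverage).  On rectangular electrode grids this reduces exactly to
textbook bilinear interpolation.

**Encoders and fusion.** The band stacks feed an MBConv /
squeeze-excitation encoder (EFEM), faces a bottleneck-residual encoder
(FEFEM).  Their token sequences, tagged with modality-type embeddings and
a class token, pass through pre-LN Transformer blocks

```
Ẋ_l = MSA(LN(X_{l-1})) + X_{l-1},    X_l = MLP(LN(Ẋ_l)) + Ẋ_l,
Attention(Q,K,V) = softmax(QKᵀ/√d_k) V,
```

and a linear head on the class token yields the 4 logits.  In the fusion
model the EEG trunk runs per band with shared weights, so class-token
attention mass can be attributed to frequency bands (and to facial
regions via a token-grid partition).  Training: cross-entropy, AdamW,
batch 32, initial learning rate 1e-3 under cosine annealing
η_t = η_min + ½(η_max−η_min)(1+cos(π·T_cur/T_max)).  Baseline fusion
heads (feature concatenation, decision-level averaging) share the same
encoders.  The reference configuration is calibrated to the published
complexity budget (15.2 M parameters); `count_params_flops()` also
reproduces the standard 18-layer residual baseline at 11.7 M parameters
and 1.8 G MACs.

All layers and backpropagation are implemented in R on BLAS matrix
products; there is no compiled code and no deep-learning dependency.

## Worked example

Generate a small synthetic corpus (2 subjects, 2 clips per emotion, 20 s
clips), extract features, train the fusion model on one clip-wise fold
and inspect it:

```r
library(mmhafnn)
cfg <- synth_config(n_subjects = 2, clips_per_emotion = 2, seed = 11)
ds  <- synth_dataset(cfg, face_size = 48)
ds
#> <synth_dataset> 2 subjects, 16 clips (2/emotion), 320 windows, 320 face frames

de <- extract_de_features(ds$eeg[[1]])
dim(de)                       # windows x channels x bands
#> [1] 20 62  5
stack <- stack_bands(de[1, , ], default_layout(), size = 64)

dat   <- prepare_model_data(ds, map_size = 64)
split <- make_clip_folds(dat$manifest, k = 2, seed = 1)
w     <- fold_windows(split, dat$manifest, 1)
fit   <- mmha_train(mmhafnn:::subset_data(dat, w$train), method = "mmha",
                    cfg = desk_model_config(), epochs = 10, seed = 1)
fit
#> <mmha_model> method=mmha  trained 10 epochs on 160 windows
#>   final training loss 0.3025, accuracy 96.2%

evaluate(fit, mmhafnn:::subset_data(dat, w$val))
#> <eval_report> accuracy 61.25% on 160 windows
#>        pred
#> truth   happy   sad  fear  calm
#>   happy 0.850 0.025 0.025 0.100
#>   sad   0.150 0.450 0.125 0.275
#>   fear  0.125 0.125 0.675 0.075
#>   calm  0.100 0.275 0.150 0.475
```

The printed accuracy is validation accuracy on held-out clips — 61 % here
against a 25 % chance level, limited by the tiny training set (160
windows).  At the package's full study scale (4 subjects, 1600 windows)
every method recovers the synthetic signal almost perfectly; see below.
The confusion matrix rows are truth-normalized.  Attention attribution of
a trained fusion model reports the class-token attention mass per EEG
band and facial region, each group normalized to sum to one:

```r
attention_attribution(fit, mmhafnn:::subset_data(dat, w$val))
#> <attribution_report> mean class-token attention
#>   EEG bands:  delta 0.206  theta 0.206  alpha 0.198  beta 0.190  gamma 0.200
#>   Face regions:  eyes 0.000  mouth 0.517  cheeks 0.000  forehead 0.483  other 0.000
```

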