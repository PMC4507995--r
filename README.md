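# ocufit

Fluorescence lifetime imaging ophthalmoscopy (FLIO) maps the decay of
retinal autofluorescence after pulsed laser excitation. A time-correlated
single photon counting (TCSPC) detector builds, for every image pixel, a
histogram of photon arrival times over the ~12.5 ns between laser pulses;
the shape of that histogram encodes the fluorescence lifetimes of the
fluorophores in the tissue, which shift in diseases such as diabetic
retinopathy and AMD long before structural change is visible. `ocufit`
implements the full analysis chain from raw photon cubes to group-level
statistics, for researchers working with FLIO/FLIM data or validating
lifetime-analysis methodology on synthetic data.

## The model

The expected signal in a pixel is a sum of exponential decays convolved
with the measured instrument response function (IRF):

    I(t) = IRF * [ sum_i alpha_i exp( -((t - tc_i) / tau_i)^beta ) ]
           + alpha_lens I_lens(t - tc_lens) + b

with amplitudes `alpha_i`, lifetimes `tau_i` (ps), optional per-layer time
shifts `tc_i`, optional stretching exponent `beta` in (0, 1], an optional
separately measured crystalline-lens decay `I_lens` (scaled and shifted —
the lens fluoresces strongly and reaches the detector ~202 ps before the
retinal signal), and a constant background `b`. Because the excitation is
periodic, slow decays wrap around: the incomplete-decay correction folds
in the tails of `j` preceding pulses, `I(t) + sum_q I(t + q tR)`.

Fitting minimizes the reduced chi-square

    chi2_r = 1/(m - p) sum_j (I_M(t_j) - I_C(t_j))^2 / w(t_j)

with Neyman weights `w = I_M` (floored at 1) by default. The linear
parameters (`alpha_i`, `alpha_lens`, `b`) are solved in closed form by
weighted non-negative least squares inside every evaluation (variable
projection); the nonlinear parameters are found in two stages —
differential evolution on the image-integrated decay for a global initial
solution, then a bound-constrained Nelder-Mead per pixel. Around the fit:
adaptive circular binning raises every pixel to a photon minimum before
fitting, reflection artifacts in the summed decay are masked from the
figure of merit, and pixels deviating >30% from their 7x7 window median
are re-fit from their best neighbor (kept only if chi2_r improves).
Downstream, maps are summarized by the amplitude-weighted mean lifetime
`tau_m = sum(alpha_i tau_i)/sum(alpha_i)`, ETDRS-grid subfield statistics,
and histogram-class group comparison (per-class Wilcoxon rank-sum tests
against the Bonferroni bound `th = s/nC`, with ROC/AUC and a Youden
cut-off for significant classes).

## Worked example

Simulate a two-component retina-like image (tau = 500/2500 ps, 6,400
photons/pixel), bin it to 100,000 photons per pixel, and fit:

```r
library(ocufit)
ta    <- TimeAxis(256, 48.8, 12.5)        # 256 channels over 12.5 ns
irf   <- IRFCurve(exp(-((channelCenters(ta) - 1000)/(172/2.355))^2/2), ta)
spec  <- modelSpec("multiexp", nComponents = 2, incompleteDecay = 1)
truth <- paramVector(alpha = c(0.6, 0.4), tau = c(500, 2500), b = 0.5)
gt    <- uniformGroundTruth(c(16, 16), truth, photons = 6400,
                            spec, irf, ta, seed = 7)
cube  <- simulateCube(gt)
ab    <- adaptiveBin(cube, threshold = 1e5)
res   <- fitImage(ab$cube, spec, fitConfig(seed = 11), irf,
                  radius = ab$radius)
res
#> FitResultMaps: 16 x 16 pixels, maps: alpha1, alpha2, tau1, tau2, b, tauM
#>   median chi2r: 0.9885; 0 artifact interval(s)
round(c(tau1 = median(resultMap(res, "tau1")),
        tau2 = median(resultMap(res, "tau2")),
        tauM = median(resultMap(res, "tauM"))), 1)
#>   tau1   tau2   tauM
#>  498.4 2504.4 1299.8
```

The median fitted lifetimes land within 0.5% of the simulated truth
(500/2500 ps), the mean lifetime matches its true value of 1300 ps, and a
median chi2_r near 1 says the residuals are at the Poisson noise level.

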