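# dlpr — dictionary-learning phase retrieval from noisy coded diffraction patterns

Optical sensors record the *intensity* of a diffracted wavefront; its phase
— which carries most of the structural information about the object — is
lost. `dlpr` recovers a complex-valued object wavefront
`x = a ⊙ exp(jψ)` from the intensities of `S` coded diffraction patterns

    z_s ~ Poisson(|F M_s x|² · χ)        (photon-limited sensors)
    z_s = |F M_s x|² + σ ε_s             (thermal noise)

where `M_s` are known random quaternary phase masks and `F` is the unitary
2-D DFT. It is aimed at heavily noisy regimes (down to ~0.1 photons per
pixel per mask), where classical Gerchberg–Saxton iterations fail, and at
users — optics, X-ray and MRI-interferometry practitioners, and methods
researchers — who need a reference implementation of dictionary-based
phase retrieval with a full simulation bench.

The estimator alternates four steps, derived as block minimizers of one
variational objective:

1. forward propagation `v_s = F M_s x`;
2. a sensor-plane *proximity operator* of the noise model's negative
   log-likelihood — closed-form for Poisson counts, a Cardan cubic root
   for Gaussian noise, magnitude replacement for exact data;
3. backprojection `(1/S) Σ Mₛᴴ Fᴴ u_s`;
4. an object-plane filter: overlapping 10×10 patches of the iterate are
   sparse-coded by complex-domain orthogonal matching pursuit over a
   complex dictionary *learned online from the data itself*
   (`variant = "dlpr"`), or over a dictionary pre-trained on clean images
   of the same class (`variant = "prior_plugged"`), then recombined in an
   exact diagonal least-squares update. `variant = "gsf"` skips step 4 —
   the sensor-filtered Gerchberg–Saxton baseline.

Because the sparse model lives in the complex domain it couples amplitude
and phase and never needs phase unwrapping. Errors are reported as the
root-mean-square of the wrapped phase difference after global-phase
alignment (`rmse_phase`, `align_global_phase`).

## A worked example

Simulate a photon-starved acquisition of an octant-truncated Gaussian
phase surface and retrieve it:

```r
library(dlpr)

size  <- c(100, 100)
psi   <- make_phase_surface("truncated_gaussian", size, peak = 12)
scene <- complex_scene(matrix(1, 100, 100), psi)   # unit amplitude

chi   <- chi_effective(1e-5, size)   # conventional chi = 1e-5  ->  0.1 photons/px
masks <- generate_masks(12, size, seed = 13)
obs   <- observe(scene$field, masks, "poisson", chi = chi, seed = 513)
snr_global(scene$field, masks, chi)
#> [1] -7.001196

cfg <- dlpr_config("poisson", "dlpr", chi = chi, iterations = 20, seed = 1)
fit <- dlpr(obs, masks, cfg, truth = scene)
xhat <- align_global_phase(fit$x, scene$field)
rmse_phase(Arg(xhat), wrap_phase(scene$phase))
#> [1] 0.2535107
```

The first number confirms the acquisition sits at −7 dB sensor SNR (0.1
expected photons per pixel per mask); the second is the wrapped-phase
error of the retrieval, about a quarter radian. On the same observations
the sensor-only baseline (`variant = "gsf"`) ends at 1.21 rad —
essentially no recovery. With a class prior — a dictionary trained once on
a clean Gaussian surface and its four quadrant cuts
(`gaussian_prior_scenes()`, `codl()`) and plugged in via
`variant = "prior_plugged"` — no in-loop learning is needed, the error
drops further (≈0.17 rad median in the shipped study), and the retrieval
runs several times faster.

`run_experiment()` sweeps scenes × noise levels × variants × seeds into a
tidy results table; `make_test_suite()` builds the standard nine-scene
bench (two fringe-rich phase surfaces crossed with four amplitude-coupling
groups). The methods vignette (`vignettes/dlpr-methods.Rmd`) documents the
model, the penalty calibration, and known limitations.

## Command line

```sh
inst/cli/dlpr simulate   --scene truncated_gaussian --size 100 --chi 1e-5 --out obs.rds
inst/cli/dlpr learn-dict --scenes gaussian_prior --size 100 --out prior.rds
inst/cli/dlpr run        --obs obs.rds --prior prior.rds --variant prior_plugged --out est
inst/cli/dlpr evaluate   --estimate est.rds --truth scene.tif
```

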