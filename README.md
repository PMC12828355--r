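# microfit

Probabilistic microstructure model fitting for diffusion and combined
diffusion–relaxometry MRI, in R.

Multi-compartment models describe the diffusion-weighted signal in a voxel
as a mixture of contributions from idealised tissue environments — axons
(sticks, or cylinders of diameter d_a under the Gaussian-phase-distribution
approximation), the extra-cellular space (zeppelins), cell bodies
(spheres), and isotropic pools (free water, or the immobile "dot" water of
fixed tissue). Fitting them to direction-averaged (spherical-mean) or
spherical-harmonic rotational-invariant data recovers signal fractions,
diffusivities, sizes and, with multi-echo-time data, compartmental T2
values. microfit is aimed at researchers who need not only the estimates
but their uncertainty, and who want to evaluate — on synthetic data
matching their protocol — which parameters their acquisition can actually
resolve.

The package provides:

* **Forward models** for Stick, Zeppelin, Cylinder, Sphere and Iso
  compartments on spherical means (closed forms built on
  √(π/4x)·erf(√x), and the GPD restricted-diffusion series over
  Bessel-function roots), plus Legendre-projected kernels and fODF
  invariants for standard-model imaging at rotational-invariant order 2.
* **Composite models**: SMT, MTE_SMT, SANDI, SANDIdot, MTE_SANDI,
  ExCaliber, SMI, SMIfw — with fraction simplexes, parameter links (e.g.
  tortuosity) and fixed-parameter declarations.
* **Estimators**: a Metropolis–Hastings sampler with uniform priors on
  bounds, optional noise-level sampling, a two-stage scheme for
  axon-diameter mapping, chain diagnostics (split-R̂, ESS) and threaded,
  seed-reproducible voxelwise maps; and an MC-dropout MLP estimator
  trained on prior-controlled synthetic data, returning posterior
  mean/std maps from stochastic forward passes.
* **Acquisition I/O**: NIfTI volumes (via RNifti) with plain-text
  side-cars (`.bvals`, `.bvecs`, `.techo`, `.tdelta`, `.tsmalldel`),
  spherical-mean/SH reduction, SNR maps, and the PGSE relation
  b = γ²G²δ²(Δ − δ/3).
* **Sensitivity analysis**: the minimal-detectable-attenuation criterion
  σ̄ = z_α/(SNR·√n) and single-/multi-shell axon-diameter sensitivity
  ranges.
* **Synthetic data**: protocol presets for several widely used acquisition
  regimes, noisy voxel/phantom generators, and an accuracy/precision
  sweep harness.

## Worked example: axon-diameter sensitivity of an ex vivo protocol

Which axon diameters can a preclinical 660 mT/m protocol actually detect?
Take the three high-b shells acquired at δ/Δ = 11/15.192 ms, intrinsic
diffusivity 0.6 µm²/ms (ex vivo), 32 directions per shell:

```r
library(microfit)
shells <- data.frame(b = c(18.1, 25, 43), delta = 11, Delta = 15.192)
for (snr in c(100, 50, 30)) {
  r <- diameterBoundsMultiB(shells, sensitivityConfig(snrB0 = snr))
  cat(sprintf("SNR %3d: sigma_bar %.5f -> [%.2f, %.2f] um\n",
              snr, r$sigmaBar, r$dmin, r$dmax))
}
```

```
SNR 100: sigma_bar 0.00291 -> [1.43, 10.50] um
SNR  50: sigma_bar 0.00582 -> [1.70, 9.18] um
SNR  30: sigma_bar 0.00969 -> [1.95, 8.32] um
```

Reading: at b = 0 SNR 100, a cylinder narrower than ~1.4 µm is
indistinguishable from a zero-diameter stick (its perpendicular attenuation
is below the noise floor σ̄), and one wider than ~10.5 µm leaves too little
signal at these b-values to separate from noise. Halving the SNR narrows
the window from both sides. A fitting example:

```r
m <- makeModel("ExCaliber")                         # cylinder + zeppelin + dot
p <- protocolPreset("excaliber_exvivo_dt15")        # 8 b-values to 43 ms/um^2
gt <- c("f.axon" = 0.7, "f.dot" = 0.15, "axon.da" = 2,
        "axon.dpara" = 0.6, "extra.dperpFrac" = 0.3)
meas <- synthVoxel(m, gt, p, snr = 100, nrealizations = 1, seed = 42)[1, ]
allp <- freeParameters(m)$name
fit <- twoStageFit(m, meas, p,
                   sampler(allp, nsamples = 10000, burnin = 3000),
                   sampler(allp[1:3], nsamples = 6000, burnin = 2000),
                   noisemodel(sigma = 0.01), seed = 7)
subset(fit$summary, stage == "stage2")
```

The stage-2 summary reports the posterior mean and std per sampled
parameter; fixing the diffusivities at their stage-1 posterior means
sharpens the diameter and fraction posteriors, which is the point of the
two-stage scheme. See the vignette
(`vignettes/microstructure-fitting.Rmd`) for the models, estimator
settings and their assumptions.

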