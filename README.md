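# cyclicell

Statistical mechanics of adherent cells on cyclically strained stiff
substrates.

Cells seeded on a 2D substrate that is strained cyclically (a few
percent around 1 Hz) reorient, together with their stress-fiber (SF)
cytoskeleton, away from the straining direction — *cyclic strain
avoidance*. `cyclicell` is for biophysicists and mechanobiologists who
want to compute the population statistics of that process from a
free-energy model rather than fit empirical orientation laws: it
predicts distributions of cell orientation, area, aspect ratio, and SF
angular order, and the stochastic trajectories by which single cells
reorient.

## The model in brief

A cell morphology is a uniform ellipse, encoded by the coefficients
$(h,k,l)$ of $h\hat x_1^2 + k\hat x_1\hat x_2 + l\hat x_2^2 = 1$
(lengths in units of the relaxed radius $R_0$), equivalently semi-axes
$\hat a_1 \ge \hat a_2$ and orientation $\theta$. Each morphology
carries a steady-state angular distribution $\hat\eta(\phi)$ of
contractile stress fibers with $\hat n(\phi)$ functional units, whose
tension follows a Hill-type law — shortening fibers lose stress, so
fibers along the cyclic strain direction lose their binding free energy.
The cycle-averaged cell free energy
$H^{(c)}_{cell} = \langle H_{cyto} + H_{passive}\rangle_{T_p}$ combines
this active term with compressible neo-Hookean elasticity of cytoplasm
and nucleus.

The population is the *homeostatic ensemble*: the maximum-entropy
distribution over morphologies constrained so the mean free energy
equals that of the suspended cell,

$$P^{(c)}_{eq} = \frac{e^{-\beta H^{(c)}_{cell}}}{\sum_c e^{-\beta H^{(c)}_{cell}}},
\qquad \sum_c P^{(c)}_{eq} H^{(c)}_{cell} = H_s,$$

with $\beta$ (an inverse "homeostatic temperature") solved from the
constraint. Kinetics follow the overdamped Langevin equation
$\partial r_i/\partial \hat t = -\partial\hat H/\partial r_i +
\sqrt{2/(\hat\beta\Delta\hat t)}\,\mathcal N(0,1)$ on the same
landscape ($\hat H = H^{(c)}_{cell}/|H_s|$,
$\hat t = t|H_s|/\gamma$), whose stationary law is the ensemble above.
SF order is quantified by the circular variance
$CV = 1 - |\int \hat\xi(\delta) e^{2i\delta} d\delta|$ (1 = isotropic,
0 = perfectly aligned) and the order parameter
$S = \langle\cos 2\theta\rangle$.

See the methods vignette (`vignettes/cyclicell-methods.Rmd`) for the
full closures, parameter meanings, and known limitations.

## Worked example

```r
library(cyclicell)

load <- cyclic_load(eps_amp = 0.1, f = 1, r = 0)   # 10 %, 1 Hz, uniaxial
sfp  <- sf_params()
cp   <- with_suspension_energy(sfp, cell_params())

ens <- homeostatic_ensemble(load, sfp, cp, n_samples = 5000, seed = 1)
ens
#> <ensemble_result> 5000 microstates; beta_hat = 17.22; H_s = -14.68

sf <- sf_global_distribution(ens)
cat(sprintf("CV(xi)  = %.3f   CV(rho) = %.3f\n",
            circular_variance(sf$xi_hat), circular_variance(sf$rho_hat)))
#> CV(xi)  = 0.458   CV(rho) = 0.477

dens <- morphology_densities(ens)
dens$theta$mid[which.max(dens$theta$density)] * 180 / pi
#> [1] 97.5

circular_cell_distribution(load, sfp, cp)$CV
#> [1] 0.6463045

rod <- rod_orientation_density(cyclic_load(0.1, 1, 0.25), sfp, cp, n_time = 32)
rod$modes * 180 / pi
#> [1]  63.75 116.25
```

Reading the numbers: `beta_hat` is the nondimensional inverse
homeostatic temperature — larger under cyclic load, meaning the
population is more deterministic. `CV(xi) = 0.46` says the global SF
distribution is strongly anisotropic, while the orientation density
peaks near 90°: SFs avoid the strain direction mainly because whole
cells reorient. `CV(rho) = 0.48` (SFs relative to each cell's own major
axis) changes much less with loading, and the fixed-circle reduced model
(`CV = 0.65`) shows that SF remodeling alone produces weaker alignment
than the full morphology-coupled ensemble. The rod-model modes sit at
$\tan^{-1}(1/\sqrt r) = 63.4°$ and its mirror — cells align with the
directions of vanishing cyclic strain rate.

Kinetics, e.g. distinguishing reorientation by rigid rotation from
reorientation by straining, run through `run_langevin_ensemble()`,
`order_parameter()`, and `mode_fraction()`; free-energy landscapes
through `free_energy_landscape()`.

A command-line driver with `ensemble`, `landscape`, `langevin`,
`circular`, `rod`, and `fixtures` subcommands is installed under
`inst/cli/cyclicell`; it reads a YAML configuration (`load_config()`)
and writes CSV tables plus JSON summaries stamped with the
configuration hash and seed.

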