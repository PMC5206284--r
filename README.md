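# lamellipod

Steady-state analysis and simulation of a reduced mechanical model of the
**lamellipodium** — the thin sheet of actin filaments that drives cell
crawling — extended by angle-dependent actin–myosin interaction. The
package is for modellers of cytoskeletal mechanics who want a tested,
reproducible implementation of the planar two-family lamellipodium
reduction: its parameters, its equilibria and their stability, the coupled
two-lamellipodia fragment model whose bistability explains why detached
keratocyte fragments can either sit still (circular) or crawl (crescent),
and an independent quadrature oracle certifying the closed-form dynamics.

## The model in brief

Two transversal families of rigid actin filaments of length $L$ cross at
angle $\varphi = \pi - 2\omega$, where $\omega \in (0, \pi/2]$ is the
filament angle to the leading edge. Transient cross-links resist stretching
($\mu^S$) and twist the crossing angle toward $\varphi_0$ ($\mu^T$);
myosin-II filaments do the same toward $\pi$ ($\overline{\mu^{SM}},
\overline{\mu^{TM}}$) but engage only above a cutoff angle $\bar\varphi$,
and walk toward barbed ends at speed $v^M$. With substrate friction
$\mu^A$, polymerization speed $v$, membrane force $f_{mem}$ and
stress-fibre force $f_{stress}$, the angle dynamics of a translationally
invariant strip reduce to

$$\dot\omega\,g(\omega) = \cos\omega\Bigl(\tfrac{f_{stress}-f_{mem}}{4} + h(\omega)\Bigr),
\qquad
h(\omega) = \mu^T(\pi-2\omega-\varphi_0) - 2\omega\,\overline{\mu^{TM}}\,(\pi-2\omega-\bar\varphi)_+ .$$

When $\overline{\mu^{TM}}/\mu^T$ exceeds a closed-form threshold, $h$ has
three zeroes and the strip is bistable between a spread,
cross-link-dominated angle and a collapsed, myosin-influenced one. A
fragment — two strips back to back, coupled through a size-regulating
stress-fibre force — then has four stable steady states: two symmetric
(stationary fragment) and two polarized (fragment moving at
$\dot y = \tfrac{v}{2}(\sin\omega - \sin\hat\omega)$, with a collapsed,
myosin-active rear). The methods vignette
(`vignettes/bistable-lamellipodium.Rmd`) derives and discusses all of this.

## Worked example

```r
library(lamellipod)

p <- default_parameters()          # reference table, "simulation2" preset
bistability_condition(p)[c("ratio", "threshold", "holds")]
#> $ratio      [1] 4.285714
#> $threshold  [1] 2.281905
#> $holds      [1] TRUE

h_zeros(p)
#>       omega    branch          dh simple
#> 1 0.9599311    linear -0.00840000   TRUE
#> 2 0.6397397 quadratic  0.03345704   TRUE
#> 3 0.1750586 quadratic -0.03345704   TRUE
```

The myosin twisting constant exceeds the dominance threshold, so the
torque balance has three zeroes: the cross-link angle (0.96 rad = 55°,
stable), a separatrix (0.64 rad, unstable) and the myosin-collapsed angle
(0.18 rad, stable).

```r
fd <- fragment_defaults()          # small-adhesion fragment regime
ss <- fragment_steady_states(fd$params, fd$sfm)
ss[ss$stable, c("omega", "omega_hat", "label", "speed")]
#>      omega omega_hat              label     speed
#> 3 0.996464  0.184420 polarized-front-CL  0.984269
#> 2 0.184420  0.996464 polarized-front-MY -0.984269
#> 1 1.020827  1.020827       symmetric-CL  0.000000
#> 4 0.178261  0.178261       symmetric-MY  0.000000

run <- integrate_fragment(make_fixture("asymmetric", fd$params, fd$sfm)[[1]],
                          fd$params, fd$sfm, t_end = 120)
c(run$outcome, round(run$terminal_speed, 4))
#> [1] "polarized" "0.9843"
```

A fragment started symmetric stays put; one whose rear angle is pushed
below the separatrix polarizes and crawls at about 1 µm/min. Lowering
`mu_TM_bar` below the threshold removes the myosin state and every start
reverts to the stationary symmetric fragment.

A command-line wrapper over the same functions is installed at
`inst/scripts/lamellipod-cli.R`:

```sh
Rscript inst/scripts/lamellipod-cli.R check-bistability --preset simulation2 --out out/
Rscript inst/scripts/lamellipod-cli.R simulate-fragment --fragment-setup --ic asymmetric --t-end 120 --out out/
```

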