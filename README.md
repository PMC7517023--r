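# miweb

Mutual information as a general measure of structure in bipartite ecological
interaction networks.

## The problem

Interaction webs — plants and their pollinators, hosts and their parasites —
are recorded as incidence matrices `a_ij`: rows are the species of one set X,
columns the species of the other set Y, and `a_ij > 0` means species `i` and
`j` interact. Ecologists describe the *topology* of such matrices with
pattern-specific indices (nestedness, modularity), but those indices are not
measures of specialization. `miweb` implements an entropy-based alternative:
the mutual information between the two species sets, normalized so that webs
of any size and fill can be compared.

From the interaction probabilities `p_i(X) = k_i / NM` (row margins over the
interaction total), `p_j(Y)` and the cell distribution `p_l(X,Y) = a_l / NM`:

    H(X)   = -Σ p_i log p_i          (marginal entropies)
    I(X;Y) = H(X) + H(Y) - H(X,Y)    (mutual information)
    S      = I(X;Y) / H(X,Y)         (normalized, 0 ≤ S ≤ 1)

`S = 1` is perfect reciprocal specialization (a diagonal matrix); `S = 0` is
the absence of it (a fully occupied matrix). The related specialization index
`H2' = I / I_max` (maximum over tables with the observed margins) is also
provided.

The package supplies, for every classical topology — uniform/regular fills,
random fills, perfectly nested matrices, modular (block-diagonal) matrices
with isometric, rectangular or increasing modules, and compound
nested-modular matrices — both a generator (`matrix_*()`) and the closed-form
solution for S (`s_*()`), plus degree-preserving checkerboard-swap
experiments showing that S is completely insensitive to topology once size,
occupancy and degree distributions are fixed.

## A worked example

```r
library(miweb)

# the half-occupied, maximally nested 20-species web
web <- matrix_nested_packed(20)
glance(entropy_decomposition(web))
#> # A tibble: 1 × 8
#>      hx    hy   hxy    mi      s h2prime    nm   rho
#>   <dbl> <dbl> <dbl> <dbl>  <dbl>   <dbl> <int> <dbl>
#> 1  2.83  2.83  5.35 0.303 0.0567   0.107   210 0.525

s_nested_packed(20)$s          # closed form: 0.05671800, identical to above
s_uniform(20, 20, 0.525)$s     # flat-margin web, same size and fill: 0.1205
```

The nested web carries *less* mutual information (S ≈ 0.057) than a web of
the same dimensions and occupancy with flat margins (S ≈ 0.121): nestedness
forces generalists, and generalism erodes reciprocal specialization.

Swaps that preserve the margins cannot change S at all, however much they
destroy the visible topology:

```r
tr <- swap_experiment(matrix_compound_nested(3, 5), n_swaps = 200, seed = 1)
range(tr$s)          # 0.3599118 0.3599118  — constant to the last digit
tr$nodf[c(1, nrow(tr))]        # 28.6 -> 21.5   (nestedness decays)
tr$modularity[c(1, nrow(tr))]  # 0.667 -> -0.067 (modularity decays)
autoplot(tr)
```

A thin command-line interface over the same functions lives at
`inst/cli/miweb.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/miweb.R", package="miweb"))')" \
  generate modular_isometric --m 3 --t 40 -o web.tsv
Rscript .../miweb.R metrics web.tsv       # prints s = 0.129609
Rscript .../miweb.R analytic modular_isometric --m 3 --t 40
```

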