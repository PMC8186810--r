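# bistablernn

Recurrent neural networks usually store long-term information in
network-wide recurrent weights. Biological neurons can instead hold a bit
*inside a single cell* through **bistability**: a neuron whose intrinsic
dynamics have two stable states keeps whichever state its input history
put it in, indefinitely. `bistablernn` implements recurrent cells built
around this mechanism, for researchers studying long-term-dependency
learning and biologically inspired gating:

* the **bistable recurrent cell (BRC)** — a gated cell whose state update

  $$h_t = c_t \odot h_{t-1} + (1-c_t) \odot \tanh(U x_t + a_t \odot h_{t-1})$$

  with gates $a_t = 1 + \tanh(U_a x_t + w_a \odot h_{t-1}) \in (0,2)$ and
  $c_t = \sigma(U_c x_t + w_c \odot h_{t-1}) \in (0,1)$, uses only
  neuron-to-itself recurrence. When the feedback gate $a_t$ exceeds 1 the
  neuron's scalar map becomes bistable (a supercritical pitchfork at
  $a = 1$) and the cell can latch information for arbitrarily long;
* the **nBRC**, whose gates are computed from the whole layer
  ($W_a h_{t-1}$, $W_c h_{t-1}$) — recurrent neuromodulation — while the
  state update stays cellular;
* a standard **GRU** baseline, hand-written BPTT training with ADAM
  (compiled RcppArmadillo kernels), a dynamical-systems module that
  verifies the monostable/bistable regimes, generators for the
  copy-first-input and denoising long-memory benchmarks and the
  (permuted, line-sequential, variable-length) MNIST transforms, and gate
  introspection utilities.

## Worked example

A single bistable neuron never forgets a pulse; a monostable one does.
The fixed-point scanner shows why — for feedback gain $a = 1.5$ the map
has two stable states besides the now-unstable origin:

```r
library(bistablernn)

find_fixed_points(a = 1.5, c = 0.5)
#> # A tibble: 3 × 3
#>   h_star derivative stability
#> *  <dbl>      <dbl> <chr>
#> 1 -0.859      0.697 stable
#> 2  0          1.25  unstable
#> 3  0.859      0.697 stable

attr(bifurcation_diagram(c = 0.5, steps = 201), "critical_a")
#> [1] 1.01
```

The origin destabilizes at $a = 1$ (within the sweep's grid step): below
it one stable state, above it two — the "two stable states" are the
memory. On the copy-first-input benchmark (recall $x_0$ after $T$ noisy
steps; guessing 0 scores MSE 1) the nBRC separates from the GRU at
$T = 50$ under the desk-scale protocol (two layers of 64 neurons,
6000/5000 train/test samples, 30 epochs, 2 seeds):

```r
train <- gen_copy(T = 50, n = 6000, seed = 8)
test  <- gen_copy(T = 50, n = 5000, seed = 9)
glance(train_protocol("nbrc", c(64, 64), train, test,
                      seeds = c(1, 2), epochs = 30, eval_every = 0))
#> # A tibble: 1 × 6
#>   cell  hidden n_seeds epochs mse_mean  mse_sd
#>   <chr> <chr>    <int>  <dbl>    <dbl>   <dbl>
#> 1 nbrc  64x64        2     30   0.0114 0.00715
```

Both nBRC seeds land two orders of magnitude below chance (0.006 and
0.017): cellular bistability makes the 50-step memory reliable. The same
protocol with `"gru"` gives `mse_mean` 0.541 with `mse_sd` 0.759 — one
seed pinned at chance (1.08), one escaping late (0.004). A 50-step noisy
gap sits at the edge of what network-level gating can bridge, and which
side of the edge a GRU run falls on is seed luck; the bistable cell does
not gamble.

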