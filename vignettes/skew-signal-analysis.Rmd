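---
title: "Nucleotide-skew properties, wavelet signal analysis and genome atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleotide-skew properties, wavelet signal analysis and genome atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skewatlas)
```

## The biological signal

Most prokaryotic chromosomes replicate bidirectionally from a single origin
(oriC).  On the leading strand of each replichore, guanine is systematically
more abundant than cytosine, so the windowed GC skew

$$ S_i = \frac{n_G - n_C}{n_G + n_C} $$

computed over non-overlapping windows along the chromosome flips sign at the
origin and the terminus.  The cumulative GC skew $C_k = \sum_{i \le k} S_i$
turns those two sign switches into a global shape: a V when the sequence
starts at the origin's antipode, a &Lambda; when it starts at the origin,
and a shifted &Lambda;/V otherwise.  The positions of the global minimum and
maximum of $C_k$ are therefore candidate origin and terminus sites, which is
how `locate_extrema()` on the output of `cumulate()` is meant to be read.
The same machinery handles AT skew, keto skew (keto bases G,T versus amino
bases A,C) and GC content; all counts exclude ambiguity codes, so the
denominator shrinks rather than the value becoming undefined.  A window with
a zero denominator reports 0 rather than NaN — the downstream wavelet and
correlation stages need finite vectors, and a warning counts such windows
once per track.

Not every chromosome carries the signal: thermophiles (and some other
lineages) show no skew polarity, and their cumulative skew is closer to a
mean-zero random walk whose extrema carry no positional information.  The
synthetic generator (below) can produce both regimes.

## Windowing and condensation

Windows tile the sequence from position 1 with `step == window` by default;
the window size that condenses a chromosome of length $L$ into at most $R$
display units is $\lceil L/R \rceil$ (`window_size_for()`), e.g. 1,160 bp
for a 4,639 kb chromosome at 4,000 units.  The final window of a linear
sequence is computed over the remaining bases without padding; on a
circular sequence it wraps across the origin.

Signal analysis requires dyadic lengths: `condense()` resamples a track to
$N = 2^m$ equal-width bins by overlap-weighted averaging of the source
windows, treating the track as a piecewise-constant function of genomic
position.  When the track has fewer windows than bins this degrades
gracefully to proportional replication.  Typical analyses use $m$ between
10 and 15; all tracks entering a cross-correlation must share one $m$.

## Wavelet decomposition and denoising

`modwt()` implements the maximal-overlap discrete wavelet transform by the
pyramid algorithm with periodic boundary conditions (the natural choice for
circular chromosomes).  Unlike the decimated DWT, every level retains $N$
coefficients, the transform is invariant to circular shifts of the input,
conserves energy ($\lVert x\rVert^2 = \sum_j \lVert W_j\rVert^2 +
\lVert V_J\rVert^2$) and inverts exactly; the test suite asserts both
identities to 1e-8 relative on random vectors.  Four filters are provided —
Haar (default), Daubechies D4, least-asymmetric LA8 and Fejér-Korovkin FK4 —
as hard-coded orthonormal quadrature pairs.  For the Haar filter the
level-1 detail is the lagged half-difference
$W_{1,t} = (x_t - x_{t-1 \bmod N})/2$, which the tests check elementwise.

"Denoising" here means reconstructing only the level-$J$ smooth: the
inverse transform with every detail series zeroed.  Level-1 details carry
the highest-frequency content (noise); the smooth carries the global shape.
$J = 4$ with $N = 2048$ is the default, mirroring the demonstration
settings used throughout the package (`m = 11`, Haar, $p = 0.999$, maximum
lag equal to the vector size).

A useful Haar-specific diagnostic: differencing undoes accumulation, so the
level-$J$ Haar details of a *cumulative* signal resemble a denoised version
of the underlying raw signal at the same level.
`haar_reverse_cumulative_similarity()` quantifies this as a Pearson
correlation.  One numerical subtlety: the running sum of a finite
realisation is not a periodic sequence, and the periodic transform folds
its net drift into the few coefficients that wrap the boundary — for
$J = 1$ a single coefficient of magnitude $|\sum_t x_t|/2$, often tens of
times the typical detail.  Those first $2^J$ boundary-affected positions
are excluded from the correlation, the standard treatment for circular
boundary artifacts; with them included the statistic would measure the
realised drift, not the similarity of shapes.

## Correlation statistics

`autocorrelation()` and `cross_correlation()` use the biased
(divide-by-$N$, fixed global mean) estimator of `stats::acf()`/`ccf()`,
with lags $0..N{-}1$ and $-(N{-}1)..(N{-}1)$ respectively.  The biased
convention matters: its taper $(1-k/N)$ is what produces the
characteristic strong negative coefficient near half-length for
&Lambda;-shaped cumulative skews (a "mirror-phase" rhythm: the rising and
falling limbs anticorrelate), and it keeps every coefficient in $[-1,1]$.
The taper also pulls the dominant extremum slightly below $N/2$ for
perfectly triangular inputs — about $0.43N$ in the idealised case — while
real, asymmetric skew curves peak closer to half length.  Significance uses
the normal approximation $CI = Z_p/\sqrt{N}$ with two-sided critical values
(1.96, 2.58, 3.29 at $p$ = 0.95, 0.99, 0.999; quantiles are computed at
full precision, the familiar constants being rounded displays).  At
$N = 2048$, $p = 0.999$ the bound is 0.073.

`find_peak()` defines a peak as the local extremum of $|r|$ (strictly
greater than both neighbours) with the largest magnitude at $|{\rm lag}|$
at or beyond a minimum (default 1 bin; lag 0 is excluded for ACF because
$r(0)=1$ is structural); ties break to the smallest $|{\rm lag}|$, and if
no local extremum exists in range the global maximum in range is returned
flagged not significant.

`similarity_summary()` condenses a pairwise comparison into one number:
the maximum $|{\rm ccf}|$ between the level-$j$ details of the two vectors
for $j = 1..J$, plus the maximum $|{\rm ccf}|$ between the two denoised
series, averaged.  Magnitudes are averaged because the underlying maxima
are frequently negative (mirror-phase alignment) while the summary is
meant as a 0-to-1 similarity; the statistic is invariant to affine
rescaling of either input and equals 1 for identical inputs.  Analysing
$k$ tracks performs exactly $k(k-1)/2$ cross-correlations.

## The synthetic generator

`make_skewed_genome()` draws bases independently with
$P(G) - P(C) = \pm\,\texttt{skew\_strength} \times \texttt{gc\_content}$
(sign by replichore), so the expected windowed GC skew on the leading
strand equals `skew_strength` directly.  `noise_sd` adds a per-kilobase
Gaussian jitter to that excess (local compositional heterogeneity), and
`period` superimposes a sinusoidal GC-content modulation (amplitude 10% of
the GC content) for periodicity tests.  `make_periodic_track()` produces a
sinusoid plus noise with a known period.  Defaults used across the tests —
skew strength 0.2–0.3, GC content 0.5, noise 0.05, 1 kb windows — sit in
the range observed for skew-polar eubacteria, where per-window skews of a
few tenths are typical.

What the generator does *not* model: codon and gene structure, repeats,
dinucleotide correlations, horizontally transferred islands, and the
asymmetric replichore lengths of real chromosomes.  Passing tests
therefore demonstrate that the estimators recover programmed ground truth
under realistic noise, not that any particular real chromosome has a
detectable origin; chromosomes without skew polarity genuinely defeat
extrema-based origin calling, and the generator reproduces that failure
mode at `skew_strength = 0`.

Problem sizes in the tests and the acceptance script (genomes of 60–500 kb,
$N$ of 64–2048, 50-seed recovery sweeps) were chosen as the smallest sizes
at which every statistic is comfortably out of its small-sample regime.

## Atlas rendering

`render_atlas()` writes standalone SVG 1.1.  Structure is contractual and
machine-checkable: one `<g class="track">` per configured track in order,
each wrapping a content group, plus one legend group per track
(min/max/mean/sd at the legend corners, condensation window size below,
values shown to 4 significant digits — the legend text layout is fixed by
this package, structural assertions rather than bit-exact text are what
the tests promise).  A property track contributes exactly `resolution`
drawable units in all three styles: histogram bars (height proportional to
$|v - \text{threshold}|$), dots, or a two-color gradient whose darkest
ends mark the minimum and maximum.  Histograms and dots split colors at a
threshold (default mean).

Circular layouts put position 0 at 12 o'clock and advance clockwise —
the common convention in prokaryote atlases; the choice is exposed through
`layout_circular()` so it is testable.  Values grow outward from the
annulus baseline by default (`invert` flips them inward).  The six
exploratory manipulations (move, rotate, size, opacity, width, flip) are
static `track_transform()` fields; transforms compose as a group action
(flips are involutions, rotations add mod 360).  The caterpillar device
references a linear track's content twice more via SVG `<use>`, one full
span to each side, so horizontal repositioning wraps like a circular
chromosome; it is rejected on circular layouts, where wrapping is native.
Scale-independent mode draws all chromosomes at the maximum display span,
discarding length ratios for cross-genome comparison.

Documents are assembled as text and parsed once with `xml2` before being
returned or written, so a malformed document can never be emitted; with a
fixed palette seed the output is byte-identical across runs.

## File formats and the CLI

GenBank flat files are parsed with a purpose-built reader (LOCUS length and
topology, CDS/tRNA/rRNA locations including `complement()` and
origin-spanning `join()` forms, ORIGIN block); coordinates stay 1-based
inclusive throughout, and origin-spanning features are kept as single
`start > end` records rather than split, since both layouts wrap natively.
Multi-segment joins that do not wrap the origin are collapsed to their
span.  Strandless CDS features go to the forward track with a warning —
an arbitrary but explicit choice.

The tab-delimited GDF track format (header
`#gdf<TAB>feature|property<TAB>seq_id<TAB>seq_length`, feature rows
`start end strand label color`, property rows `start end value`) is fully
specified by this package; the historical format of the same name was
never publicly documented, so this dialect is a self-contained stand-in
and round-trips bit-exactly (doubles are written with 17 significant
digits).

The `exec/skewatlas` script exposes `properties`, `analyze`, `atlas` and
`synth` subcommands over the same functions, writing a JSON manifest
(inputs, outputs, seed, config digest, version) beside each run.  Exit
codes: 0 success, 2 usage/configuration error, 1 runtime error.

## Known limitations

* Origin calling from skew extrema fails by construction on chromosomes
  without skew polarity, and misleads on chromosomes (e.g. some
  *Streptomyces*) whose origin sits at the cumulative-skew *maximum*.
* The displayed "wavelet coefficient" panels are raw MODWT details, not
  multiresolution detail series; the two differ by a filtering step and
  either could be argued for.
* The correlation significance bound is a white-noise approximation;
  strongly autocorrelated tracks exceed it easily, so it separates
  structure from noise but is not a calibrated p-value.
* Rasterisation of the SVG output is delegated to external converters.
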