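# carotenostruct

Structural descriptors for carotenoid-binding proteins.

Some marine invertebrates turn orange carotenoids blue: a protein binds the
pigment, and the absorption maximum moves tens of nanometres to the red. The
structural signatures of that bathochromic shift live in a handful of
geometric and interaction descriptors of the bound pigment — how planar and
delocalised its conjugated polyene is, how its end rings are rotated, how two
pigments sit against each other at a dimer interface, and how tightly each
protein subunit wraps the chromophore. `carotenostruct` computes those
descriptors from deposited or generated coordinates, for structural
biologists and photophysics-minded biochemists characterising
carotenoproteins such as the crustacyanins and their sponge analogues.

## What it computes

For a ligand with a conjugated path C6…C6′ the **bond length alternation** is

BLA = mean(single-bond lengths) − mean(double-bond lengths)

over the formal single/double bonds of the path (a triple bond is excluded
from both classes). Lower BLA means a more delocalised pi system and a lower
excitation energy. Around it sit the rest of the toolkit:

* signed torsions in the IUPAC convention, and end-ring *s-cis*/*s-trans*
  classification about the C6–C7 bond (|torsion| > 90° is *s-trans*);
* least-squares polyene planes, interplanar angle, minimum inter-pigment
  distance, and the signed crossing dihedral of a carotenoid pair;
* pseudo-twofold axes: the dimer axis from the α→β superposition rotation
  and the pigment-pair axis from the best polyene-onto-polyene rigid map,
  classified coincident (<30°) / perpendicular (>60°) / oblique;
* contact shells (4 Å heavy-atom criterion), heavy-atom hydrogen-bond
  detection, Shrake–Rupley SASA on a deterministic 960-point lattice and its
  partition across subunits, and per-fragment B-factor statistics;
* sequence-guided Kabsch superposition with outlier trimming
  (BLOSUM62-aligned Cα pairs);
* sequence utilities (Asn-x-Thr sequon scan, signal-peptide bookkeeping,
  conserved-cysteine profiling, monoisotopic masses) and absorption-spectrum
  utilities (λmax calls, bathochromic shifts).

Everything operates on a tidy atom table (one row per atom), so results
compose with dplyr, and each result type has `tidy()`/`glance()` methods and
plot helpers. A synthetic-structure generator (`make_polyene()`,
`make_complex()`, `make_c2_dimer()`, `make_sequence()`, `make_spectrum()`)
builds inputs with known ground truth so the full pipeline is testable with
no downloads.

## Worked example

```r
library(carotenostruct)

# a synthetic dimer-interface complex: two parallel polyenes 7 A apart,
# alternating 1.45/1.35 A bonds, end rings rotated to 170 deg (s-trans)
cx <- make_complex(synthetic_complex_spec())

bla(extract_polyene(cx$ligandA)) |> tidy()
#> # A tibble: 1 x 7
#>   ligand scope mean_single mean_double    bla n_single n_double
#>   <chr>  <chr>       <dbl>       <dbl>  <dbl>    <int>    <int>
#> 1 SYN    full         1.45        1.35 0.1000       10        9

pair_geometry(cx$ligandA, cx$ligandB)
#> <plane_pair> interplanar 0.0 deg, min distance 7.00 A, crossing -, axes -

ring_conformation(cx$ligandA, "ring1")
#> <ring_conformation> ring1: 170.0 deg -> s-trans

sasa_partition(cx$structure, cx$ligandA)
#> <sasa_partition> SYN: isolated 744.2 A^2, exposed 74.0%
#>   buried by A     13.0%
#>   buried by B     12.9%
#>   buried by SYN    0.0%

exact_mass("C40H52O4", "[M+H]+")   # astaxanthin
#> <mass> C40H52O4 [M+H]+: m/z 597.3938

free  <- find_lambda_max(make_spectrum(478)$spectrum)
bound <- find_lambda_max(make_spectrum(549)$spectrum)
bathochromic_shift(free, bound)
#> [1] 71
```

The BLA of 0.10 Å is exactly the constructed single/double difference; the
two chains bury the ligand equally because the generator places their shell
residues mirror-symmetrically; the +71 nm shift is the classic
orange-to-blue displacement of a protein-bound carotenoid.

Deposited structures run through the same surface:

```r
f <- fetch_structure("8I34")                    # needs network
rep <- bcp_structure_report(f, crossing = c("C9", "C15", "C15", "C9"))
rep$chain_superposition; rep$pair; rep$per_ligand$AXT$sasa
```

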