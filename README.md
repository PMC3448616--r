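# phytophore

Sequential virtual screening of natural-product libraries against a
structure-based pharmacophore, with shape/electrostatic-field rescoring
and scaffold-novelty analysis.

## The problem

Dipeptidyl peptidase-IV (DPP-IV) inhibitors are an established class of
type-2-diabetes drugs: DPP-IV degrades the incretins GLP-1 and GIP, so
inhibiting it prolongs glucose-induced insulin secretion. Screening
annotated phytochemical collections for DPP-IV inhibitor candidates is a
way both to explain the activity of traditional antidiabetic plant
extracts and to find new inhibitor scaffolds of natural origin.

`phytophore` is an open, testable engine for the screening cascade used
in that setting. Each stage consumes the survivors of the previous one:

1. **Pharmacophore screen (reorienting).** Ligand conformers are matched
   against a common structure-based pharmacophore — two mandatory sites
   (one positive/donor for the Glu205/Glu206 dyad, one
   hydrophobic/aromatic ring for the S1 pocket) and five optional sites
   (two H-bond acceptors, three rings) — with rigid reorientation
   allowed. A hit must match both mandatory sites plus at least one
   optional site without penetrating any receptor-derived
   excluded-volume sphere.
2. **Pose acquisition.** Docked poses for the survivors are obtained
   from a pluggable provider (any external docking tool writing SDF).
3. **Static pharmacophore re-filter.** Docked poses are re-matched with
   *no* reorientation, discarding molecules predicted to bind
   non-productively.
4. **Field rescoring.** Surviving poses are compared with the reference
   inhibitor pose by the shape Tanimoto
   `ST = V_AB / (V_AA + V_BB − V_AB)` over analytic Gaussian atom
   overlaps, and the electrostatic Tanimoto
   `ET_pb = O_AB / (O_AA + O_BB − O_AB)` over potential-field inner
   products (1 for identical fields, negative for opposed charges).
   A molecule survives when at least one pose meets both inclusive
   thresholds; the shipped operating point is `ET_pb ≥ 0.468` and
   `ST ≥ 0.237`, and `ET_combo = ST + ET_pb` ranks the survivors.

Downstream, hits merged with known inhibitors are fingerprinted
(MOLPRINT2D atom environments hashed to 32 bits), clustered
hierarchically on `1 − Tanimoto` distance with the cut level chosen by
the Kelley criterion, and clusters free of known inhibitors are flagged
as novel scaffolds. A source-annotation module joins hits to their
natural sources and categorizes extracts (reported antidiabetic /
same-genus related / other).

Deterministic synthetic-fixture generators (`make_toy_pharmacophore`,
`make_funnel_library`, `make_scaffold_collection`) plant known outcomes
at every stage so the whole funnel is testable end to end without any
proprietary database or commercial docking engine.

## Worked example

```r
library(phytophore)

model <- make_toy_pharmacophore(seed = 1)
fix <- make_funnel_library(fixture_spec(seed = 1, n_pass_all = 4,
  n_fail_pharmacophore = 3, n_fail_static = 2, n_fail_thresholds = 1), model)
report <- run_funnel(fix$molecules, model, memory_pose_provider(fix$poses),
                     fix$reference, thresholds = field_thresholds())
print(report)
#> <funnel_report>
#>   input                  10
#>   pharmacophore          7
#>   docking                7
#>   pharmacophore_static   5
#>   field_rescoring        4
print(report$scores, digits = 3)
#>   molecule_id    st  et_pb et_combo
#> 1     PASS_01 0.996  0.995     1.99
#> 2     PASS_02 0.995  0.998     1.99
#> 3     PASS_03 0.997  0.996     1.99
#> 4     PASS_04 0.995  0.997     1.99
#> 5     NOTH_01 0.993 -0.232     0.76
```

Ten planted molecules enter; three lack any optional site (rejected at
the pharmacophore), two dock in a displaced orientation (rejected by the
static re-filter), and one has its charge pattern negated — its shape
score stays at 0.993 but `ET_pb` drops to −0.232, below the 0.468
threshold. Exactly the four planted passers survive.

Scaffold-novelty analysis on a planted collection:

```r
col <- make_scaffold_collection(families = 3, seed = 2, members_per_family = 4)
sol <- cluster_with_reference(col$molecules[col$family == 1],
                              col$molecules[col$family != 1])
novelty_clusters(sol)
#> [1] 1
head(cluster_membership_table(sol), 5)
#>   molecule_id cluster_index is_reference cluster_is_novel
#> 1      F1_M01             1        FALSE             TRUE
#> 2      F1_M02             1        FALSE             TRUE
#> 3      F1_M03             1        FALSE             TRUE
#> 4      F1_M04             1        FALSE             TRUE
#> 5      F2_M01             2         TRUE            FALSE
```

The Kelley criterion selects three clusters and the one containing no
"known inhibitor" member is flagged novel.

A command-line front end for file-based screening lives at
`inst/scripts/phytophore.R`:

```sh
Rscript inst/scripts/phytophore.R screen --library lib.sdf \
    --pharmacophore model.phore --poses poses.sdf --reference ref.sdf \
    --out report/
```

## Scope notes

The headline counts of the original screening campaign
(29,779 → 10,883 → 332 → 84 molecules) are not reproducible here: the
screened natural-product database is proprietary and two funnel stages
ran closed commercial engines. The package reproduces the *method* —
filters, scores, thresholds and accounting — and verifies it on planted
synthetic fixtures. The shipped pharmacophore definition file is a
synthetic stand-in with the published feature topology (its true
coordinates are not public); docking is a pluggable interface, not a
re-implementation.
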