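# ohdsurv

Ontology-based representation of dental EHR data, and survival analysis of
dental restoration longevity on top of it.

Dental electronic health records live in vendor-specific relational tables
where a filling is a row of codes: a CDT billing code (`D2140` = one-surface
amalgam), a Universal tooth number, a surface-letter string (`"MOD"`).
`ohdsurv` is for health-informatics researchers who want the alternative
representation: every clinical particular — this patient, this tooth, this
portion of restoration material, this procedure — becomes an OWL individual
with a stable IRI, typed against a small realist (BFO-style) ontology of
oral health, and linked by well-defined relations (`is part of`,
`realizes`, `has specified input`, `is about`).  On that instance graph the
package reconstructs a classic outcomes question end to end: **how long do
resin fillings last, and which correlates shift their hazard?**

The package contains, as first-class tested modules:

* a **mini ontology** of oral health (encounter hierarchy, roles, teeth
  1–32 and their surface enamels, materials, findings with negated-parthood
  missing-tooth definitions, CDT code classes), serializable to Turtle
  (round-tripping) and OWL 2 functional syntax;
* a **synthetic dental-practice generator**: a flat `patient_history` table
  (patient, provider, birth date, gender, encounter date, CDT code, tooth,
  surfaces) with known ground truth — failure times follow a Weibull
  proportional-hazards model, `h(t | x) = h0(t) · exp(Σ log(HR_i) x_i)`,
  over four binary correlates (male, age ≥ 40 at restoration, posterior
  tooth, multi-surface), with the baseline scale calibrated in closed form,
  `λ = m / (log 2)^(1/k)`, to a target median `m`, plus an optional
  early-failure mixture;
* a **row → RDF translator** with deterministic IRI minting (referent
  tracking: the same tooth keeps the same IRI across repeated work);
* an in-memory **semantic store** materializing exactly the entailments the
  clinical queries need — subclass-closure typing, transitive parthood,
  occurrence-date propagation from visits to their part procedures, and the
  per-patient `next_encounter` chain with its transitive
  `subsequent_encounter` closure — plus cohort extraction under the
  restoration-failure rules (a later restoration on the same tooth sharing
  a restored surface, or a crown / endodontic procedure / extraction of the
  tooth; censoring at the last recorded encounter);
* a **survival stage**: native Kaplan–Meier (product-limit, Greenwood
  bands, median), Cox proportional hazards via `survival::coxph()` rendered
  as percent hazard change `(exp(β) − 1)·100`, and an Epanechnikov-kernel
  smoothed hazard curve;
* SPARQL 1.1 versions of the main queries (`ohd_sparql()`), runnable on the
  exported Turtle with any SPARQL engine, and a command-line front end
  (`inst/cli/ohd-pipeline.R`) with `generate / translate / query / analyze /
  run-all` subcommands.

## Worked example

```r
library(ohdsurv)
library(dplyr)

cfg <- generator_config(n_patients = 200, seed = 7)
res <- run_pipeline(cfg)   # generate -> translate -> materialize -> chain
                           # -> extract -> KM / Cox / hazard
res
#> <ohd_pipeline_result>
#>   cohort: 483 restorations (174 failed)
#>   KM median: 7.66 years
#> <ohd_cox> joint proportional-hazards fit: 483 records, 174 failures
#>   term              p label
#> 1 male         0.242  21% increase
#> 2 age_40plus   0.150  27% increase
#> 3 posterior    0.0271 29% decrease
#> 4 multisurface 0.808  4% increase

tidy(res$cox) |> select(term, hr, conf.low, conf.high, label)
#>   term            hr conf.low conf.high label
#> 1 male         1.21     0.881     1.65  21% increase
#> 2 age_40plus   1.27     0.917     1.76  27% increase
#> 3 posterior    0.709    0.522     0.962 29% decrease
#> 4 multisurface 1.04     0.769     1.40  4% increase
```

Read: on this small synthetic practice, 483 resin restorations enter the
cohort and 174 fail within follow-up.  The overall Kaplan–Meier median of
7.7 years sits well below the 12-year baseline because the default
conditions include an early-failure mixture (15% of failures with mean 0.8
years); the smoothed hazard over the first two years is roughly twice the
hazard over years two to five (`mean_hazard(res$hazard, 0, 2)` = 0.116
vs 0.064 per year).  The Cox column `label` renders each hazard ratio as a
percent change — posterior teeth show a significant 29% hazard decrease
here; at this sample size the other three effects are direction-consistent
with their generating values but not individually significant.  Each result
object has `tidy()` / `glance()` methods and an `autoplot()`.

At recovery scale (thousands of patients, early mixture off) the fitted
percent changes converge on the generating hazard ratios; that computation
is what the acceptance script runs.

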