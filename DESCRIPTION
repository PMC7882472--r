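Package: fragweb
Title: Quantitative Plant-Leafhopper Food Webs in Fragmented Calcareous Grasslands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles quantitative plant-leafhopper food webs from transect
    vegetation surveys, sweep-net leafhopper counts and a literature diet
    database, computes weighted bipartite network indices (Shannon interaction
    diversity, generality, vulnerability, linkage density), incidence-function
    patch connectivity, and specialist/generalist community structure, and
    analyses them with all-subsets AICc model selection and conditional model
    averaging. Includes a synthetic-study generator emulating a paired
    small/large fragment design along connectivity and landscape-composition
    gradients, with known ground-truth effects for power and parameter-recovery
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
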