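Package: sedq
Title: Syndrome-Element Differentiation: Quantification, Weight Condensation,
    Matched-Degree Evaluation and APOSD Knowledge Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational engine for questionnaire-based syndrome-element
    differentiation in traditional Chinese medicine informatics. Quantifies
    categorical inquiry answers (four severity/frequency levels) into scores
    for 47 syndrome elements through a symptom-to-element mapping-weight
    matrix; condenses original real-valued weights onto small ordinal scales
    by four interval-quantization rules (symptom- or element-basis, normal or
    fuzzy granularity); assigns per-group value orders; evaluates agreement
    between condensed and original weights with a weighted matched-degree
    statistic at group and integrated level; and discovers frequent
    syndrome-element combinations by building formal contexts and layered
    attribute partial-ordered structure diagrams (APOSD). Includes a synthetic
    cohort and matrix simulator, cohort screening, CSV/JSON readers and
    writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
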