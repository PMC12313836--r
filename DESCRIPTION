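Package: thyrocost
Title: Activity-Based Costing of Treatments for Benign Thyroid Nodules
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An activity-based costing (ABC) engine for comparing the full
    per-patient cost of treatments for benign symptomatic thyroid nodules
    within a national health service: total thyroidectomy, hemithyroidectomy
    with isthmectomy, and ultrasound-guided thermal ablation. Models
    phase-partitioned cost drivers (pre-hospitalization work-up, drugs,
    disposable materials, personnel, operating room, hospital stay),
    complication-weighted follow-up mixtures, retreatment-rate cost uplift,
    human-capital productivity losses, and payer versus societal accounting
    perspectives. Bundles transcriptions of a published Italian costing study
    as fixture datasets, and provides one-way, tornado and Monte Carlo
    sensitivity analysis plus a seeded synthetic-data generator with
    closed-form ground-truth totals for validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
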