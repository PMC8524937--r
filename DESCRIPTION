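Package: rtflow
Title: Stock-and-Flow Simulation of Radiotherapy Patient Flow and Vacation Capacity Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic continuous (stock-and-flow) simulator of a
    radiotherapy department: a capacity-limited preparation pipeline with a
    fixed lead time feeding a linac treatment stage modelled as an aging
    chain of daily fractions. Includes tools to read, clean, Pareto-aggregate
    and scale booking extracts into weekly referral schedules; a seeded
    synthetic booking generator for testing without clinical data; a built-in
    suite of summer-vacation capacity-reduction scenarios varying period
    length, reduction depth and the timing offset between preparation and
    treatment vacations; baseline-capacity calibration by bisection; and
    scenario metrics (ready-queue peaks, overtime, idle capacity,
    utilization) with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
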