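Package: nearroad
Title: Reduced-Form Near-Road Emission and Dispersion Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts hourly to annual concentrations of traffic-related air
    pollutants (CO, PM2.5, NOx, HC) at receptors near straight road segments
    using a fast 13-parameter multiplicative surrogate of the MOBILE6.2 /
    CALINE4 emission and dispersion models. Includes the Bureau of Public
    Roads volume-delay speed function, speed-binned emission-factor lookups,
    day-type traffic adjustment, a wind-sector double-exponential distance
    profile with wind-speed and traffic-volume dispersion factors, calm-hour
    missing-value semantics, and exposure analytics (daily averaging with
    completeness rules, percentile fields, extreme-day selection,
    cross-receptor correlation of running means, and monitoring-campaign
    error versus the annual mean). A synthetic-data module generates
    meteorology, traffic, vehicle-mix and emission-factor inputs emulating a
    Great Lakes urban setting so every stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
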