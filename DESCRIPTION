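Package: aedmatch
Title: Matching Volunteer Responders and Defibrillators to Cardiac Arrests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A responder-network matching engine for out-of-hospital cardiac
    arrest. Uniquely pairs volunteer responders with automated external
    defibrillators (AEDs) and simultaneously reported emergencies so that
    travel time to the patient is minimized, subject to user-once, AED-once
    and device-battery feasibility constraints. Provides three solvers --
    iterative Hungarian (bipartite) matching over combined AED-emergency
    columns, an exact integer-programming formulation with an inverted-time
    objective, and a travel-time-sliced variant that solves the problem in
    ascending time bands -- plus a lexicographic max-min fairness objective
    that spreads responders across emergencies, a per-emergency cap, a seeded
    synthetic scenario generator, scenario/match I/O (JSON, CSV, GeoJSON) and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    clue,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
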