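Package: apapsim
Title: Whole-Body Simulation of Acetaminophen Metabolism, Hepatotoxicity and
    N-Acetylcysteine Rescue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A five-compartment (gut, plasma, liver, tissue, urine)
    pharmacokinetic model of acetaminophen (APAP) transport and liver
    metabolism: sulfation (bi-bi kinetics limited by PAPS), glucuronidation by
    four UGT isoforms (Michaelis-Menten, Hill, and substrate-inhibition
    kinetics), cytochrome P450 oxidation to the reactive metabolite NAPQI with
    substrate activation, conjugation of NAPQI with glutathione (GSH),
    reversible covalent binding of NAPQI to liver protein, and hepatocyte
    necrosis and regeneration. A calibrated surrogate submodel of hepatic
    glutathione turnover couples APAP load to GSH depletion and recovery and to
    rescue by infused N-acetylcysteine (NAC). Tools are provided to build oral
    and chronic dosing schedules and the three standard NAC infusion
    protocols, to integrate the stiff ODE system over a protocol, and to run
    dose-sweep, chronic-dosing, enzyme-polymorphism, NAC-timing and
    survival-boundary studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
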