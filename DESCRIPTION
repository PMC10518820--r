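Package: mbwater
Title: Analytical Mercedes-Benz Model of Liquid Water in Two Dimensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-mechanical model of liquid water built on the
    two-dimensional Mercedes-Benz picture of hydrogen bonding. Each
    water-water relationship is assigned one of four states (hydrogen
    bonded, Lennard-Jones contact, non-interacting, or cooperative
    hexagonal cage) with isothermal-isobaric statistical weights; a
    hexagon partition function yields state populations and the full
    equilibrium thermodynamics (volume, enthalpy, entropy, heat
    capacities, compressibility, expansivity) by differentiation. A
    population-weighted random-walk extension maps the equilibrium
    solution onto transport properties: diffusion coefficient,
    Stokes-Einstein viscosity, speed of sound, Bridgman-style thermal
    conductivity, and thermal diffusivity on (temperature, pressure)
    grids in reduced units. Includes brute-force validation oracles,
    CSV grid sweeps, anomaly trend detection, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
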